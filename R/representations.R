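# Building-block population codes: object-vector cells (discrete one-hot and
# continuous Gaussian populations), conjunctions as outer products, and
# rate-map conjunctions producing landmark-cell responses.

#' Discrete object-vector population code
#'
#' Encodes the vector relation from location `x` to object `o` as four
#' concatenated one-hot blocks, one per action in the fixed order north, east,
#' south, west. Each block one-hot encodes the signed distance to the object
#' along that action, with distance clamped to -1 for actions pointing away
#' from the object. An object one step east and three steps south of `x` is
#' therefore `onehot(-1), onehot(1), onehot(3), onehot(-1)`, and `x == o`
#' gives `onehot(0)` in all four blocks. Exactly four cells are active for
#' any in-range offset.
#'
#' @param x,o Cells `c(x, y)`.
#' @param max_dist Largest encodable distance `D - 1`; each block spans
#'   distances `-1 ... D - 1` and has `D + 1` cells. Defaults to
#'   `max(width, height)` when a `world` is given.
#' @param world Optional `gridworld` used to default `max_dist`.
#' @return An `ov_code`: numeric activity vector with block layout attributes.
#' @export
discrete_object_vector <- function(x, o, max_dist = NULL, world = NULL) {
  if (is.null(max_dist)) {
    if (is.null(world)) stop("give either max_dist or a world")
    max_dist <- max(world$width, world$height) - 1L
  }
  offset <- c(o[1] - x[1], o[2] - x[2])
  ov_encode_offset(offset, max_dist)
}

# Signed distance along each action; opposite directions clamp to -1.
ov_block_distances <- function(offset) {
  c(
    north = if (offset[2] >= 0) offset[2] else -1L,
    east = if (offset[1] >= 0) offset[1] else -1L,
    south = if (offset[2] <= 0) -offset[2] else -1L,
    west = if (offset[1] <= 0) -offset[1] else -1L
  )
}

ov_encode_offset <- function(offset, max_dist) {
  d <- ov_block_distances(offset)
  if (any(d > max_dist)) {
    stop("offset (", offset[1], ",", offset[2], ") exceeds one-hot range ", max_dist)
  }
  block_len <- max_dist + 2L # distances -1 .. max_dist
  code <- numeric(4L * block_len)
  for (b in seq_len(4L)) {
    code[(b - 1L) * block_len + d[b] + 2L] <- 1
  }
  structure(code,
    class = "ov_code", block_len = block_len, max_dist = max_dist,
    actions = GRID_ACTIONS
  )
}

#' Decode a discrete object-vector code back to its (dx, dy) offset
#'
#' @param code An `ov_code` from [discrete_object_vector()].
#' @return Integer `c(dx, dy)`.
#' @export
decode_object_vector <- function(code) {
  block_len <- attr(code, "block_len")
  d <- vapply(seq_len(4L), function(b) {
    which.max(code[(b - 1L) * block_len + seq_len(block_len)]) - 2L
  }, numeric(1))
  dx <- if (d[2] > 0) d[2] else -d[4]
  dy <- if (d[1] > 0) d[1] else -d[3]
  c(dx, dy)
}

#' Continuous object-vector population
#'
#' `make_ovc_population()` lays preferred vectors on a square grid centred on
#' the object; `continuous_object_vector()` evaluates one 2D Gaussian firing
#' field per cell, tuned to its preferred distance and direction from the
#' reference object, at the current offset `x - o`.
#'
#' @param spacing Grid spacing of preferred vectors (metres).
#' @param extent Half-width of the preferred-vector grid (metres).
#' @param sigma Isotropic Gaussian field width (s.d., metres).
#' @return A tibble of preferred vectors `dx`, `dy` with parameters attached.
#' @export
make_ovc_population <- function(spacing = 0.1, extent = 1, sigma = 0.05) {
  g <- seq(-extent, extent, by = spacing)
  pop <- tidyr::expand_grid(dx = g, dy = g)
  attr(pop, "sigma") <- sigma
  attr(pop, "spacing") <- spacing
  pop
}

#' @rdname make_ovc_population
#' @param x,o Continuous coordinates (metres).
#' @param pop Population from [make_ovc_population()].
#' @return Nonnegative activity vector, one entry per cell. Codes whose peak
#'   activity falls below `exp(-8)` (offset far outside the population's
#'   coverage) carry attribute `coverage_ok = FALSE`.
#' @export
continuous_object_vector <- function(x, o, pop = make_ovc_population()) {
  stopifnot(nrow(pop) > 0)
  sigma <- attr(pop, "sigma")
  off <- c(x[1] - o[1], x[2] - o[2])
  act <- exp(-((pop$dx - off[1])^2 + (pop$dy - off[2])^2) / (2 * sigma^2))
  structure(act, coverage_ok = max(act) >= exp(-8))
}

#' Conjunction of two population codes
#'
#' The conjunctive code has one cell for every pair of parent cells, with
#' activity equal to the product of the pair (an outer product). With
#' `length(a) == 3` and `length(b) == 4` the conjunction has 12 cells.
#'
#' @param a,b Numeric activity vectors.
#' @return A tibble with parent indices `i` (into `a`), `j` (into `b`) and
#'   the product `value`.
#' @export
conjunction <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty parent code")
  prod <- outer(as.numeric(a), as.numeric(b))
  tibble::tibble(
    i = rep(seq_along(a), times = length(b)),
    j = rep(seq_along(b), each = length(a)),
    value = as.numeric(prod)
  )
}

# ---- rate-map container ----------------------------------------------------

#' Rate-map container
#'
#' A dense 2D firing-rate image with bin metadata. `rate[i, j]` is the bin
#' whose centre is `origin + (c(i, j) - 0.5) * bin_size`, i.e. rows index x
#' and columns index y.
#'
#' @param rate Numeric matrix of rates (Hz).
#' @param bin_size Bin side length (same unit as `origin`).
#' @param origin Coordinate of the map's lower-left corner.
#' @param occupancy Optional occupancy matrix (seconds).
#' @export
ratemap <- function(rate, bin_size, origin = c(0, 0), occupancy = NULL) {
  structure(
    list(
      rate = rate, bin_size = bin_size, origin = origin,
      occupancy = occupancy
    ),
    class = "ratemap"
  )
}

#' @export
print.ratemap <- function(x, ...) {
  cat(sprintf(
    "<ratemap %dx%d bins of %.3g, peak %.3g Hz>\n",
    nrow(x$rate), ncol(x$rate), x$bin_size, max(x$rate, na.rm = TRUE)
  ))
  invisible(x)
}

same_binning <- function(a, b) {
  identical(dim(a$rate), dim(b$rate)) &&
    isTRUE(all.equal(a$bin_size, b$bin_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Rate-map conjunction
#'
#' Elementwise product of two rate maps on identical binning. This is how
#' landmark-cell responses arise: a grid map multiplied by an object-vector
#' map has fields only where the grid peaks overlap the object-vector field,
#' so the conjunctive cell responds to some objects but not others.
#'
#' @param map_a,map_b `ratemap` objects with identical binning.
#' @return A `ratemap` holding the product.
#' @export
ratemap_conjunction <- function(map_a, map_b) {
  if (!same_binning(map_a, map_b)) stop("rate maps have mismatched binning")
  ratemap(map_a$rate * map_b$rate, map_a$bin_size, map_a$origin)
}
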