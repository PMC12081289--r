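# Deterministic MDP worlds: discrete square grids and continuous 1 m x 1 m
# arenas with randomly placed walls and a reward.
#
# Discrete coordinates are 0-based (col, row) with the origin at the
# south-west corner, so "north" increases y and "east" increases x.
# Continuous coordinates are metres with the same origin.

GRID_ACTIONS <- c("north", "east", "south", "west")
GRID_DELTAS <- matrix(c(0L, 1L, 1L, 0L, 0L, -1L, -1L, 0L),
  nrow = 4, byrow = TRUE,
  dimnames = list(GRID_ACTIONS, c("dx", "dy"))
)

#' Ordered action set of discrete grid worlds
#'
#' @return Character vector `c("north", "east", "south", "west")`.
#' @export
grid_actions <- function() GRID_ACTIONS

cell_key <- function(x, y) paste(x, y, sep = ",")

canonical_edge <- function(x1, y1, x2, y2) {
  swap <- (x2 < x1) | (x2 == x1 & y2 < y1)
  a1 <- ifelse(swap, x2, x1)
  b1 <- ifelse(swap, y2, y1)
  a2 <- ifelse(swap, x1, x2)
  b2 <- ifelse(swap, y1, y2)
  tibble::tibble(x1 = a1, y1 = b1, x2 = a2, y2 = b2)
}

all_grid_edges <- function(width, height) {
  xs <- seq_len(width) - 1L
  ys <- seq_len(height) - 1L
  horiz <- tidyr::expand_grid(x1 = xs[-length(xs)], y1 = ys) |>
    dplyr::mutate(x2 = .data$x1 + 1L, y2 = .data$y1)
  vert <- tidyr::expand_grid(x1 = xs, y1 = ys[-length(ys)]) |>
    dplyr::mutate(x2 = .data$x1, y2 = .data$y1 + 1L)
  dplyr::bind_rows(horiz, vert)
}

edge_blocked <- function(world, x1, y1, x2, y2) {
  if (nrow(world$walls) == 0) {
    return(FALSE)
  }
  e <- canonical_edge(x1, y1, x2, y2)
  any(world$walls$x1 == e$x1 & world$walls$y1 == e$y1 &
    world$walls$x2 == e$x2 & world$walls$y2 == e$y2)
}

new_gridworld <- function(width, height, walls, reward) {
  structure(
    list(
      width = as.integer(width), height = as.integer(height),
      walls = walls, reward = reward
    ),
    class = "gridworld"
  )
}

#' @export
print.gridworld <- function(x, ...) {
  cat(sprintf(
    "<gridworld %dx%d, %d wall(s), reward %s>\n", x$width, x$height,
    nrow(x$walls), if (is.null(x$reward)) "none" else cell_key(x$reward[1], x$reward[2])
  ))
  invisible(x)
}

grid_free_cells <- function(world) {
  tidyr::expand_grid(x = seq_len(world$width) - 1L, y = seq_len(world$height) - 1L)
}

# Breadth-first distances from a source cell over open edges.
grid_bfs <- function(world, source) {
  dist <- matrix(NA_integer_, nrow = world$width, ncol = world$height)
  dist[source[1] + 1L, source[2] + 1L] <- 0L
  frontier <- matrix(source, ncol = 2)
  while (nrow(frontier) > 0) {
    nxt <- vector("list", nrow(frontier) * 4L)
    k <- 0L
    for (i in seq_len(nrow(frontier))) {
      cx <- frontier[i, 1]
      cy <- frontier[i, 2]
      for (a in seq_len(4L)) {
        nx <- cx + GRID_DELTAS[a, 1]
        ny <- cy + GRID_DELTAS[a, 2]
        if (nx < 0 || ny < 0 || nx >= world$width || ny >= world$height) next
        if (!is.na(dist[nx + 1L, ny + 1L])) next
        if (edge_blocked(world, cx, cy, nx, ny)) next
        dist[nx + 1L, ny + 1L] <- dist[cx + 1L, cy + 1L] + 1L
        k <- k + 1L
        nxt[[k]] <- c(nx, ny)
      }
    }
    frontier <- if (k > 0) do.call(rbind, nxt[seq_len(k)]) else matrix(numeric(0), ncol = 2)
  }
  dist
}

#' Sample a discrete grid world
#'
#' Draws a rectangular grid world with `n_walls` blocked edges and (optionally)
#' a reward cell, resampling until every cell remains connected to the reward.
#' Walls are blocked edges between adjacent cells, not filled cells; each wall
#' records its two endpoint cells, which later feed the two wall-end vector
#' populations. Randomness comes from R's global stream, so `set.seed()` makes
#' the draw reproducible.
#'
#' @param width,height Cell counts, at least 2.
#' @param n_walls Number of blocked edges.
#' @param reward Either `TRUE` (place uniformly at random), a length-2 cell
#'   `c(x, y)`, or `FALSE` for a reward-free world (then connectivity is
#'   checked from cell (0, 0)).
#' @param max_tries Resampling attempts before giving up.
#' @return A `gridworld` object.
#' @export
sample_gridworld <- function(width, height, n_walls = 0, reward = TRUE,
                             max_tries = 100) {
  stopifnot(width >= 2, height >= 2)
  edges <- all_grid_edges(width, height)
  for (try in seq_len(max_tries)) {
    r <- if (isTRUE(reward)) {
      c(sample.int(width, 1) - 1L, sample.int(height, 1) - 1L)
    } else if (is.numeric(reward)) as.integer(reward) else NULL
    walls <- edges[sample.int(nrow(edges), min(n_walls, nrow(edges))), , drop = FALSE]
    world <- new_gridworld(width, height, walls, r)
    src <- if (is.null(r)) c(0L, 0L) else r
    if (all(!is.na(grid_bfs(world, src)))) {
      return(world)
    }
  }
  stop(
    "could not sample a fully connected world in ", max_tries,
    " attempts; the wall budget is too large for this grid"
  )
}

#' Step through a world
#'
#' Applies one action to a location. Moves that would cross a wall or leave
#' the world are no-ops: the unchanged location is returned, so rollouts are
#' total.
#'
#' @param world A `gridworld` or `arena`.
#' @param location Discrete cell `c(x, y)` or continuous coordinate in metres.
#' @param action For grids, one of [grid_actions()] (or its index); for
#'   arenas, a heading angle in radians.
#' @return The next location.
#' @export
transition <- function(world, location, action) UseMethod("transition")

#' @export
transition.gridworld <- function(world, location, action) {
  if (is.character(action)) action <- match(action, GRID_ACTIONS)
  if (is.na(action) || action < 1 || action > 4) stop("invalid action")
  nxt <- location + GRID_DELTAS[action, ]
  if (nxt[1] < 0 || nxt[2] < 0 || nxt[1] >= world$width || nxt[2] >= world$height) {
    return(location)
  }
  if (edge_blocked(world, location[1], location[2], nxt[1], nxt[2])) {
    return(location)
  }
  unname(nxt)
}

#' Ground-truth optimal policy of a world
#'
#' The optimal policy minimises the number of steps (discrete) or the
#' obstacle-avoiding path length (continuous) to the reward from each
#' location. Unreachable locations are excluded from the table and reported
#' in the `"unreachable"` attribute.
#'
#' @param world A `gridworld` or `arena` with a reward.
#' @param ... Method arguments, e.g. `resolution` for arenas.
#' @return A tibble with one row per location: `x`, `y`, `dist` and either
#'   `action` (discrete) or a unit heading `hx`, `hy` (continuous).
#' @export
optimal_policy <- function(world, ...) UseMethod("optimal_policy")

#' @export
optimal_policy.gridworld <- function(world, ...) {
  if (is.null(world$reward)) stop("world has no reward")
  dist <- grid_bfs(world, world$reward)
  cells <- grid_free_cells(world)
  cells$dist <- dist[cbind(cells$x + 1L, cells$y + 1L)]
  pick_action <- function(x, y, d) {
    if (is.na(d) || d == 0) {
      return(NA_character_)
    }
    for (a in seq_len(4L)) { # fixed action order breaks ties
      nx <- x + GRID_DELTAS[a, 1]
      ny <- y + GRID_DELTAS[a, 2]
      if (nx < 0 || ny < 0 || nx >= world$width || ny >= world$height) next
      if (edge_blocked(world, x, y, nx, ny)) next
      if (!is.na(dist[nx + 1L, ny + 1L]) && dist[nx + 1L, ny + 1L] == d - 1L) {
        return(GRID_ACTIONS[a])
      }
    }
    NA_character_
  }
  cells$action <- purrr::pmap_chr(
    list(cells$x, cells$y, cells$dist),
    pick_action
  )
  unreachable <- cells[is.na(cells$dist), c("x", "y")]
  out <- cells[!is.na(cells$dist), ]
  attr(out, "unreachable") <- unreachable
  out
}

# ---- continuous arenas -----------------------------------------------------

new_arena <- function(side, walls, reward, contact_radius = 0.05,
                      step_size = 0.05) {
  structure(
    list(
      side = side, walls = walls, reward = reward,
      contact_radius = contact_radius, step_size = step_size
    ),
    class = "arena"
  )
}

#' @export
print.arena <- function(x, ...) {
  cat(sprintf(
    "<arena %.2g m, %d wall(s), reward (%.2f, %.2f)>\n",
    x$side, nrow(x$walls), x$reward[1], x$reward[2]
  ))
  invisible(x)
}

# TRUE where segment p1-p2 properly intersects q1-q2 (shared endpoints and
# collinear touching count as crossing, which is the conservative choice for
# movement blocking). Vectorised over the q segments.
segments_cross <- function(p1, p2, q1x, q1y, q2x, q2y) {
  o <- function(ax, ay, bx, by, cx, cy) {
    sign((by - ay) * (cx - bx) - (bx - ax) * (cy - by))
  }
  d1 <- o(p1[1], p1[2], p2[1], p2[2], q1x, q1y)
  d2 <- o(p1[1], p1[2], p2[1], p2[2], q2x, q2y)
  d3 <- o(q1x, q1y, q2x, q2y, p1[1], p1[2])
  d4 <- o(q1x, q1y, q2x, q2y, p2[1], p2[2])
  crossing <- d1 != d2 & d3 != d4
  on_seg <- function(ax, ay, bx, by, cx, cy) { # c collinear with a-b?
    cx >= pmin(ax, bx) - 1e-12 & cx <= pmax(ax, bx) + 1e-12 &
      cy >= pmin(ay, by) - 1e-12 & cy <= pmax(ay, by) + 1e-12
  }
  touch <- (d1 == 0 & on_seg(p1[1], p1[2], p2[1], p2[2], q1x, q1y)) |
    (d2 == 0 & on_seg(p1[1], p1[2], p2[1], p2[2], q2x, q2y)) |
    (d3 == 0 & on_seg(q1x, q1y, q2x, q2y, p1[1], p1[2])) |
    (d4 == 0 & on_seg(q1x, q1y, q2x, q2y, p2[1], p2[2]))
  crossing | touch
}

move_blocked <- function(world, from, to) {
  if (any(to < 0) || any(to > world$side)) {
    return(TRUE)
  }
  if (nrow(world$walls) == 0) {
    return(FALSE)
  }
  any(segments_cross(
    from, to, world$walls$x1, world$walls$y1,
    world$walls$x2, world$walls$y2
  ))
}

#' Sample a continuous arena
#'
#' Places `n_walls` straight wall segments at random locations and
#' orientations inside a square arena, plus a reward coordinate, resampling
#' until the reward is reachable from a grid of test points.
#'
#' @param n_walls Number of wall segments.
#' @param side Arena side length in metres.
#' @param reward `TRUE` (uniform random), a coordinate, or `FALSE`.
#' @param wall_length Range the segment lengths are drawn from (metres).
#' @param max_tries Resampling attempts before erroring.
#' @return An `arena` object.
#' @export
sample_arena <- function(n_walls = 0, side = 1, reward = TRUE,
                         wall_length = c(0.2, 0.5), max_tries = 100) {
  for (try in seq_len(max_tries)) {
    r <- if (isTRUE(reward)) {
      stats::runif(2, 0.05, side - 0.05)
    } else if (is.numeric(reward)) reward else NULL
    walls <- purrr::map(seq_len(n_walls), function(i) {
      len <- stats::runif(1, wall_length[1], wall_length[2])
      theta <- stats::runif(1, 0, pi)
      for (k in seq_len(50)) {
        ctr <- stats::runif(2, 0, side)
        a <- ctr - len / 2 * c(cos(theta), sin(theta))
        b <- ctr + len / 2 * c(cos(theta), sin(theta))
        if (all(c(a, b) >= 0) && all(c(a, b) <= side)) {
          return(tibble::tibble(x1 = a[1], y1 = a[2], x2 = b[1], y2 = b[2]))
        }
      }
      stop("could not place a wall inside the arena")
    }) |> purrr::list_rbind()
    if (n_walls == 0) {
      walls <- tibble::tibble(
        x1 = numeric(), y1 = numeric(),
        x2 = numeric(), y2 = numeric()
      )
    }
    world <- new_arena(side, walls, r)
    if (is.null(r) || arena_all_reachable(world)) {
      return(world)
    }
  }
  stop("could not sample a reachable arena in ", max_tries, " attempts")
}

arena_nodes <- function(world, resolution = 21) {
  g <- seq(0, world$side, length.out = resolution)
  tidyr::expand_grid(x = g, y = g)
}

# Lattice graph over the arena with edges removed where they cross a wall;
# used both for reachability checks and the continuous optimal policy.
arena_graph <- function(world, resolution = 21) {
  nodes <- arena_nodes(world, resolution)
  n <- nrow(nodes)
  idx <- matrix(seq_len(n), nrow = resolution) # [ix, iy]
  nbr <- tidyr::expand_grid(dx = -1:1, dy = -1:1) |> dplyr::filter(!(.data$dx == 0 & .data$dy == 0))
  from <- integer(0)
  to <- integer(0)
  w <- numeric(0)
  for (k in seq_len(nrow(nbr))) {
    ix <- seq_len(resolution)
    jx <- ix + nbr$dx[k]
    iy <- seq_len(resolution)
    jy <- iy + nbr$dy[k]
    okx <- jx >= 1 & jx <= resolution
    oky <- jy >= 1 & jy <= resolution
    pairs <- tidyr::expand_grid(ix = ix[okx], iy = iy[oky])
    a <- idx[cbind(pairs$ix, pairs$iy)]
    b <- idx[cbind(pairs$ix + nbr$dx[k], pairs$iy + nbr$dy[k])]
    keep <- a < b
    a <- a[keep]
    b <- b[keep]
    if (nrow(world$walls) > 0 && length(a) > 0) {
      open <- purrr::map2_lgl(a, b, function(i, j) {
        !move_blocked(world, c(nodes$x[i], nodes$y[i]), c(nodes$x[j], nodes$y[j]))
      })
      a <- a[open]
      b <- b[open]
    }
    from <- c(from, a)
    to <- c(to, b)
    w <- c(w, sqrt((nodes$x[a] - nodes$x[b])^2 + (nodes$y[a] - nodes$y[b])^2))
  }
  list(
    nodes = nodes,
    graph = igraph::graph_from_edgelist(cbind(from, to), directed = FALSE) |>
      igraph::set_edge_attr("weight", value = w)
  )
}

arena_all_reachable <- function(world, resolution = 11) {
  ag <- arena_graph(world, resolution)
  ri <- which.min((ag$nodes$x - world$reward[1])^2 + (ag$nodes$y - world$reward[2])^2)
  d <- igraph::distances(ag$graph, v = ri)
  all(is.finite(d[seq_len(nrow(ag$nodes))]))
}

#' @export
transition.arena <- function(world, location, action) {
  if (!is.numeric(action) || length(action) != 1 || !is.finite(action)) {
    stop("invalid action: arena actions are heading angles in radians")
  }
  nxt <- location + world$step_size * c(cos(action), sin(action))
  if (move_blocked(world, location, nxt)) {
    return(location)
  }
  nxt
}

#' @rdname optimal_policy
#' @param resolution Nodes per side of the discretisation the continuous
#'   policy is computed on.
#' @export
optimal_policy.arena <- function(world, resolution = 21, ...) {
  if (is.null(world$reward)) stop("world has no reward")
  ag <- arena_graph(world, resolution)
  nodes <- ag$nodes
  ri <- which.min((nodes$x - world$reward[1])^2 + (nodes$y - world$reward[2])^2)
  d <- as.numeric(igraph::distances(ag$graph, v = ri))
  heading <- matrix(NA_real_, nrow(nodes), 2)
  adj <- igraph::as_adj_list(ag$graph)
  for (i in seq_len(nrow(nodes))) {
    if (!is.finite(d[i]) || d[i] == 0) next
    p <- c(nodes$x[i], nodes$y[i])
    if (!move_blocked(world, p, world$reward)) {
      # reward in direct line of sight: exact straight-line heading
      h <- world$reward - p
    } else {
      nb <- as.integer(adj[[i]])
      step <- sqrt((nodes$x[nb] - p[1])^2 + (nodes$y[nb] - p[2])^2)
      best <- nb[which.min(d[nb] + step)]
      h <- c(nodes$x[best], nodes$y[best]) - p
    }
    heading[i, ] <- h / sqrt(sum(h^2))
  }
  out <- tibble::tibble(
    x = nodes$x, y = nodes$y, dist = d,
    hx = heading[, 1], hy = heading[, 2]
  )
  attr(out, "unreachable") <- out[!is.finite(out$dist), c("x", "y")]
  out[is.finite(out$dist), ]
}

# ---- serialization ---------------------------------------------------------

#' Serialize a world to and from JSON
#'
#' @param world A `gridworld` or `arena`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @export
world_to_json <- function(world, path = NULL) {
  spec <- if (inherits(world, "gridworld")) {
    list(
      type = "gridworld", width = world$width, height = world$height,
      walls = as.data.frame(world$walls), reward = world$reward
    )
  } else {
    list(
      type = "arena", side = world$side, walls = as.data.frame(world$walls),
      reward = world$reward, contact_radius = world$contact_radius,
      step_size = world$step_size
    )
  }
  js <- jsonlite::toJSON(spec, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) {
    return(js)
  }
  writeLines(js, path)
  invisible(path)
}

#' @rdname world_to_json
#' @param json A JSON string or file path produced by [world_to_json()].
#' @export
world_from_json <- function(json) {
  spec <- jsonlite::fromJSON(json)
  walls <- tibble::as_tibble(spec$walls)
  if (nrow(walls) == 0) {
    walls <- tibble::tibble(
      x1 = numeric(), y1 = numeric(),
      x2 = numeric(), y2 = numeric()
    )
  }
  if (spec$type == "gridworld") {
    new_gridworld(spec$width, spec$height, walls, spec$reward)
  } else {
    new_arena(spec$side, walls, spec$reward, spec$contact_radius, spec$step_size)
  }
}
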