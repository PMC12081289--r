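# Key-value conjunctive memory plus the online tracking loop: noisy path
# integration of vector relations, memory retrieval at the observed location,
# and fusion of the two before re-encoding.
#
# Vector relations are stored as offsets c(dx, dy) = object - agent; the
# memory abstracts the hippocampal conjunction, with the location code as key
# and the object/wall/reward vector as value.

#' Create a key-value memory
#'
#' Entries are append-only within a session. Discrete memories are keyed by
#' exact cell; continuous memories retrieve every entry within the cutoff
#' distance of the query (5 cm by default) and weight the stored values with
#' a softmax over cosine similarities.
#'
#' @param type `"discrete"` or `"continuous"`.
#' @param cutoff Continuous retrieval cutoff in metres.
#' @param temperature Softmax temperature on cosine similarities.
#' @return A `kv_memory` object (environment-backed).
#' @export
kv_memory <- function(type = c("discrete", "continuous"), cutoff = 0.05,
                      temperature = 1) {
  type <- match.arg(type)
  env <- new.env(parent = emptyenv())
  env$key_x <- numeric(0)
  env$key_y <- numeric(0)
  env$val_dx <- numeric(0)
  env$val_dy <- numeric(0)
  env$object <- character(0)
  env$time <- numeric(0)
  env$origin <- character(0)
  env$reads <- 0L
  structure(
    list(type = type, cutoff = cutoff, temperature = temperature, env = env),
    class = "kv_memory"
  )
}

#' @export
print.kv_memory <- function(x, ...) {
  cat(sprintf(
    "<kv_memory (%s): %d entr%s, %d read(s)>\n", x$type,
    length(x$env$key_x), if (length(x$env$key_x) == 1) "y" else "ies",
    x$env$reads
  ))
  invisible(x)
}

#' Store a vector relation in memory
#'
#' @param memory A [kv_memory()].
#' @param key Location `c(x, y)` serving as the key.
#' @param value Offset `c(dx, dy)` (object relative to the key location).
#' @param object Object label, to keep relations to different objects apart.
#' @param time Encoding time (model steps or seconds).
#' @param origin `"behavior"` or `"replay"`; replay-origin entries count
#'   toward retrieval exactly like behavioural ones.
#' @export
memory_encode <- function(memory, key, value, object = "obj", time = NA_real_,
                          origin = "behavior") {
  e <- memory$env
  n <- length(e$key_x) + 1L
  e$key_x[n] <- key[1]
  e$key_y[n] <- key[2]
  e$val_dx[n] <- value[1]
  e$val_dy[n] <- value[2]
  e$object[n] <- object
  e$time[n] <- time
  e$origin[n] <- origin
  invisible(memory)
}

#' Dump a memory as a tibble
#'
#' @param memory A [kv_memory()].
#' @return Tibble with key, value offset, object, time and origin columns.
#' @export
memory_tbl <- function(memory) {
  e <- memory$env
  tibble::tibble(
    key_x = e$key_x, key_y = e$key_y, dx = e$val_dx, dy = e$val_dy,
    object = e$object, time = e$time, origin = e$origin
  )
}

#' Number of retrievals performed on a memory
#' @param memory A [kv_memory()].
#' @export
memory_reads <- function(memory) memory$env$reads

#' Retrieve vector relations stored at a location
#'
#' Discrete memories return a distribution `p_M` over distinct stored offsets
#' with probability proportional to the number of matching entries.
#' Continuous memories return the softmax-weighted entries within the cutoff;
#' the fused point estimate `s_M` is their convex combination. When nothing
#' is retrievable an explicit `"no_memory"` marker is returned and fusion
#' falls back to path integration alone.
#'
#' @param memory A [kv_memory()].
#' @param location Query location `c(x, y)`.
#' @param object Object label to retrieve.
#' @return For discrete memories a tibble `dx, dy, prob`; for continuous a
#'   list with `values` (matrix of offsets), `weights` and `s_m`; or an
#'   object of class `"no_memory"`.
#' @export
memory_retrieve <- function(memory, location, object = "obj") {
  e <- memory$env
  e$reads <- e$reads + 1L
  sel <- e$object == object
  if (memory$type == "discrete") {
    sel <- sel & e$key_x == location[1] & e$key_y == location[2]
    if (!any(sel)) {
      return(structure(list(), class = "no_memory"))
    }
    tb <- tibble::tibble(dx = e$val_dx[sel], dy = e$val_dy[sel]) |>
      dplyr::count(.data$dx, .data$dy, name = "prob")
    tb$prob <- tb$prob / sum(tb$prob)
    tb
  } else {
    d <- sqrt((e$key_x - location[1])^2 + (e$key_y - location[2])^2)
    sel <- sel & d <= memory$cutoff
    if (!any(sel)) {
      return(structure(list(), class = "no_memory"))
    }
    keys <- cbind(e$key_x[sel], e$key_y[sel])
    qn <- sqrt(sum(location^2))
    kn <- sqrt(rowSums(keys^2))
    cossim <- ifelse(qn * kn > 0, as.numeric(keys %*% location) / (qn * kn), 1)
    w <- exp((cossim - max(cossim)) / memory$temperature)
    w <- w / sum(w)
    values <- cbind(dx = e$val_dx[sel], dy = e$val_dy[sel])
    list(values = values, weights = w, s_m = as.numeric(t(values) %*% w))
  }
}

#' Is a retrieval result the "no memory" marker?
#' @param x A retrieval result.
#' @export
is_no_memory <- function(x) inherits(x, "no_memory")

# ---- path integration ------------------------------------------------------

#' Noisy discrete path integration of a vector relation
#'
#' Updates the offset to an object under an action and returns the belief
#' distribution `p_PI`: the correct updated relation with probability
#' `1 - e_pi`, and each of its four action-adjacent neighbour relations with
#' probability `e_pi / 4`.
#'
#' @param offset Current believed offset `c(dx, dy)` (object - agent).
#' @param action One of [grid_actions()] or its index.
#' @param e_pi Path-integration error probability in `[0, 1]`.
#' @return Tibble `dx, dy, prob`, normalised.
#' @export
path_integrate_discrete <- function(offset, action, e_pi = 0) {
  stopifnot(e_pi >= 0, e_pi <= 1)
  if (is.character(action)) action <- match(action, GRID_ACTIONS)
  correct <- c(offset[1] - GRID_DELTAS[action, 1], offset[2] - GRID_DELTAS[action, 2])
  tb <- tibble::tibble(
    dx = unname(correct[1] + c(0, GRID_DELTAS[, 1])),
    dy = unname(correct[2] + c(0, GRID_DELTAS[, 2])),
    prob = c(1 - e_pi, rep(e_pi / 4, 4))
  )
  out <- dplyr::summarise(tb, prob = sum(.data$prob), .by = c("dx", "dy"))
  out[out$prob > 0, ]
}

#' Sample one relation from a discrete belief distribution
#' @param p Tibble `dx, dy, prob`.
#' @return Offset `c(dx, dy)`.
#' @export
sample_relation <- function(p) {
  i <- if (nrow(p) == 1) 1L else sample.int(nrow(p), 1, prob = p$prob)
  c(unname(p$dx[i]), unname(p$dy[i]))
}

#' Noisy continuous path integration
#'
#' Applies a movement step to the believed offset, perturbing the step's
#' direction and size with independent Gaussian noise. The returned point
#' estimate `s_PI` is unbiased to first order in the direction noise (the
#' exact mean of the noisy step is shrunk radially by
#' `exp(-dir_sd^2 / 2)`, which [pi_step_moments()] reports).
#'
#' @param offset Believed offset `c(dx, dy)` in metres.
#' @param step Movement step `c(dx, dy)` actually taken (metres).
#' @param dir_sd Direction noise s.d. (radians).
#' @param step_sd Step-size noise s.d. (metres).
#' @return Updated offset `c(dx, dy)`.
#' @export
path_integrate_continuous <- function(offset, step, dir_sd = 0, step_sd = 0) {
  stopifnot(dir_sd >= 0, step_sd >= 0)
  m <- sqrt(sum(step^2))
  theta <- atan2(step[2], step[1]) + stats::rnorm(1, 0, dir_sd)
  m <- m + stats::rnorm(1, 0, step_sd)
  offset - m * c(cos(theta), sin(theta))
}

#' Exact moments of the noisy continuous step
#'
#' Closed-form mean and variance of the perturbed step used by
#' [path_integrate_continuous()], for testing and bias accounting: with step
#' magnitude m, direction theta, direction noise s.d. a and size noise s.d.
#' b, the noisy step has mean `exp(-a^2/2) * m * (cos theta, sin theta)` and
#' per-axis variances that follow from `E[cos(2(theta + e))]`.
#'
#' @param step Noise-free step `c(dx, dy)`.
#' @param dir_sd,step_sd Noise parameters.
#' @return List with `mean` (length 2) and `var` (length 2).
#' @export
pi_step_moments <- function(step, dir_sd = 0, step_sd = 0) {
  m <- sqrt(sum(step^2))
  theta <- atan2(step[2], step[1])
  k1 <- exp(-dir_sd^2 / 2)
  k2 <- exp(-2 * dir_sd^2)
  em2 <- m^2 + step_sd^2 # E[(m + eps)^2]
  mean <- k1 * m * c(cos(theta), sin(theta))
  # E[cos^2(theta+e)] = (1 + k2 cos 2theta)/2, similarly for sin^2
  ex2 <- em2 * (1 + k2 * cos(2 * theta)) / 2
  ey2 <- em2 * (1 - k2 * cos(2 * theta)) / 2
  list(mean = mean, var = c(ex2, ey2) - mean^2)
}

# ---- discovery and fusion --------------------------------------------------

#' Discover an object and initialise its vector representation
#'
#' Discrete agents discover an object when standing at an adjacent cell (or
#' on it); continuous agents when within `range` (5 cm). Discovery sets the
#' zero-offset relation (in code form, `onehot(0)` in all four blocks) and
#' encodes the true offset at the current location. Re-visiting an already
#' tracked object is a no-op.
#'
#' @param memory A [kv_memory()].
#' @param location Agent location.
#' @param object_location Object coordinate or cell.
#' @param object Object label.
#' @param time Encoding time.
#' @param range Continuous discovery range (metres).
#' @return The initial offset `c(dx, dy)` invisibly, or `NULL` when the
#'   object was already tracked.
#' @export
discover_object <- function(memory, location, object_location, object = "obj",
                            time = NA_real_, range = 0.05) {
  in_range <- if (memory$type == "discrete") {
    sum(abs(object_location - location)) <= 1
  } else {
    sqrt(sum((object_location - location)^2)) <= range
  }
  if (!in_range) {
    stop("discovery attempted out of range")
  }
  if (any(memory$env$object == object)) {
    return(invisible(NULL))
  }
  off <- c(object_location[1] - location[1], object_location[2] - location[2])
  memory_encode(memory, location, off, object = object, time = time)
  invisible(off)
}

#' Fuse path integration with memory retrieval and re-encode
#'
#' Discrete: samples the updated relation from the mixture
#' `w * p_PI + (1 - w) * p_M`. Continuous: returns the weighted point
#' estimate `w * s_PI + (1 - w) * s_M`. Either way the result is stored in
#' memory at the new location. A `"no_memory"` retrieval degenerates to path
#' integration alone.
#'
#' @param p_pi Discrete belief tibble, or continuous point estimate `s_PI`.
#' @param p_m Retrieval result from [memory_retrieve()] (possibly
#'   `"no_memory"`).
#' @param w Fusion weight on path integration, in `[0, 1]`.
#' @param memory A [kv_memory()] the fused relation is encoded into.
#' @param new_location Key for the new entry.
#' @param object Object label.
#' @param time Encoding time.
#' @return The fused/sampled offset `c(dx, dy)`.
#' @export
fuse_and_encode <- function(p_pi, p_m, w, memory, new_location,
                            object = "obj", time = NA_real_) {
  stopifnot(w >= 0, w <= 1)
  no_mem <- is_no_memory(p_m)
  if (memory$type == "discrete") {
    if (is.null(p_pi) && no_mem) stop("both belief sources are empty")
    mix <- if (no_mem) {
      p_pi
    } else {
      dplyr::bind_rows(
        dplyr::mutate(p_pi, prob = .data$prob * w),
        dplyr::mutate(p_m, prob = .data$prob * (1 - w))
      ) |>
        dplyr::summarise(prob = sum(.data$prob), .by = c("dx", "dy"))
    }
    mix$prob <- mix$prob / sum(mix$prob)
    s <- sample_relation(mix)
  } else {
    s <- if (no_mem) p_pi else w * p_pi + (1 - w) * p_m$s_m
  }
  memory_encode(memory, new_location, s, object = object, time = time)
  s
}
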