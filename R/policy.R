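# Supervised policy mapping f(s) = a from state representations to optimal
# actions, for traditional (absolute location) versus compositional
# (object-vector) state codes, plus the latent-learning simulation.

#' Build a state representation
#'
#' Traditional mode encodes absolute location as a one-hot over cells and
#' carries no wall or reward information. Compositional mode concatenates the
#' object-vector codes of the reward first, then of each wall (two codes per
#' wall, one per wall end) in environment-generation order. Undiscovered or
#' absent objects are all-zero blocks, so the layout is identical across
#' environments for a given configuration.
#'
#' @param world A `gridworld`.
#' @param location Cell `c(x, y)`.
#' @param mode `"traditional"` or `"compositional"`.
#' @param layout A layout from [state_layout()]; required so that codes from
#'   different worlds conform.
#' @param discovered Character vector of known objects among
#'   `"reward", "wall1", "wall2", ...`; `NULL` means everything present in
#'   the world is known.
#' @return Numeric vector; its layout is attached as an attribute.
#' @export
build_state_representation <- function(world, location,
                                       mode = c("compositional", "traditional"),
                                       layout = state_layout(world),
                                       discovered = NULL) {
  mode <- match.arg(mode)
  if (mode == "traditional") {
    stopifnot(world$width == layout$width, world$height == layout$height)
    s <- numeric(layout$width * layout$height)
    s[location[2] * layout$width + location[1] + 1L] <- 1
    return(structure(s, layout = layout, mode = mode))
  }
  block <- 4L * (layout$max_dist + 2L)
  known <- function(obj) is.null(discovered) || obj %in% discovered
  s <- numeric(block * (1L + 2L * layout$n_wall_slots))
  if (!is.null(world$reward) && known("reward")) {
    s[seq_len(block)] <- discrete_object_vector(location, world$reward,
      max_dist = layout$max_dist
    )
  }
  n_walls <- min(nrow(world$walls), layout$n_wall_slots)
  for (k in seq_len(n_walls)) {
    if (!known(paste0("wall", k))) next
    ends <- list(
      c(world$walls$x1[k], world$walls$y1[k]),
      c(world$walls$x2[k], world$walls$y2[k])
    )
    for (e in 1:2) {
      at <- block * (1L + 2L * (k - 1L) + (e - 1L))
      s[at + seq_len(block)] <- discrete_object_vector(location, ends[[e]],
        max_dist = layout$max_dist
      )
    }
  }
  structure(s, layout = layout, mode = mode)
}

#' Concatenation layout of a state representation
#'
#' @param world A `gridworld` setting the grid size.
#' @param n_wall_slots Wall slots reserved in the compositional code; worlds
#'   with fewer walls leave the remaining slots at zero.
#' @export
state_layout <- function(world, n_wall_slots = nrow(world$walls)) {
  list(
    width = world$width, height = world$height,
    max_dist = max(world$width, world$height) - 1L,
    n_wall_slots = as.integer(n_wall_slots)
  )
}

# ---- feedforward network ---------------------------------------------------

mlp_init <- function(dims) {
  layers <- purrr::map(seq_len(length(dims) - 1L), function(l) {
    fan_in <- dims[l]
    list(
      W = matrix(stats::rnorm(fan_in * dims[l + 1L], 0, sqrt(2 / fan_in)),
        nrow = fan_in
      ),
      b = numeric(dims[l + 1L])
    )
  })
  list(dims = dims, layers = layers)
}

mlp_forward <- function(net, X) {
  acts <- list(X)
  nl <- length(net$layers)
  for (l in seq_len(nl)) {
    Z <- acts[[l]] %*% net$layers[[l]]$W
    Z <- sweep(Z, 2, net$layers[[l]]$b, "+")
    acts[[l + 1L]] <- if (l < nl) pmax(Z, 0) else Z
  }
  acts
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# One Adam step on the cross-entropy (discrete) or mean-squared (continuous)
# loss; `state` carries the first/second moment accumulators.
mlp_step <- function(net, state, X, Y, task, lr) {
  acts <- mlp_forward(net, X)
  nl <- length(net$layers)
  out <- acts[[nl + 1L]]
  n <- nrow(X)
  if (task == "discrete") {
    P <- softmax_rows(out)
    loss <- -mean(log(pmax(P[cbind(seq_len(n), max.col(Y))], 1e-12)))
    delta <- (P - Y) / n
  } else {
    loss <- mean((out - Y)^2)
    delta <- 2 * (out - Y) / (n * ncol(Y))
  }
  state$t <- state$t + 1L
  for (l in rev(seq_len(nl))) {
    gW <- crossprod(acts[[l]], delta)
    gb <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(net$layers[[l]]$W)) * (acts[[l]] > 0)
    }
    for (p in c("W", "b")) {
      g <- if (p == "W") gW else gb
      state$m[[l]][[p]] <- 0.9 * state$m[[l]][[p]] + 0.1 * g
      state$v[[l]][[p]] <- 0.999 * state$v[[l]][[p]] + 0.001 * g^2
      mhat <- state$m[[l]][[p]] / (1 - 0.9^state$t)
      vhat <- state$v[[l]][[p]] / (1 - 0.999^state$t)
      net$layers[[l]][[p]] <- net$layers[[l]][[p]] - lr * mhat / (sqrt(vhat) + 1e-8)
    }
  }
  list(net = net, state = state, loss = loss)
}

#' Train a policy network
#'
#' Fits a feedforward network with rectified-linear hidden layers by
#' backpropagation with the Adam optimiser (default hyperparameters: learning
#' rate 1e-3, beta 0.9/0.999). Discrete tasks output action probabilities
#' through a softmax; continuous tasks output the `(sin, cos)` of the optimal
#' heading. Training is full-batch passes over the set until the epoch cap.
#' Given the same RNG seed the fit is bit-reproducible.
#'
#' @param X Matrix of state representations (rows = examples).
#' @param y For `task = "discrete"`, integer action indices (1..4) or action
#'   names; for `"continuous"`, headings in radians.
#' @param hidden Hidden layer dimensions, e.g. `c(1000, 750, 500)` for
#'   discrete worlds or `c(3000, 2000, 1000)` for continuous ones.
#' @param task `"discrete"` or `"continuous"`.
#' @param epochs Full-batch passes.
#' @param lr Adam learning rate.
#' @param batch_size Optional minibatch size; `NULL` trains full-batch.
#' @return A `policy_net` object with the fitted weights and a loss trace.
#' @export
train_policy_network <- function(X, y, hidden = c(200, 100),
                                 task = c("discrete", "continuous"),
                                 epochs = 200, lr = 1e-3, batch_size = NULL) {
  task <- match.arg(task)
  stopifnot(nrow(X) > 0)
  if (task == "discrete") {
    if (is.character(y)) y <- match(y, GRID_ACTIONS)
    Y <- matrix(0, nrow(X), 4L)
    Y[cbind(seq_len(nrow(X)), y)] <- 1
  } else {
    Y <- cbind(sin(y), cos(y))
  }
  net <- mlp_init(c(ncol(X), hidden, ncol(Y)))
  state <- list(
    t = 0L,
    m = purrr::map(net$layers, ~ list(W = .x$W * 0, b = .x$b * 0)),
    v = purrr::map(net$layers, ~ list(W = .x$W * 0, b = .x$b * 0))
  )
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    if (is.null(batch_size) || batch_size >= nrow(X)) {
      res <- mlp_step(net, state, X, Y, task, lr)
      net <- res$net
      state <- res$state
      losses[ep] <- res$loss
    } else {
      ord <- sample.int(nrow(X))
      bl <- split(ord, ceiling(seq_along(ord) / batch_size))
      lsum <- 0
      for (b in bl) {
        res <- mlp_step(net, state, X[b, , drop = FALSE], Y[b, , drop = FALSE], task, lr)
        net <- res$net
        state <- res$state
        lsum <- lsum + res$loss * length(b)
      }
      losses[ep] <- lsum / nrow(X)
    }
    if (!is.finite(losses[ep])) stop("training diverged (non-finite loss)")
  }
  structure(
    list(
      net = net, task = task, hidden = hidden,
      loss = tibble::tibble(epoch = seq_len(epochs), loss = losses)
    ),
    class = "policy_net"
  )
}

#' @export
print.policy_net <- function(x, ...) {
  cat(sprintf(
    "<policy_net (%s): %s, final loss %.4g>\n", x$task,
    paste(x$net$dims, collapse = "-"), utils::tail(x$loss$loss, 1)
  ))
  invisible(x)
}

#' Predict actions from a policy network
#'
#' @param object A `policy_net`.
#' @param X Matrix of state representations.
#' @param ... Unused.
#' @return Discrete: matrix of action probabilities (rows sum to 1).
#'   Continuous: matrix of unit-norm `(sin, cos)` headings.
#' @export
predict.policy_net <- function(object, X, ...) {
  out <- mlp_forward(object$net, X)[[length(object$net$layers) + 1L]]
  if (object$task == "discrete") {
    softmax_rows(out)
  } else {
    out / pmax(sqrt(rowSums(out^2)), 1e-12)
  }
}

#' Sample a supervised training set from a world
#'
#' Draws `(state representation, optimal action)` pairs at uniformly sampled
#' reachable locations (excluding the reward cell itself).
#'
#' @param world A `gridworld`.
#' @param n Number of pairs.
#' @param mode Representation mode.
#' @param layout State layout.
#' @return List with matrix `X` and integer actions `y`.
#' @export
sample_training_set <- function(world, n, mode = "compositional",
                                layout = state_layout(world)) {
  pol <- optimal_policy(world)
  pol <- pol[pol$dist > 0, ]
  rows <- sample.int(nrow(pol), n, replace = TRUE)
  X <- t(vapply(
    rows,
    function(i) {
      as.numeric(build_state_representation(
        world, c(pol$x[i], pol$y[i]), mode,
        layout = layout
      ))
    },
    numeric(length(build_state_representation(world, c(0, 0), mode, layout = layout)))
  ))
  list(X = X, y = match(pol$action[rows], GRID_ACTIONS))
}

#' Evaluate a policy by rollout success
#'
#' Rolls the policy out from each start and reports the fraction of starts
#' from which it reaches the reward (within 5 cm in continuous arenas) inside
#' a step budget of four times the optimal path length (minimum 30 steps).
#' Discrete actions are the argmax of the predicted probabilities, ties
#' broken by the fixed action order.
#'
#' @param policy A `policy_net`, or a function `(world, location) -> action`
#'   (e.g. an oracle backed by [optimal_policy()]).
#' @param world The evaluation world.
#' @param starts Matrix/data frame of start cells; defaults to all reachable
#'   non-reward cells.
#' @param mode Representation mode matching the training of `policy`.
#' @param layout State layout used at training time.
#' @param budget_factor Step budget multiplier on the optimal distance.
#' @return Success fraction in `[0, 1]`.
#' @export
evaluate_policy <- function(policy, world, starts = NULL,
                            mode = "compositional",
                            layout = state_layout(world),
                            budget_factor = 4) {
  pol_tbl <- optimal_policy(world)
  if (is.null(starts)) {
    starts <- as.matrix(pol_tbl[pol_tbl$dist > 0, c("x", "y")])
  } else {
    starts <- as.matrix(starts)
  }
  act_fun <- if (inherits(policy, "policy_net")) {
    # deterministic argmax policy: batch-predict one action per cell upfront
    X <- t(vapply(
      seq_len(nrow(pol_tbl)),
      function(i) {
        as.numeric(build_state_representation(
          world, c(pol_tbl$x[i], pol_tbl$y[i]), mode,
          layout = layout
        ))
      },
      numeric(length(build_state_representation(world, c(0, 0), mode, layout = layout)))
    ))
    acts <- max.col(predict(policy, X), ties.method = "first")
    lut <- acts
    names(lut) <- cell_key(pol_tbl$x, pol_tbl$y)
    function(world, loc) unname(lut[[cell_key(loc[1], loc[2])]])
  } else {
    policy
  }
  dists <- pol_tbl$dist
  names(dists) <- cell_key(pol_tbl$x, pol_tbl$y)
  ok <- vapply(seq_len(nrow(starts)), function(i) {
    loc <- as.numeric(starts[i, ])
    d0 <- dists[cell_key(loc[1], loc[2])]
    if (is.na(d0)) {
      return(FALSE)
    }
    budget <- max(30, budget_factor * d0)
    for (step in seq_len(budget)) {
      if (all(loc == world$reward)) {
        return(TRUE)
      }
      loc <- transition(world, loc, act_fun(world, loc))
    }
    all(loc == world$reward)
  }, logical(1))
  mean(ok)
}

# ---- latent learning -------------------------------------------------------

# States where ignoring the wall leads to a suboptimal or blocked route.
behind_wall_states <- function(world) {
  naive <- new_gridworld(world$width, world$height, world$walls[0, ], world$reward)
  pol_true <- optimal_policy(world)
  pol_naive <- optimal_policy(naive)
  joined <- dplyr::inner_join(pol_true, pol_naive,
    by = c("x", "y"),
    suffix = c("_true", "_naive")
  )
  joined[joined$dist_true > joined$dist_naive, c("x", "y")]
}

# Success = rollout on the true world following the optimal policy of the
# world the agent currently believes in (its compositional representation).
belief_rollout_success <- function(world, believed, start, budget_factor = 4) {
  plan <- optimal_policy(believed)
  pol_true <- optimal_policy(world)
  d0 <- pol_true$dist[pol_true$x == start[1] & pol_true$y == start[2]]
  budget <- max(30, budget_factor * d0)
  loc <- start
  for (step in seq_len(budget)) {
    if (all(loc == world$reward)) {
      return(TRUE)
    }
    a <- plan$action[plan$x == loc[1] & plan$y == loc[2]]
    if (length(a) == 0 || is.na(a)) {
      return(FALSE)
    }
    loc <- transition(world, loc, a)
  }
  all(loc == world$reward)
}

#' Latent-learning simulation
#'
#' Contrasts an agent that tracked the wall-vector representation before
#' finding the reward (latent) with one that only knows the reward vector and
#' must rediscover the wall (non-latent). Both agents random-walk a
#' single-wall world; at each encounter of a behind-the-wall state we test
#' whether a rollout planned from the agent's current believed composition
#' reaches the reward. Success is averaged over the 1st..`n_encounters`-th
#' encounter across `n_worlds` worlds.
#'
#' @param n_worlds Number of sampled worlds.
#' @param width,height Grid size.
#' @param n_encounters Encounters tracked per state.
#' @param max_steps Random-walk cap per world.
#' @param remove_wall Ablation: drop the wall from the true world (both
#'   agents then share the correct belief and their curves coincide).
#' @return Tibble `agent, encounter, success` averaged over worlds.
#' @export
latent_learning_experiment <- function(n_worlds = 25, width = 6, height = 6,
                                       n_encounters = 15, max_steps = 3000,
                                       remove_wall = FALSE) {
  res <- purrr::map(seq_len(n_worlds), function(wi) {
    # condition on worlds where the wall actually lengthens some paths,
    # otherwise there are no behind-the-wall states to probe
    world <- NULL
    for (try in seq_len(200)) {
      cand <- sample_gridworld(width, height, n_walls = 1)
      if (remove_wall) cand$walls <- cand$walls[0, ]
      if (remove_wall || nrow(behind_wall_states(cand)) > 0) {
        world <- cand
        break
      }
    }
    if (is.null(world)) {
      return(NULL)
    }
    states <- behind_wall_states(world)
    if (nrow(states) == 0) {
      return(NULL)
    }
    naive <- new_gridworld(world$width, world$height, world$walls[0, ], world$reward)
    wall_cells <- if (nrow(world$walls)) {
      list(
        c(world$walls$x1[1], world$walls$y1[1]),
        c(world$walls$x2[1], world$walls$y2[1])
      )
    } else {
      list()
    }
    counts <- matrix(0L, nrow(states), 1)
    succ <- array(NA, dim = c(2, nrow(states), n_encounters)) # latent, nonlatent
    wall_known <- FALSE # for the non-latent agent
    loc <- world$reward
    for (step in seq_len(max_steps)) {
      loc <- transition(world, loc, sample.int(4, 1))
      if (!wall_known && length(wall_cells) &&
        any(vapply(wall_cells, function(w) all(w == loc), logical(1)))) {
        wall_known <- TRUE
      }
      hit <- which(states$x == loc[1] & states$y == loc[2])
      if (length(hit) == 1 && counts[hit, 1] < n_encounters) {
        counts[hit, 1] <- counts[hit, 1] + 1L
        k <- counts[hit, 1]
        succ[1, hit, k] <- belief_rollout_success(world, world, loc)
        succ[2, hit, k] <- belief_rollout_success(
          world,
          if (wall_known) world else naive, loc
        )
      }
      if (all(counts >= n_encounters)) break
    }
    tibble::tibble(
      agent = rep(c("latent", "nonlatent"), each = n_encounters),
      encounter = rep(seq_len(n_encounters), 2),
      success = c(
        apply(succ[1, , , drop = FALSE], 3, mean, na.rm = TRUE),
        apply(succ[2, , , drop = FALSE], 3, mean, na.rm = TRUE)
      )
    )
  }) |> purrr::list_rbind()
  if (nrow(res) == 0) {
    return(tibble::tibble(
      agent = character(), encounter = integer(),
      success = numeric()
    ))
  }
  dplyr::summarise(res,
    success = mean(.data$success, na.rm = TRUE),
    .by = c("agent", "encounter")
  )
}

# ---- continuous worlds -----------------------------------------------------

#' Continuous state representation and training set
#'
#' In continuous arenas the compositional state is the activity of an
#' object-vector population evaluated at the agent's offset from the reward
#' (walls add two populations each, omitted for reward-only arenas). The
#' optimal action is the heading of the continuous [optimal_policy()].
#'
#' @param arena An `arena`.
#' @param n Number of training pairs.
#' @param pop Object-vector population from [make_ovc_population()].
#' @return List with matrix `X` and headings `y` (radians).
#' @export
sample_training_set_continuous <- function(arena, n,
                                           pop = make_ovc_population()) {
  pol <- optimal_policy(arena)
  pol <- pol[pol$dist > 0, ]
  rows <- sample.int(nrow(pol), n, replace = TRUE)
  X <- t(vapply(rows, function(i) {
    as.numeric(continuous_object_vector(c(pol$x[i], pol$y[i]), arena$reward, pop))
  }, numeric(nrow(pop))))
  list(X = X, y = atan2(pol$hy[rows], pol$hx[rows]))
}

#' Evaluate a continuous policy network by rollout
#'
#' Rolls out the predicted heading (5 cm steps) from each start and reports
#' the fraction of starts reaching within 5 cm of the reward inside the step
#' budget.
#'
#' @param f A continuous-task `policy_net`.
#' @param arena The evaluation arena.
#' @param pop Population used at training time.
#' @param starts Matrix of start coordinates; defaults to a grid.
#' @param goal_cm Success radius (m scale of the arena; 0.05).
#' @param max_steps Rollout budget.
#' @return Success fraction.
#' @export
evaluate_policy_continuous <- function(f, arena, pop = make_ovc_population(),
                                       starts = NULL, goal_cm = 0.05,
                                       max_steps = 80) {
  if (is.null(starts)) {
    g <- seq(0.1, arena$side - 0.1, length.out = 5)
    starts <- as.matrix(tidyr::expand_grid(x = g, y = g))
  }
  ok <- vapply(seq_len(nrow(starts)), function(i) {
    loc <- as.numeric(starts[i, ])
    for (k in seq_len(max_steps)) {
      if (sqrt(sum((loc - arena$reward)^2)) <= goal_cm) {
        return(TRUE)
      }
      s <- continuous_object_vector(loc, arena$reward, pop)
      h <- predict(f, matrix(as.numeric(s), nrow = 1))
      loc <- transition(arena, loc, atan2(h[1], h[2]))
    }
    sqrt(sum((loc - arena$reward)^2)) <= goal_cm
  }, logical(1))
  mean(ok)
}
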