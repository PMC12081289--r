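# Offline replay as imagined path integration: constructive replay writes
# vector memories at remote locations; the contrast model replays backward
# Bellman (Q) backups. Includes the visit-efficiency and noisy-homing
# experiments.

OPPOSITE_ACTION <- c(north = "south", east = "west", south = "north", west = "east")

#' Sample a replay trajectory
#'
#' Trajectories start from a designated state (typically the reward or home
#' location) and either extend out along a random policy (uniform over open
#' actions) or along a reverse-optimal policy that ascends the
#' distance-to-reward field.
#'
#' @param world A `gridworld`.
#' @param start Start cell; defaults to the reward.
#' @param mode `"random"` or `"reverse_optimal"`.
#' @param length Maximum number of steps; defaults to twice the grid
#'   diameter. Reverse-optimal trajectories stop early at local maxima of
#'   the distance field.
#' @return Tibble `step, x, y, action` (`action` is the imagined action that
#'   produced each location; `NA` for the start).
#' @export
sample_replay_trajectory <- function(world, start = world$reward,
                                     mode = c("random", "reverse_optimal"),
                                     length = NULL) {
  mode <- match.arg(mode)
  if (is.null(length)) length <- 2L * (world$width + world$height)
  dist <- if (mode == "reverse_optimal") grid_bfs(world, world$reward) else NULL
  loc <- start
  xs <- integer(length + 1L)
  ys <- integer(length + 1L)
  as <- integer(length + 1L)
  xs[1] <- loc[1]
  ys[1] <- loc[2]
  as[1] <- NA_integer_
  n <- 1L
  for (k in seq_len(length)) {
    open <- which(vapply(
      seq_len(4L),
      function(a) !all(transition(world, loc, a) == loc), logical(1)
    ))
    if (mode == "reverse_optimal") {
      d0 <- dist[loc[1] + 1L, loc[2] + 1L]
      open <- open[vapply(open, function(a) {
        nxt <- transition(world, loc, a)
        dist[nxt[1] + 1L, nxt[2] + 1L] == d0 + 1L
      }, logical(1))]
      if (length(open) == 0) break
    }
    a <- if (length(open) == 1) open else sample(open, 1)
    loc <- transition(world, loc, a)
    n <- n + 1L
    xs[n] <- loc[1]
    ys[n] <- loc[2]
    as[n] <- a
  }
  tibble::tibble(
    step = seq_len(n) - 1L, x = xs[seq_len(n)], y = ys[seq_len(n)],
    action = GRID_ACTIONS[as[seq_len(n)]]
  )
}

#' Constructive replay: encode vector memories along an imagined trajectory
#'
#' Path-integrates both the location (the memory key) and the tracked vector
#' relation (the value) along the trajectory, encoding one replay-origin
#' memory entry per step. Because the transitioned location cannot be
#' observed during replay, path-integration noise corrupts keys as well as
#' values (independently); with zero noise every entry is exact. No memory
#' retrieval happens during replay.
#'
#' @param memory A discrete [kv_memory()].
#' @param world The world the trajectory lives in.
#' @param trajectory From [sample_replay_trajectory()]; the replayed vector
#'   code is anchored at the trajectory start (offset `c(0, 0)` there).
#' @param e_pi Path-integration error probability applied to key and value.
#' @param object Object label for the encoded entries.
#' @param time Encoding time stamp.
#' @return The memory, invisibly (entries appended).
#' @export
constructive_replay <- function(memory, world, trajectory, e_pi = 0,
                                object = "obj", time = NA_real_) {
  anchor <- c(trajectory$x[1], trajectory$y[1])
  key <- anchor
  offset <- c(0, 0)
  for (i in seq_len(nrow(trajectory))[-1]) {
    a <- trajectory$action[i]
    offset <- sample_relation(path_integrate_discrete(offset, a, e_pi))
    # the key path integrates with independent noise: correct transition with
    # probability 1 - e_pi, otherwise one of the action-adjacent cells
    ai <- match(a, GRID_ACTIONS)
    key_next <- key + GRID_DELTAS[ai, ]
    if (e_pi > 0 && stats::runif(1) < e_pi) {
      key_next <- key_next + GRID_DELTAS[sample.int(4L, 1), ]
    }
    key <- key_next
    memory_encode(memory, key, offset, object = object, time = time, origin = "replay")
  }
  invisible(memory)
}

#' Backward Q backups along a replay trajectory
#'
#' Applies temporal-difference backups in the opposite direction of replay:
#' after a replay transition from `a` to `b`, the backup runs from `b` to
#' `a`, i.e. `Q[b, b->a] <- Q[b, b->a] + alpha * (r(a) + gamma * max Q[a, ] -
#' Q[b, b->a])`, with reward 1 on arrival at the world's reward cell.
#'
#' @param Q Matrix of values, `n_cells x 4` (cells indexed
#'   `y * width + x + 1`, actions in [grid_actions()] order); initialise at 0.
#' @param world A `gridworld`.
#' @param trajectory From [sample_replay_trajectory()].
#' @param gamma Temporal discount, default 0.7.
#' @param alpha Learning rate, default 0.8.
#' @param reward_loc Rewarded cell; defaults to the world's reward.
#' @return The updated Q matrix.
#' @export
q_backup_replay <- function(Q, world, trajectory, gamma = 0.7, alpha = 0.8,
                            reward_loc = world$reward) {
  cid <- function(x, y) y * world$width + x + 1L
  for (i in seq_len(nrow(trajectory))[-1]) {
    a_cell <- c(trajectory$x[i - 1L], trajectory$y[i - 1L])
    b_cell <- c(trajectory$x[i], trajectory$y[i])
    if (all(a_cell == b_cell)) next
    rev_a <- match(OPPOSITE_ACTION[[trajectory$action[i]]], GRID_ACTIONS)
    r <- as.numeric(all(a_cell == reward_loc))
    target <- r + gamma * max(Q[cid(a_cell[1], a_cell[2]), ])
    bi <- cid(b_cell[1], b_cell[2])
    Q[bi, rev_a] <- Q[bi, rev_a] + alpha * (target - Q[bi, rev_a])
  }
  Q
}

#' Empty Q table for a world
#' @param world A `gridworld`.
#' @export
q_table <- function(world) {
  matrix(0, world$width * world$height, 4L, dimnames = list(NULL, GRID_ACTIONS))
}

# Is this action optimal at (x, y), i.e. does it strictly decrease the
# breadth-first distance to reward?
action_is_optimal <- function(dist, world, loc, action) {
  nxt <- transition(world, loc, action)
  d0 <- dist[loc[1] + 1L, loc[2] + 1L]
  dist[nxt[1] + 1L, nxt[2] + 1L] == d0 - 1L
}

# Fast exact sampler of the noisy path-integration distribution: the
# correct updated relation with probability 1 - e_pi, else one of its four
# action-adjacent neighbours. Distributionally identical to
# sample_relation(path_integrate_discrete(...)) without the table overhead.
pi_sample_offset <- function(offset, action_idx, e_pi) {
  nxt <- c(
    offset[1] - GRID_DELTAS[action_idx, 1],
    offset[2] - GRID_DELTAS[action_idx, 2]
  )
  if (e_pi > 0 && stats::runif(1) < e_pi) {
    nxt <- nxt + GRID_DELTAS[sample.int(4L, 1), ]
  }
  nxt
}

greedy_offset_action <- function(offset) {
  # offset points agent -> object; step along the largest component, fixed
  # action order (north, east, south, west) breaking ties
  cand <- c(north = offset[2], east = offset[1], south = -offset[2], west = -offset[1])
  which.max(cand)
}

#' Policy success as a function of per-state replay visits
#'
#' For each step of each replay trajectory, applies the agent's replay update
#' (memory encoding or backward Q backup), then asks whether the currently
#' learned policy is optimal at that step's location: for the memory agent,
#' whether the greedy action on the retrieved reward vector decreases the
#' distance to reward; for the Q agent, whether the argmax action does (and
#' some value has been learned there). Success is aggregated by the 1st,
#' 2nd, ... `n_visits`-th replay visit to each location and averaged over
#' `n_worlds` reward-only worlds.
#'
#' @param n_worlds Number of worlds (paper-scale default 25).
#' @param width,height Grid size.
#' @param mode Replay trajectory mode, `"random"` or `"reverse_optimal"`.
#' @param agent `"memory"` or `"q"`.
#' @param n_visits Visit indices tracked.
#' @param e_pi Path-integration noise during replay (0 = noiseless).
#' @param max_replays Replay trajectories per world.
#' @param gamma,alpha Q-backup parameters.
#' @return Tibble `visit, success` (mean over states and worlds), plus
#'   `agent`, `mode` columns.
#' @export
replay_visit_curve <- function(n_worlds = 25, width = 6, height = 6,
                               mode = c("random", "reverse_optimal"),
                               agent = c("memory", "q"), n_visits = 15,
                               e_pi = 0, max_replays = 200,
                               gamma = 0.7, alpha = 0.8) {
  mode <- match.arg(mode)
  agent <- match.arg(agent)
  acc <- matrix(0, n_visits, 2) # successes, counts
  for (wi in seq_len(n_worlds)) {
    world <- sample_gridworld(width, height, n_walls = 0)
    dist <- grid_bfs(world, world$reward)
    visits <- matrix(0L, width, height)
    # per-cell stored offsets (flat lists of entries), avoiding per-step
    # table construction; distributionally equivalent to the kv_memory ops
    m_dx <- vector("list", width * height)
    m_dy <- vector("list", width * height)
    Q <- q_table(world)
    cid <- function(x, y) y * width + x + 1L
    for (rep_i in seq_len(max_replays)) {
      traj <- sample_replay_trajectory(world, mode = mode)
      offset <- c(0, 0)
      for (i in seq_len(nrow(traj))[-1]) {
        loc <- c(traj$x[i], traj$y[i])
        if (agent == "memory") {
          ai <- match(traj$action[i], GRID_ACTIONS)
          offset <- pi_sample_offset(offset, ai, e_pi)
          ci <- cid(loc[1], loc[2])
          m_dx[[ci]] <- c(m_dx[[ci]], offset[1])
          m_dy[[ci]] <- c(m_dy[[ci]], offset[2])
          # offset tracks reward - imagined location, so the greedy step
          # toward the reward follows the most frequent retrieved offset
          key <- paste(m_dx[[ci]], m_dy[[ci]])
          top <- which.max(tabulate(match(key, unique(key))))
          best <- which(key == unique(key)[top])[1]
          ok <- action_is_optimal(
            dist, world, loc,
            greedy_offset_action(c(m_dx[[ci]][best], m_dy[[ci]][best]))
          )
        } else {
          a_cell <- c(traj$x[i - 1L], traj$y[i - 1L])
          rev_a <- match(OPPOSITE_ACTION[[traj$action[i]]], GRID_ACTIONS)
          r <- as.numeric(all(a_cell == world$reward))
          target <- r + gamma * max(Q[cid(a_cell[1], a_cell[2]), ])
          bi <- cid(loc[1], loc[2])
          Q[bi, rev_a] <- Q[bi, rev_a] + alpha * (target - Q[bi, rev_a])
          ok <- max(Q[bi, ]) > 0 &&
            action_is_optimal(dist, world, loc, which.max(Q[bi, ]))
        }
        if (all(loc == world$reward)) next # success is about reaching reward
        v <- visits[loc[1] + 1L, loc[2] + 1L] + 1L
        visits[loc[1] + 1L, loc[2] + 1L] <- v
        if (v <= n_visits) {
          acc[v, 1] <- acc[v, 1] + ok
          acc[v, 2] <- acc[v, 2] + 1
        }
      }
      if (all(visits[dist > 0] >= n_visits)) break
    }
  }
  tibble::tibble(
    agent = agent, mode = mode, visit = seq_len(n_visits),
    success = acc[, 1] / pmax(acc[, 2], 1)
  )
}

# ---- homing ----------------------------------------------------------------

escape_steps <- function(world) 4L * (world$width + world$height)

# One homing run for a given agent; returns the distance from home (in
# steps) after the escape. Uses flat per-cell entry lists and the fast
# pi_sample_offset sampler - distributionally equivalent to the kv_memory /
# path_integrate_discrete / fuse_and_encode surface, without the per-step
# table overhead.
homing_run <- function(world, home, agent, e_pi, explore_len, replays_per_bout,
                       w = 0.5, replay_every = 4L, gamma = 0.7, alpha = 0.8) {
  width <- world$width
  height <- world$height
  Q <- q_table(world)
  cid <- function(x, y) y * width + x + 1L
  m_dx <- vector("list", width * height)
  m_dy <- vector("list", width * height)
  encode <- function(loc, off) {
    ci <- cid(loc[1], loc[2])
    m_dx[[ci]] <<- c(m_dx[[ci]], off[1])
    m_dy[[ci]] <<- c(m_dy[[ci]], off[2])
  }
  # sample s ~ w * p_PI + (1 - w) * p_M: with probability w draw from the
  # noisy path-integration distribution, else one stored entry uniformly
  # (equivalent to p_M with probability proportional to entry counts)
  fuse <- function(belief, ai, loc) {
    ci <- cid(loc[1], loc[2])
    has_mem <- length(m_dx[[ci]]) > 0
    s <- if (!has_mem || stats::runif(1) < w) {
      pi_sample_offset(belief, ai, e_pi)
    } else {
      k <- sample.int(length(m_dx[[ci]]), 1)
      c(m_dx[[ci]][k], m_dy[[ci]][k])
    }
    encode(loc, s)
    s
  }
  random_walk_actions <- function(loc, len) {
    out <- integer(len)
    for (k in seq_len(len)) {
      repeat {
        a <- sample.int(4L, 1)
        nxt <- loc + GRID_DELTAS[a, ]
        if (all(nxt >= 0) && nxt[1] < width && nxt[2] < height) break
      }
      out[k] <- a
      loc <- loc + GRID_DELTAS[a, ]
    }
    out
  }
  clamp <- function(p) pmin(pmax(p, 0L), c(width, height) - 1L)
  do_replays <- function(agent_loc) {
    for (r in seq_len(replays_per_bout)) {
      if (agent == "memory") {
        acts <- random_walk_actions(home, width + height)
        # home-vector memories: value = home relative to imagined location,
        # key path-integrated with independent noise (unobservable in replay)
        key <- home
        off <- c(0, 0)
        for (ai in acts) {
          off <- pi_sample_offset(off, ai, e_pi)
          key_next <- key + GRID_DELTAS[ai, ]
          if (e_pi > 0 && stats::runif(1) < e_pi) {
            key_next <- key_next + GRID_DELTAS[sample.int(4L, 1), ]
          }
          key <- clamp(key_next)
          encode(key, off)
        }
      } else {
        # on-policy Q replay: imagined trajectory starts at the agent's
        # observed location and follows the current policy; the imagined
        # location must be path integrated, so with noise the updates (and
        # the home-reward event) can be assigned to the wrong cells
        bel <- agent_loc
        for (k in seq_len(width + height)) {
          bi0 <- cid(bel[1], bel[2])
          ai <- if (max(Q[bi0, ]) > 0) which.max(Q[bi0, ]) else sample.int(4L, 1)
          bel_next <- bel + GRID_DELTAS[ai, ]
          if (e_pi > 0 && stats::runif(1) < e_pi) {
            bel_next <- bel_next + GRID_DELTAS[sample.int(4L, 1), ]
          }
          bel_next <- clamp(bel_next)
          if (all(bel_next == bel)) next
          r_home <- as.numeric(all(bel_next == home))
          target <- r_home + gamma * max(Q[cid(bel_next[1], bel_next[2]), ])
          Q[bi0, ai] <<- Q[bi0, ai] + alpha * (target - Q[bi0, ai])
          if (r_home > 0) break # imagined arrival at home ends the replay
          bel <- bel_next
        }
      }
    }
  }
  loc <- home
  belief <- c(0L, 0L) # believed offset of home relative to agent
  encode(home, belief)
  for (step in seq_len(explore_len)) {
    a <- sample.int(4L, 1)
    nxt <- transition(world, loc, a)
    if (!all(nxt == loc)) {
      belief <- if (agent == "memory") {
        fuse(belief, a, nxt)
      } else {
        pi_sample_offset(belief, a, e_pi)
      }
    }
    loc <- nxt
    if (agent != "pi" && step %% replay_every == 0L && replays_per_bout > 0) {
      do_replays(loc)
    }
  }
  # escape: greedy descent on the believed home vector (or argmax Q from the
  # observed location, which does not suffer path-integration error)
  for (step in seq_len(escape_steps(world))) {
    if (agent == "q") {
      if (all(loc == home)) break
      qs <- Q[cid(loc[1], loc[2]), ]
      a <- if (max(qs) > 0) which.max(qs) else sample.int(4L, 1)
      loc <- transition(world, loc, a)
    } else {
      if (all(belief == c(0, 0))) break # believes it is home
      a <- greedy_offset_action(belief)
      nxt <- transition(world, loc, a)
      if (!all(nxt == loc)) {
        belief <- if (agent == "memory") {
          fuse(belief, a, nxt)
        } else {
          pi_sample_offset(belief, a, e_pi)
        }
      }
      loc <- nxt
    }
  }
  sum(abs(loc - home))
}

#' Noisy homing experiment
#'
#' The agent starts from home, initialises its home-vector representation,
#' random-walks the arena for `explore_len` steps under path-integration
#' noise, then must escape back home by greedy descent on its believed home
#' vector (or its learned Q values). Three agents are compared: `pi` (path
#' integration only), `memory` (encodes home-vector memories in replays from
#' home, five per bout every four steps by default, and retrieves them during
#' behaviour), and `q` (replays backward Q updates whose update locations are
#' themselves path integrated, then escapes greedily on Q from the observed
#' location).
#'
#' @param noise_levels Path-integration error probabilities.
#' @param explore_lengths Exploration lengths (steps) for the noise-by-length
#'   grid (`pi` vs `memory`).
#' @param replay_counts Replays per bout for the noise-by-replays grid
#'   (`memory` vs `q`), at fixed `explore_len_fixed`.
#' @param n_seeds Repeats per grid cell.
#' @param width,height Grid size (home at the centre).
#' @param explore_len_fixed Exploration length used in the replay-count grid.
#' @return Tidy tibble `experiment, noise, length, replays, agent, seed,
#'   error` with homing error in steps.
#' @export
homing_experiment <- function(noise_levels = c(0, 0.1, 0.2, 0.4),
                              explore_lengths = c(8, 16, 32, 64),
                              replay_counts = c(1, 2, 5, 10),
                              n_seeds = 10, width = 9, height = 9,
                              explore_len_fixed = 32) {
  world <- sample_gridworld(width, height, n_walls = 0, reward = FALSE)
  home <- c(width %/% 2L, height %/% 2L)
  grid1 <- tidyr::expand_grid(
    noise = noise_levels, length = explore_lengths,
    agent = c("pi", "memory"), seed = seq_len(n_seeds)
  )
  res1 <- purrr::pmap(grid1, function(noise, length, agent, seed) {
    err <- homing_run(world, home, agent, noise, length, replays_per_bout = 5)
    tibble::tibble(
      experiment = "noise_by_length", noise = noise, length = length,
      replays = 5, agent = agent, seed = seed, error = err
    )
  }) |> purrr::list_rbind()
  grid2 <- tidyr::expand_grid(
    noise = noise_levels, replays = replay_counts,
    agent = c("memory", "q"), seed = seq_len(n_seeds)
  )
  res2 <- purrr::pmap(grid2, function(noise, replays, agent, seed) {
    err <- homing_run(world, home, agent, noise, explore_len_fixed,
      replays_per_bout = replays
    )
    tibble::tibble(
      experiment = "noise_by_replays", noise = noise,
      length = explore_len_fixed, replays = replays, agent = agent,
      seed = seed, error = err
    )
  }) |> purrr::list_rbind()
  dplyr::bind_rows(res1, res2)
}
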