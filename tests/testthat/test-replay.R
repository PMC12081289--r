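# Replay trajectories, constructive replay, Q backups and their contrasts.

test_that("replay trajectories respect transitions and modes", {
  set.seed(31)
  w <- sample_gridworld(6, 6, 0, reward = c(2, 2))
  dist <- optimal_policy(w)
  dist_at <- function(x, y) dist$dist[dist$x == x & dist$y == y]
  tr <- sample_replay_trajectory(w, mode = "reverse_optimal")
  d <- vapply(seq_len(nrow(tr)), function(i) dist_at(tr$x[i], tr$y[i]), numeric(1))
  expect_true(all(diff(d) == 1)) # strictly ascends the distance field
  expect_equal(c(tr$x[1], tr$y[1]), c(2, 2))
  set.seed(32)
  t1 <- sample_replay_trajectory(w, mode = "random")
  set.seed(32)
  t2 <- sample_replay_trajectory(w, mode = "random")
  expect_identical(t1, t2)
  for (i in seq_len(nrow(t1))[-1]) { # consecutive locations are transitions
    expect_equal(
      transition(w, c(t1$x[i - 1], t1$y[i - 1]), t1$action[i]),
      c(t1$x[i], t1$y[i])
    )
  }
})

test_that("random replay visit marginals match a random-walk oracle", {
  set.seed(33)
  w <- sample_gridworld(4, 4, 0, reward = c(1, 1))
  # transition matrix of the uniform-over-open-actions walk
  P <- matrix(0, 16, 16)
  for (x in 0:3) {
    for (y in 0:3) {
      open <- list()
      for (a in 1:4) {
        nxt <- transition(w, c(x, y), a)
        if (!all(nxt == c(x, y))) open[[length(open) + 1]] <- nxt
      }
      for (nxt in open) {
        P[y * 4 + x + 1, nxt[2] * 4 + nxt[1] + 1] <-
          P[y * 4 + x + 1, nxt[2] * 4 + nxt[1] + 1] + 1 / length(open)
      }
    }
  }
  p0 <- numeric(16)
  p0[1 * 4 + 1 + 1] <- 1
  counts2 <- numeric(16)
  n <- 4000
  for (i in seq_len(n)) {
    tr <- sample_replay_trajectory(w, mode = "random", length = 2)
    id <- tr$y[3] * 4 + tr$x[3] + 1
    counts2[id] <- counts2[id] + 1
  }
  expected2 <- as.numeric(p0 %*% P %*% P)
  expect_lt(max(abs(counts2 / n - expected2)), 4 * sqrt(max(expected2) * (1 - max(expected2)) / n) + 0.01)
})

test_that("noiseless constructive replay writes exact keys and values without reads", {
  set.seed(34)
  w <- sample_gridworld(6, 6, 0, reward = c(3, 3))
  mem <- kv_memory("discrete")
  tr <- sample_replay_trajectory(w, mode = "random", length = 10)
  constructive_replay(mem, w, tr, e_pi = 0, object = "reward")
  expect_equal(memory_reads(mem), 0) # no retrieval during replay
  tb <- memory_tbl(mem)
  expect_equal(nrow(tb), nrow(tr) - 1)
  expect_true(all(tb$origin == "replay"))
  for (r in seq_len(nrow(tb))) { # value = anchor - key, exactly
    expect_equal(c(tb$dx[r], tb$dy[r]), c(3 - tb$key_x[r], 3 - tb$key_y[r]))
  }
  # replay-origin entries retrieve exactly like behavioural ones
  k <- c(tb$key_x[1], tb$key_y[1])
  ret <- memory_retrieve(mem, k, object = "reward")
  expect_false(is_no_memory(ret))
})

test_that("noisy replay encodings are unbiased and average out over replays", {
  set.seed(35)
  w <- sample_gridworld(9, 9, 0, reward = c(4, 4))
  tr <- tibble::tibble(
    step = 0:3, x = c(4, 5, 6, 7), y = c(4, 4, 4, 4),
    action = c(NA, "east", "east", "east")
  )
  vals <- replicate(1500, {
    mem <- kv_memory("discrete")
    constructive_replay(mem, w, tr, e_pi = 0.3)
    tb <- memory_tbl(mem)
    c(tb$dx[3], tb$dy[3]) # value encoded at the trajectory end
  })
  truth <- c(-3, 0)
  se <- apply(vals, 1, stats::sd) / sqrt(ncol(vals))
  expect_true(all(abs(rowMeans(vals) - truth) < 4 * pmax(se, 1e-9)))
  # variance of the k-replay average shrinks like 1/k
  m10 <- replicate(200, rowMeans(matrix(vals[, sample(1500, 10)], nrow = 2)))
  expect_lt(stats::var(m10[1, ]), stats::var(vals[1, ]) / 5)
})

test_that("backward Q backups match hand-computed Bellman updates", {
  set.seed(36)
  w <- sample_gridworld(5, 5, 0, reward = c(0, 0))
  tr <- tibble::tibble(step = 0:1, x = c(0, 1), y = c(0, 0), action = c(NA, "east"))
  Q <- q_backup_replay(q_table(w), w, tr)
  # single backup adjacent to reward: Q = alpha * r = 0.8 on the west action
  expect_equal(unname(Q[0 * 5 + 1 + 1, ]), c(0, 0, 0, 0.8), tolerance = 1e-12)
  expect_equal(sum(Q != 0), 1)
  # gamma = 0: values never propagate beyond one step from reward
  tr2 <- tibble::tibble(
    step = 0:2, x = c(0, 1, 2), y = c(0, 0, 0),
    action = c(NA, "east", "east")
  )
  Q0 <- q_table(w)
  for (i in 1:50) Q0 <- q_backup_replay(Q0, w, tr2, gamma = 0)
  vals <- matrix(Q0, 25, 4)
  cell <- function(x, y) y * 5 + x + 1
  expect_gt(max(Q0[cell(1, 0), ]), 0)
  expect_equal(max(Q0[cell(2, 0), ]), 0)
})

test_that("repeated reverse-optimal replays converge to the gamma^d profile", {
  set.seed(37)
  w <- sample_gridworld(6, 2, 0, reward = c(0, 0))
  Q <- q_table(w)
  for (i in 1:300) {
    tr <- sample_replay_trajectory(w, mode = "reverse_optimal")
    Q <- q_backup_replay(Q, w, tr, gamma = 0.7, alpha = 0.8)
  }
  pol <- optimal_policy(w)
  for (i in seq_len(nrow(pol))) {
    if (pol$dist[i] == 0) next
    v <- max(Q[pol$y[i] * 6 + pol$x[i] + 1, ])
    expect_equal(v, 0.7^(pol$dist[i] - 1), tolerance = 0.02)
  }
})

test_that("Q backups depend on replay order but memory content does not", {
  set.seed(38)
  w <- sample_gridworld(3, 2, 0, reward = c(0, 0))
  fwd <- tibble::tibble(
    step = 0:2, x = c(0, 1, 2), y = c(0, 0, 0),
    action = c(NA, "east", "east")
  )
  # same state set replayed in two different orders
  back <- tibble::tibble(
    step = 0:3, x = c(0, 1, 2, 1), y = c(0, 0, 0, 0),
    action = c(NA, "east", "east", "west")
  )
  q1 <- q_backup_replay(q_table(w), w, fwd)
  q2 <- q_backup_replay(q_table(w), w, back)
  expect_false(isTRUE(all.equal(q1, q2)))
  m1 <- kv_memory("discrete")
  m2 <- kv_memory("discrete")
  constructive_replay(m1, w, fwd, e_pi = 0)
  constructive_replay(m2, w, back, e_pi = 0)
  # noiseless final memory is a function of the visited-state set only
  latest <- function(m) {
    tb <- memory_tbl(m)
    keep <- !duplicated(tb[, c("key_x", "key_y")], fromLast = TRUE)
    tb <- tb[keep, c("key_x", "key_y", "dx", "dy")]
    tb[order(tb$key_x, tb$key_y), ]
  }
  expect_equal(latest(m1), latest(m2), ignore_attr = TRUE)
})

test_that("the visit-efficiency contrast reproduces the one-shot property", {
  set.seed(39)
  cv <- replay_visit_curve(
    n_worlds = 4, agent = "memory", mode = "random",
    n_visits = 5, max_replays = 60
  )
  expect_equal(cv$success[cv$visit == 1], 1.0)
  set.seed(39)
  cq <- replay_visit_curve(
    n_worlds = 4, agent = "q", mode = "reverse_optimal",
    n_visits = 5, max_replays = 60
  )
  expect_equal(cq$success[cq$visit == 1], 1.0, tolerance = 0.01)
})
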