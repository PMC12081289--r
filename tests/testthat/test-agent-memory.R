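# Key-value memory, noisy path integration and belief fusion.

test_that("object discovery initialises the zero-offset relation in range only", {
  mem <- kv_memory("discrete")
  expect_error(discover_object(mem, c(0, 0), c(3, 0)), "out of range")
  off <- discover_object(mem, c(1, 0), c(2, 0))
  tb <- memory_tbl(mem)
  expect_equal(nrow(tb), 1)
  expect_equal(c(tb$dx, tb$dy), c(1, 0))
  # repeated visits do not re-initialise a tracked object
  expect_null(discover_object(mem, c(2, 1), c(2, 0)))
  expect_equal(nrow(memory_tbl(mem)), 1)
  cm <- kv_memory("continuous")
  expect_error(discover_object(cm, c(0, 0), c(0.06, 0)), "out of range")
  discover_object(cm, c(0, 0), c(0.04, 0))
  expect_equal(nrow(memory_tbl(cm)), 1)
})

test_that("discrete path integration spreads e_pi mass over neighbour relations", {
  # reward one step east; agent goes north -> reward now to the southeast
  p <- path_integrate_discrete(c(1, 0), "north", e_pi = 0.1)
  mode <- p[which.max(p$prob), ]
  expect_equal(c(mode$dx, mode$dy), c(1, -1))
  expect_equal(mode$prob, 0.9)
  expect_equal(sum(p$prob), 1)
  p0 <- path_integrate_discrete(c(1, 0), "north", e_pi = 0)
  expect_equal(nrow(p0), 1)
  # Monte-Carlo frequency oracle at e_pi = 0.2
  set.seed(11)
  draws <- replicate(6000, sample_relation(path_integrate_discrete(c(2, 1), "east", 0.2)))
  correct <- mean(draws[1, ] == 1 & draws[2, ] == 1)
  expect_lt(abs(correct - 0.8), 0.02)  # 3 s.e. at this n is 0.016
})

test_that("continuous path integration matches its closed-form step moments", {
  expect_equal(
    path_integrate_continuous(c(0.3, 0.1), c(0.05, 0)),
    c(0.25, 0.1)
  )
  set.seed(12)
  step <- c(0.04, 0.03)
  draws <- replicate(1e5, c(0, 0) - path_integrate_continuous(
    c(0, 0), step,
    dir_sd = 0.1, step_sd = 0.01
  ))
  mom <- pi_step_moments(step, dir_sd = 0.1, step_sd = 0.01)
  se <- sqrt(mom$var / 1e5)
  expect_true(all(abs(rowMeans(draws) - mom$mean) < 4 * se))
  expect_equal(apply(draws, 1, var), mom$var, tolerance = 0.05)
})

test_that("retrieval returns count-weighted / softmax-weighted stored values", {
  mem <- kv_memory("discrete")
  memory_encode(mem, c(1, 1), c(2, 0))
  memory_encode(mem, c(1, 1), c(2, 0))
  p <- memory_retrieve(mem, c(1, 1))
  expect_equal(nrow(p), 1)
  expect_equal(p$prob, 1)
  expect_true(is_no_memory(memory_retrieve(mem, c(0, 0))))
  expect_equal(memory_reads(mem), 2)
  # continuous softmax over cosine similarities, 3 hand-placed memories
  cm <- kv_memory("continuous", cutoff = 0.05)
  keys <- list(c(0.10, 0.10), c(0.13, 0.11), c(0.09, 0.13))
  vals <- list(c(1, 0), c(0, 1), c(0.5, 0.5))
  for (i in 1:3) memory_encode(cm, keys[[i]], vals[[i]])
  memory_encode(cm, c(0.5, 0.5), c(9, 9)) # outside the 5 cm cutoff
  q <- c(0.11, 0.11)
  ret <- memory_retrieve(cm, q)
  cs <- vapply(keys, function(k) sum(k * q) / sqrt(sum(k^2) * sum(q^2)), numeric(1))
  w_oracle <- exp(cs - max(cs))
  w_oracle <- w_oracle / sum(w_oracle)
  expect_equal(ret$weights, w_oracle, tolerance = 1e-12)
  expect_equal(ret$s_m, colSums(do.call(rbind, vals) * w_oracle), tolerance = 1e-12)
})

test_that("fusion samples the stated mixture and re-encodes the result", {
  mem <- kv_memory("discrete")
  memory_encode(mem, c(3, 3), c(1, 1))
  p_pi <- path_integrate_discrete(c(2, 1), "north", 0)
  s <- fuse_and_encode(p_pi, memory_retrieve(mem, c(3, 3)), w = 1, mem, c(3, 3))
  expect_equal(s, c(2, 0)) # w = 1: pure path integration
  s0 <- fuse_and_encode(p_pi, memory_retrieve(mem, c(3, 3)), w = 0, mem, c(3, 3))
  expect_equal(s0, c(1, 1)) # w = 0 with point-mass memory
  # encoding then retrieving at the same key returns the encoded value
  mem2 <- kv_memory("discrete")
  memory_encode(mem2, c(5, 2), c(-1, 4))
  r <- memory_retrieve(mem2, c(5, 2))
  expect_equal(c(r$dx, r$dy), c(-1, 4))
  # mixture frequencies over many draws
  mem3 <- kv_memory("discrete")
  memory_encode(mem3, c(0, 0), c(9, 9))
  p_noisy <- path_integrate_discrete(c(1, 0), "north", 0.2)
  set.seed(13)
  draws <- replicate(3000, {
    m <- kv_memory("discrete")
    memory_encode(m, c(0, 0), c(9, 9))
    fuse_and_encode(p_noisy, memory_retrieve(m, c(0, 0)), 0.5, m, c(0, 0))
  })
  freq_mem <- mean(draws[1, ] == 9)
  expect_lt(abs(freq_mem - 0.5), 0.03)
  freq_mode <- mean(draws[1, ] == 1 & draws[2, ] == -1)
  expect_lt(abs(freq_mode - 0.5 * 0.8), 0.03)
  expect_error(
    fuse_and_encode(NULL, memory_retrieve(mem3, c(5, 5)), 0.5, mem3, c(0, 0)),
    "empty"
  )
})

test_that("noiseless tracking recovers the exact latent map everywhere", {
  set.seed(14)
  w <- sample_gridworld(5, 5, 0, reward = c(2, 2))
  offset <- c(w$reward[1] - 2, w$reward[2] - 2)
  loc <- c(2, 2)
  seen <- matrix(FALSE, 5, 5)
  for (k in 1:400) {
    a <- sample.int(4, 1)
    nxt <- transition(w, loc, a)
    if (!all(nxt == loc)) {
      offset <- sample_relation(path_integrate_discrete(offset, a, 0))
      loc <- nxt
    }
    expect_equal(offset, w$reward - loc) # exact latent map at every visit
    seen[loc[1] + 1, loc[2] + 1] <- TRUE
  }
  expect_true(all(seen))
})

test_that("memory-assisted tracking beats pure path integration on average", {
  set.seed(15)
  err <- function(agent) {
    mean(replicate(12, {
      w <- sample_gridworld(7, 7, 0, reward = c(3, 3))
      mem <- kv_memory("discrete")
      loc <- c(3, 3)
      belief <- c(0, 0)
      memory_encode(mem, loc, belief)
      e <- numeric(0)
      for (k in 1:30) {
        a <- sample.int(4, 1)
        nxt <- transition(w, loc, a)
        if (!all(nxt == loc)) {
          p_pi <- path_integrate_discrete(belief, a, 0.25)
          belief <- if (agent == "memory") {
            fuse_and_encode(p_pi, memory_retrieve(mem, nxt), 0.5, mem, nxt)
          } else {
            sample_relation(p_pi)
          }
          loc <- nxt
        }
        e <- c(e, sum(abs(belief - (w$reward - loc))))
      }
      mean(e)
    }))
  }
  expect_lt(err("memory"), err("pi"))
})
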