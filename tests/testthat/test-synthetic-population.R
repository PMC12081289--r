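# Entorhinal/hippocampal population generator and the replay-session
# simulator.

small_pop <- function(seed = 40) {
  set.seed(seed)
  ent <- build_entorhinal_populations(
    arena_cm = 120, home_day1 = c(40, 40), home_day2 = c(80, 80),
    n_grid = 3, n_ovc = 4, n_sensory = 5, grid_spacing = 60,
    ovc_dist_range = c(0, 60)
  )
  list(ent = ent, pop = build_conjunctive_population(ent))
}

test_that("population classes have the stated counts and exact 20 Hz maxima", {
  set.seed(41)
  ent <- build_entorhinal_populations(arena_cm = 120)
  expect_equal(dim(ent$grid)[3], 10)
  expect_equal(dim(ent$ovc_day1)[3], 20)
  expect_equal(dim(ent$sensory)[3], 40)
  expect_equal(max(ent$grid), 20, tolerance = 1e-12)
  expect_equal(max(ent$ovc_day1), 20, tolerance = 1e-12)
  expect_equal(max(ent$sensory), 20, tolerance = 1e-12)
  pop <- build_conjunctive_population(ent)
  expect_equal(sum(pop$cells$class == "landmark"), 200)
  expect_equal(sum(pop$cells$class == "place"), 400)
  expect_equal(nrow(pop$cells), 600)
  expect_equal(max(pop$day1[, , 1:200]), 20, tolerance = 1e-12)
  expect_equal(max(pop$day1[, , 201:600]), 20, tolerance = 1e-12)
})

test_that("grid-map autocorrelation peaks at the lattice spacing", {
  set.seed(42)
  ent <- build_entorhinal_populations(arena_cm = 300, grid_spacing = 120)
  M <- ent$grid[, , 1]
  n <- nrow(M)
  pad <- 2^ceiling(log2(2 * n))
  Z <- matrix(0, pad, pad)
  Z[1:n, 1:n] <- M - mean(M)
  F <- stats::fft(Z)
  ac <- Re(stats::fft(F * Conj(F), inverse = TRUE))
  shift <- function(i) ifelse(i <= pad / 2, i - 1, i - 1 - pad)
  lagx <- outer(shift(seq_len(pad)), rep(1, pad)) * ent$bin_cm
  lagy <- t(lagx)
  rr <- sqrt(lagx^2 + lagy^2)
  # nearest-neighbour autocorrelation ring should sit near 120 cm
  ring <- ac[rr > 80 & rr < 160]
  peak_r <- rr[rr > 80 & rr < 160][which.max(ring)]
  expect_lt(abs(peak_r - 120), 15)
})

test_that("day-2 object-vector maps are day-1 maps translated with the home well", {
  sp <- small_pop()
  ent <- sp$ent
  shift_bins <- (ent$home_day2 - ent$home_day1) / ent$bin_cm # 20, 20
  n <- dim(ent$ovc_day1)[1]
  src <- seq_len(n - shift_bins[1])
  for (c_i in c(1, 4)) {
    a <- ent$ovc_day1[src, src, c_i]
    b <- ent$ovc_day2[src + shift_bins[1], src + shift_bins[2], c_i]
    expect_lt(max(abs(a - b)), 1e-9)
  }
})

test_that("conjunctive maps equal parent products up to one class scale factor", {
  sp <- small_pop()
  ent <- sp$ent
  pop <- sp$pop
  n_grid <- dim(ent$grid)[3]
  # recomputation oracle over all landmark cells
  prods <- array(0, dim = dim(pop$day1)[1:2])
  k <- 0
  raw <- list()
  for (j in seq_len(dim(ent$ovc_day1)[3])) {
    for (i in seq_len(n_grid)) {
      k <- k + 1
      raw[[k]] <- ent$grid[, , i] * ent$ovc_day1[, , j]
    }
  }
  scale <- 20 / max(unlist(lapply(raw, max)))
  for (k in seq_along(raw)) {
    expect_equal(pop$day1[, , k], raw[[k]] * scale, tolerance = 1e-9)
  }
})

test_that("replay sessions respect exclusion zones and the landmark first-spike rule", {
  sp <- small_pop()
  set.seed(43)
  ses <- simulate_replay_session(sp$pop, n_replays = 40, t_range = c(10, 1200))
  tr <- dplyr::left_join(ses$trajectories, ses$events, by = "replay_id")
  d_home <- sqrt((tr$x - 40)^2 + (tr$y - 40)^2)
  expect_true(all(d_home[tr$type == "elsewhere"] > 30))
  expect_true(all(tr$x >= 0 & tr$x <= 120 & tr$y >= 0 & tr$y <= 120))
  expect_equal(ses$events$type[1:8], rep(c("home", "elsewhere", "elsewhere", "elsewhere"), 2))
  # landmark cells never spike elsewhere before their first home-replay spike
  lmk <- ses$spikes[ses$spikes$class == "landmark", ]
  if (nrow(lmk) > 0) {
    for (c_i in unique(lmk$cell)) {
      own <- lmk[lmk$cell == c_i, ]
      types <- ses$events$type[match(own$replay_id, ses$events$replay_id)]
      expect_equal(types[which.min(own$time)], "home")
      expect_true(all(own$time >= ses$t0[c_i]))
    }
  }
  set.seed(43)
  ses2 <- simulate_replay_session(sp$pop, n_replays = 40, t_range = c(10, 1200))
  expect_identical(ses$spikes, ses2$spikes) # seeded reproducibility
})

test_that("ground-truth change maps follow the t0/t1 decay rule", {
  sp <- small_pop()
  set.seed(44)
  ses <- simulate_replay_session(sp$pop, n_replays = 40, t_range = c(10, 1200))
  lmk_cells <- which(!is.na(ses$t0))
  if (length(lmk_cells) > 0) {
    c_i <- lmk_cells[1]
    ev0 <- ses$events$replay_id[ses$events$t_event == ses$t0[c_i]]
    # first home replay: full new landmark peak (t1 = t0), noiseless check
    ch <- session_change_map(ses, sp$pop, c_i, ev0, noise_hz = 0)
    expect_equal(ch, sp$pop$day1[, , c_i], tolerance = 1e-12)
    later <- ses$events$replay_id[ses$events$t_event > ses$t0[c_i]][1]
    t1 <- ses$events$t_event[ses$events$replay_id == later]
    ch2 <- session_change_map(ses, sp$pop, c_i, later, noise_hz = 0)
    expect_equal(ch2, sp$pop$day1[, , c_i] * ses$t0[c_i] / t1, tolerance = 1e-12)
  }
  # place-cell change maps are noise only (zero in the noiseless limit)
  place <- which(sp$pop$cells$class == "place")[1]
  ch_p <- session_change_map(ses, sp$pop, place, 1, noise_hz = 0)
  expect_true(all(ch_p == 0))
  ch_pn <- session_change_map(ses, sp$pop, place, 1, noise_hz = 0.5)
  expect_gt(stats::sd(ch_pn), 0)
})

test_that("day-2 change maps are sign-symmetric for landmarks, noise for place cells", {
  set.seed(46)
  # move the home well by one grid-lattice vector so the (static) grid maps
  # take the same values at the displaced object-vector fields
  v1 <- 60 * c(cos(6 * pi / 180), sin(6 * pi / 180))
  ent <- build_entorhinal_populations(
    arena_cm = 160, home_day1 = c(40, 50), home_day2 = c(40, 50) + v1,
    n_grid = 3, n_ovc = 6, n_sensory = 4, grid_spacing = 60,
    ovc_dist_range = c(0, 25) # fields stay inside the arena on both days
  )
  pop <- build_conjunctive_population(ent)
  ch <- day2_change_maps(pop, noise_hz = 0)
  lmk <- which(pop$cells$class == "landmark")
  peaks1 <- apply(pop$day1[, , lmk], 3, max)
  peaks2 <- apply(pop$day2[, , lmk], 3, max)
  good <- lmk[which.max(pmin(peaks1, peaks2))]
  expect_gt(pmin(peaks1, peaks2)[which.max(pmin(peaks1, peaks2))], 1)
  expect_equal(max(ch[, , good]), -min(ch[, , good]), tolerance = 0.05)
  place <- which(pop$cells$class == "place")[1]
  expect_true(all(ch[, , place] == 0))
})

test_that("foraging tracks stay in the arena and drive plausible Poisson spiking", {
  set.seed(45)
  track <- generate_foraging_track(100, duration = 60, dt = 0.1)
  expect_true(all(track$x >= 0 & track$x <= 100 & track$y >= 0 & track$y <= 100))
  maps <- array(5, dim = c(50, 50, 3)) # homogeneous 5 Hz cells
  sp <- simulate_behavior_spikes(maps, track, bin_cm = 2)
  expected <- 5 * 60 * 3
  expect_lt(abs(nrow(sp) - expected), 4 * sqrt(expected))
})
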