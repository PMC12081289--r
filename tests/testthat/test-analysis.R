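# Rate maps, population rate, event segmentation, Bayesian decoding,
# spike-location interpolation, change maps and the summary statistics.

test_that("rate maps are occupancy-normalised, speed-filtered and ratio-invariant", {
  set.seed(50)
  # uniform random occupancy with all spikes confined to one location
  n_t <- 4000
  track <- tibble::tibble(
    time = (1:n_t) * 0.1,
    x = runif(n_t, 0, 100), y = runif(n_t, 0, 100)
  )
  spikes <- tibble::tibble(cell = 1, time = track$time[track$x > 48 & track$x < 52 &
    track$y > 48 & track$y < 52] + 0.01)
  rm1 <- compute_ratemap(spikes, track, 100, occupancy_floor = 0.05)
  peak <- which(rm1$rate == max(rm1$rate, na.rm = TRUE), arr.ind = TRUE)
  expect_lt(max(abs(peak - 25)), 3) # smoothed peak at the spike bin
  # doubling both occupancy and spikes leaves the map unchanged
  track2 <- dplyr::bind_rows(track, dplyr::mutate(track, time = time + n_t * 0.1 + 1))
  spikes2 <- dplyr::bind_rows(spikes, dplyr::mutate(spikes, time = time + n_t * 0.1 + 1))
  rm2 <- compute_ratemap(spikes2, track2, 100, occupancy_floor = 0.05)
  expect_equal(rm2$rate, rm1$rate, tolerance = 0.2)
  expect_error(
    compute_ratemap(spikes, track[1:5, ], 100, interval = c(1e6, 2e6)),
    "empty filtered occupancy"
  )
})

test_that("a homogeneous Poisson cell decodes to its constant rate", {
  set.seed(51)
  n_t <- 30000
  track <- generate_foraging_track(100, duration = 3000, dt = 0.1, speed_cm_s = 20)
  maps <- array(4, dim = c(50, 50, 1))
  spikes <- simulate_behavior_spikes(maps, track, 2)
  rm <- compute_ratemap(spikes, track, 100, occupancy_floor = 0.05)
  m <- mean(rm$rate, na.rm = TRUE)
  expect_lt(abs(m - 4), 3 * 4 / sqrt(nrow(spikes))) # +/- 3 s.e. of the mean rate
})

test_that("population rate is a mass-preserving smoothed histogram", {
  pr0 <- population_rate(numeric(0), t_range = c(0, 1))
  expect_true(all(pr0$rate == 0))
  pr1 <- population_rate(0.5, t_range = c(0, 1))
  expect_equal(sum(pr1$rate), 1, tolerance = 1e-6) # one spike, one count of mass
  expect_equal(pr1$time[which.max(pr1$rate)], 0.5, tolerance = 2e-3)
  # direct convolution oracle on random spikes
  set.seed(52)
  sp <- runif(40, 0.2, 0.8)
  pr <- population_rate(sp, t_range = c(0, 1))
  k <- exp(-(-40:40)^2 / (2 * 10^2))
  k <- k / sum(k)
  breaks <- seq(0, 1.001, by = 0.001)
  sp_bin <- .bincode(sp, breaks, right = TRUE, include.lowest = TRUE)
  oracle <- vapply(seq_along(pr$time), function(i) {
    lag <- i - sp_bin
    sum(k[lag[abs(lag) <= 40] + 41])
  }, numeric(1))
  expect_equal(pr$rate, oracle, tolerance = 1e-6)
})

test_that("replay events bracket their ripple by the pre-ripple mean rule", {
  # constructed population-rate bump around a ripple at t = 1.0
  tt <- seq(0, 2, by = 0.001)
  rate <- 0.2 + ifelse(abs(tt - 1) < 0.05, 2, 0)
  pr <- tibble::tibble(time = tt, rate = rate)
  ev <- detect_replay_events(pr, 1.0)
  expect_equal(nrow(ev), 1)
  expect_lt(ev$start, 1)
  expect_gt(ev$end, 1)
  expect_equal(ev$start, 0.949, tolerance = 2e-3)
  expect_equal(ev$end, 1.051, tolerance = 2e-3)
  # two distant ripples give two disjoint events
  rate2 <- 0.2 + ifelse(abs(tt - 0.5) < 0.03, 2, 0) + ifelse(abs(tt - 1.5) < 0.03, 2, 0)
  ev2 <- detect_replay_events(tibble::tibble(time = tt, rate = rate2), c(0.5, 1.5))
  expect_equal(nrow(ev2), 2)
  expect_lt(ev2$end[1], ev2$start[2])
  # a ripple in a silent region is rejected
  ev3 <- detect_replay_events(tibble::tibble(time = tt, rate = 0 * tt), 1.0)
  expect_equal(nrow(ev3), 0)
})

test_that("the Bayesian posterior equals the direct formula on toy problems", {
  # uniform maps give a uniform posterior
  dec_u <- make_decoder(array(3, dim = c(4, 4, 2)), bin_cm = 2)
  post_u <- bayesian_decode(c(1L, 2L), dec_u, tau = 0.02)
  expect_equal(as.numeric(post_u), rep(1 / 16, 16), tolerance = 1e-12)
  expect_equal(sum(post_u), 1, tolerance = 1e-9)
  # one spike from a single-bin field peaks the posterior at that bin
  maps <- array(0.01, dim = c(4, 4, 2))
  maps[2, 3, 1] <- 30
  dec <- make_decoder(maps, bin_cm = 2)
  post <- bayesian_decode(c(1L, 0L), dec, tau = 0.02)
  expect_equal(which(post == max(post), arr.ind = TRUE)[1, ], c(row = 2, col = 3))
  # 5-bin toy problem against direct evaluation of F / sum(F)
  f1 <- c(0.5, 2, 8, 2, 0.5)
  f2 <- c(6, 3, 1, 0.5, 0.2)
  toy <- array(c(f1, f2), dim = c(5, 1, 2))
  dtoy <- make_decoder(toy, bin_cm = 2)
  counts <- c(2L, 1L)
  tau <- 0.02
  F_direct <- f1^2 * f2 * exp(-tau * (f1 + f2))
  expect_equal(
    as.numeric(bayesian_decode(counts, dtoy, tau)),
    F_direct / sum(F_direct),
    tolerance = 1e-9
  )
})

test_that("leave-one-out decoding localises spikes on a known trajectory", {
  set.seed(53)
  tp <- tiling_population()
  dec <- make_decoder(tp$maps, tp$bin_cm)
  # a straight replay trajectory with dense Poisson spikes
  steps <- 20
  path <- tibble::tibble(
    x = seq(15, 85, length.out = steps),
    y = seq(20, 80, length.out = steps),
    t = 100 + (1:steps) * 0.005
  )
  spikes <- purrr::pmap(path, function(x, y, t) {
    ib <- ceiling(x / 2)
    jb <- ceiling(y / 2)
    counts <- rpois(dim(tp$maps)[3], tp$maps[ib, jb, ] * 25 * 0.005)
    hit <- which(counts > 0)
    if (!length(hit)) {
      return(NULL)
    }
    tibble::tibble(cell = hit, time = t + runif(length(hit), 0, 0.005), x = x, y = y)
  }) |> purrr::list_rbind()
  t0 <- 100.005
  t1 <- 100.005 + steps * 0.005
  traj_full <- decode_event_trajectory(spikes, dec, t0, t1)
  expect_equal(diff(traj_full$t), rep(0.005, nrow(traj_full) - 1), tolerance = 1e-9)
  # excluding a cell that never spiked leaves the decode unchanged
  silent <- setdiff(seq_len(dim(tp$maps)[3]), unique(spikes$cell))[1]
  traj_lo <- decode_event_trajectory(spikes, dec, t0, t1, exclude = silent)
  expect_equal(traj_lo, traj_full)
  # median distance between decoded and true spike locations is small
  errs <- vapply(unique(spikes$cell), function(c_i) {
    tr <- decode_event_trajectory(spikes, dec, t0, t1, exclude = c_i)
    own <- spikes[spikes$cell == c_i, ]
    mean(vapply(seq_len(nrow(own)), function(k) {
      loc <- interpolate_spike_location(own$time[k], tr)
      sqrt((loc[1] - own$x[k])^2 + (loc[2] - own$y[k])^2)
    }, numeric(1)))
  }, numeric(1))
  expect_lt(median(errs), 10)
  expect_error(
    decode_event_trajectory(spikes, dec, t0, t0 + 0.01),
    "shorter than one decoding window"
  )
})

test_that("spike locations interpolate linearly between window centres", {
  traj <- tibble::tibble(t = c(0.0, 0.005, 0.010), x = c(10, 20, 40), y = c(5, 5, 25))
  expect_equal(as.numeric(interpolate_spike_location(0.005, traj)), c(20, 5))
  expect_equal(as.numeric(interpolate_spike_location(0.0075, traj)), c(30, 15))
  expect_equal(as.numeric(interpolate_spike_location(0.001, traj)), c(12, 5))
  out <- interpolate_spike_location(0.02, traj)
  expect_equal(as.numeric(out), c(40, 25)) # clamps to the nearest endpoint
  expect_true(attr(out, "extrapolated"))
})

test_that("change-map alignment translates values exactly onto the origin", {
  M <- matrix(0, 10, 10)
  M[7, 4] <- 5
  A <- align_change_map(M, c(13, 7), bin_cm = 2) # spike in bin (7, 4)
  ctr <- 10 # canvas centre of a 19x19 canvas
  expect_equal(A[ctr, ctr], 5)
  expect_equal(sum(A, na.rm = TRUE), 5) # translation preserves values
  # identical before/after maps give an all-zero change
  expect_true(all(ratemap_change(M, M) == 0))
  # several spikes of one cell average their aligned maps
  A2 <- align_change_map(M, rbind(c(13, 7), c(13, 9)), bin_cm = 2)
  expect_equal(A2[ctr, ctr], 2.5)
  expect_equal(A2[ctr, ctr - 1], 2.5)
})

test_that("replay events classify as home, elsewhere or excluded per the criteria", {
  home <- c(50, 50)
  # passes by home while the animal sits at home, extending far out
  traj_home <- tibble::tibble(t = 1:10, x = seq(52, 150, length.out = 10), y = 50)
  expect_equal(classify_replay_event(traj_home, home, c(52, 50)), "home")
  # animal far from home, trajectory stays far from home
  traj_far <- tibble::tibble(t = 1:10, x = seq(120, 190, length.out = 10), y = 120)
  expect_equal(classify_replay_event(traj_far, home, c(150, 60)), "elsewhere")
  # passes 20 cm from home while the animal sits elsewhere: excluded both ways
  traj_mid <- tibble::tibble(t = 1:10, x = seq(70, 150, length.out = 10), y = 50)
  expect_equal(classify_replay_event(traj_mid, home, c(150, 120)), "excluded")
  # mean decoded position only 10 cm from the animal: excluded
  traj_near <- tibble::tibble(t = 1:5, x = 52:56, y = rep(50, 5))
  expect_equal(classify_replay_event(traj_near, home, c(50, 50)), "excluded")
})

test_that("matched controls maximise the event-time histogram correlation", {
  set.seed(54)
  home_t <- runif(20, 0, 1000)
  # elsewhere times drawn from the same distribution: near-perfect match
  else_t <- runif(200, 0, 1000)
  idx <- match_controls(home_t, else_t, n_draws = 300)
  expect_length(idx, 20)
  expect_gt(attr(idx, "correlation"), 0.8)
  set.seed(55)
  i1 <- match_controls(home_t, else_t, n_draws = 100)
  set.seed(55)
  i2 <- match_controls(home_t, else_t, n_draws = 100)
  expect_identical(i1, i2)
  # strongly skewed elsewhere times: matched beats a plain random subsample
  else_skew <- c(runif(150, 900, 1000), runif(50, 0, 1000))
  hist5 <- function(tms) {
    breaks <- seq(min(c(home_t, else_skew)) - 1e-9, max(c(home_t, else_skew)) + 1e-9,
      length.out = 6
    )
    tabulate(findInterval(tms, breaks, all.inside = TRUE), 5)
  }
  set.seed(56)
  idx_m <- match_controls(home_t, else_skew, n_draws = 500)
  r_matched <- cor(hist5(home_t), hist5(else_skew[idx_m]))
  r_random <- mean(replicate(50, cor(hist5(home_t), hist5(sample(else_skew, 20)))))
  expect_gt(r_matched, r_random)
  expect_error(match_controls(home_t, else_t[1:5]), "fewer elsewhere")
})

test_that("change summaries report origin ROI and radial spokes correctly", {
  z <- matrix(0, 21, 21)
  s <- summarize_changes(list(z), bin_cm = 2, n_steps = 5)
  expect_equal(s$roi$value, 0)
  expect_true(all(s$profile$value == 0, na.rm = TRUE))
  d <- matrix(0, 21, 21)
  d[11, 11] <- 10 # delta peak at the origin
  d <- gaussian_smooth(d, 2, renormalize = FALSE)
  s2 <- summarize_changes(list(d), bin_cm = 2, n_steps = 8)
  expect_gt(s2$roi$value, 0)
  prof <- s2$profile$value
  expect_true(all(diff(prof) <= 1e-12)) # decays with radius
  # spoke sampling equals a nearest-bin lookup oracle along one ray
  set.seed(57)
  M <- matrix(rnorm(21 * 21), 21, 21)
  s3 <- summarize_changes(list(M), bin_cm = 2, n_angles = 1, n_steps = 4)
  oracle <- vapply(1:4, function(k) M[11 + k, 11], numeric(1)) # angle 0 ray
  expect_equal(s3$profile$value, oracle)
})

test_that("home-shift correlations detect generalising change maps", {
  n <- 40
  bump <- function(cx, cy) {
    M <- matrix(0, n, n)
    M[cx, cy] <- 1
    gaussian_smooth(M, 2, renormalize = FALSE)
  }
  home_new <- c(20, 20)
  home_prev <- c(60, 40)
  # +field south of the new home, -field south of the previous home
  change <- bump(10, 6) - bump(30, 16)
  r <- home_shift_correlation(change, home_new, home_prev, bin_cm = 2)
  expect_lt(r, -0.3)
  expect_equal(home_shift_correlation(change, home_new, home_new, 2), 1)
  set.seed(58)
  noise <- matrix(rnorm(n * n), n, n)
  expect_lt(abs(home_shift_correlation(noise, home_new, home_prev, 2)), 0.2)
  expect_error(
    home_shift_correlation(change, c(1e5, 1e5), home_prev, 2),
    "insufficient overlap"
  )
})

test_that("replay-change overlap separates coincident from disjoint spikes", {
  n <- 40
  change <- matrix(0, n, n)
  change[10, 10] <- 4
  change <- gaussian_smooth(change, 2, renormalize = FALSE)
  expect_equal(replay_change_overlap(change, NULL, 2)$overlap, 0)
  co <- replay_change_overlap(change, rbind(c(19, 19), c(21, 21)), 2, n_replays = 2)
  dis <- replay_change_overlap(change, rbind(c(70, 70), c(72, 72)), 2, n_replays = 2)
  expect_gt(co$overlap, dis$overlap)
  expect_gt(co$location_correlation, dis$location_correlation)
  expect_equal(co$n_replays, 2)
  # brute-force oracle for the overlap value
  smap <- matrix(0, n, n)
  smap[10, 10] <- 2
  smap <- gaussian_smooth(smap, 2, renormalize = FALSE)
  expect_equal(
    replay_change_overlap(change, rbind(c(19, 19), c(19, 19)), 2)$overlap,
    mean(abs(change) * smap),
    tolerance = 1e-9
  )
})

test_that("nonlocal door spikes require nearness, stillness and non-fields", {
  n <- 50
  doors <- rbind(c(50, 50))
  # animal parked 2 cm from the door, barely moving
  track <- tibble::tibble(time = seq(0, 60, by = 0.1), x = 52, y = 50)
  track$x <- track$x + cumsum(rnorm(nrow(track), 0, 0.005))
  fields <- list(
    matrix(FALSE, n, n), # cell 1: no field here -> flagged
    {
      M <- matrix(FALSE, n, n)
      M[20:30, 20:30] <- TRUE # cell 2's field covers the door area
      M
    }
  )
  spikes <- tibble::tibble(cell = c(1, 2), time = c(10, 20))
  res <- nonlocal_door_spikes(spikes, track, doors, fields, bin_cm = 2)
  expect_true(res$spikes$nonlocal_door[1])
  expect_false(res$spikes$nonlocal_door[2]) # criterion 3: own field
  expect_equal(res$cells$replayed, c(1L, 0L))
  # a spike 12 cm from the door is not flagged (criterion 1)
  track_far <- dplyr::mutate(track, x = 62)
  res_far <- nonlocal_door_spikes(
    tibble::tibble(cell = 1, time = 10),
    track_far, doors, fields[1], 2
  )
  expect_false(any(res_far$spikes$nonlocal_door))
  expect_error(
    nonlocal_door_spikes(spikes, track, doors[0, , drop = FALSE], fields, 2),
    "no closed-door"
  )
})

test_that("replay indicator regression recovers a planted new-field effect", {
  set.seed(59)
  n_cells <- 80
  replayed <- rbinom(n_cells, 1, 0.4)
  new_field <- rbinom(n_cells, 1, 0.15 + 0.5 * replayed)
  mean_rate <- rgamma(n_cells, 2, 1)
  doors <- rbind(c(50, 50))
  track <- tibble::tibble(time = seq(0, 100, length.out = 1001), x = 52, y = 50)
  fields <- replicate(n_cells, matrix(FALSE, 50, 50), simplify = FALSE)
  # one door spike per replaying cell, none otherwise
  spikes <- tibble::tibble(
    cell = which(replayed == 1),
    time = seq(1, 99, length.out = sum(replayed))
  )
  res <- nonlocal_door_spikes(spikes, track, doors, fields, 2,
    cells = tibble::tibble(cell = 1:n_cells, new_field = new_field, mean_rate = mean_rate)
  )
  coef_replay <- res$regression[res$regression$term == "replayed", ]
  expect_gt(coef_replay$estimate, 0)
  expect_lt(coef_replay$p_one_tailed, 0.05)
})
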