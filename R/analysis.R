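# Replay-analysis pipeline: occupancy-normalised rate maps, population-rate
# replay-event segmentation around ripple times, memoryless Bayesian position
# decoding with leave-one-neuron-out spike-location interpolation,
# replay-spike-aligned change maps, home/elsewhere classification with
# time-matched controls, change summaries and generalization statistics.
#
# Inputs are plain columnar tables: spikes (cell, time), tracks
# (time, x, y in cm), ripple times (s). All maps use 2 cm bins by default.

track_speed <- function(track) {
  n <- nrow(track)
  dt <- diff(track$time)
  v <- sqrt(diff(track$x)^2 + diff(track$y)^2) / dt
  if (n == 2) {
    return(rep(v, 2))
  }
  c(v[1], (v[-1] + v[-(n - 1)]) / 2, v[n - 1]) # centred where possible
}

interp_track <- function(track, times) {
  tibble::tibble(
    x = stats::approx(track$time, track$x, times, rule = 2)$y,
    y = stats::approx(track$time, track$y, times, rule = 2)$y,
    speed = stats::approx(track$time, track_speed(track), times, rule = 2)$y
  )
}

#' Compute an occupancy-normalised rate map
#'
#' Discretises the arena into square bins, keeps only times when the animal
#' moves faster than `speed_min` (5 cm/s), smooths the spike-count and
#' occupancy maps with a Gaussian kernel (4 cm s.d., renormalised at the
#' arena edge) and divides the two. Bins whose smoothed occupancy falls
#' below `occupancy_floor` seconds are masked `NA`.
#'
#' @param spikes Tibble `cell, time` (or just `time`) for one cell.
#' @param track Tibble `time, x, y` in cm.
#' @param arena_cm Arena side (cm).
#' @param interval Optional `c(t0, t1)`; only data inside it are used.
#' @param bin_cm Bin side (cm).
#' @param smooth_cm Kernel s.d. (cm).
#' @param speed_min Speed filter (cm/s).
#' @param occupancy_floor Minimum smoothed occupancy (s).
#' @return A [ratemap()] with occupancy attached.
#' @export
compute_ratemap <- function(spikes, track, arena_cm, interval = NULL,
                            bin_cm = 2, smooth_cm = 4, speed_min = 5,
                            occupancy_floor = 0.2) {
  n <- as.integer(round(arena_cm / bin_cm))
  if (!is.null(interval)) {
    track <- track[track$time >= interval[1] & track$time <= interval[2], ]
    spikes <- spikes[spikes$time >= interval[1] & spikes$time <= interval[2], ]
  }
  if (nrow(track) < 2) stop("empty filtered occupancy")
  dt <- stats::median(diff(track$time))
  sp <- track_speed(track)
  keep <- sp > speed_min
  if (!any(keep)) stop("empty filtered occupancy")
  occ <- matrix(0, n, n)
  ib <- coord_to_bin(track$x[keep], bin_cm, n)
  jb <- coord_to_bin(track$y[keep], bin_cm, n)
  for (k in seq_along(ib)) occ[ib[k], jb[k]] <- occ[ib[k], jb[k]] + dt
  spk <- matrix(0, n, n)
  if (nrow(spikes) > 0) {
    at <- interp_track(track, spikes$time)
    sel <- at$speed > speed_min
    if (any(sel)) {
      si <- coord_to_bin(at$x[sel], bin_cm, n)
      sj <- coord_to_bin(at$y[sel], bin_cm, n)
      for (k in seq_along(si)) spk[si[k], sj[k]] <- spk[si[k], sj[k]] + 1
    }
  }
  socc <- gaussian_smooth(occ, smooth_cm / bin_cm)
  sspk <- gaussian_smooth(spk, smooth_cm / bin_cm)
  rate <- sspk / socc
  rate[socc < occupancy_floor] <- NA_real_
  ratemap(rate, bin_cm, c(0, 0), occupancy = socc)
}

#' Population firing rate around rest
#'
#' Histogram of all spikes emitted while the animal moves slower than
#' `speed_max` (5 cm/s) in 1 ms bins, smoothed with a 10 ms s.d. Gaussian
#' kernel. The kernel preserves spike mass: a single spike integrates to one
#' count across bins.
#'
#' @param spike_times Numeric vector of spike times (s), all cells pooled.
#' @param track Tibble `time, x, y`; used only for the speed filter. `NULL`
#'   skips the filter.
#' @param t_range Time span covered by the returned series.
#' @param bin_s Histogram bin (s).
#' @param smooth_s Kernel s.d. (s).
#' @param speed_max Speed ceiling (cm/s).
#' @return Tibble `time, rate` (counts per bin) at `bin_s` resolution.
#' @export
population_rate <- function(spike_times, track = NULL, t_range = NULL,
                            bin_s = 0.001, smooth_s = 0.010, speed_max = 5) {
  if (!is.null(track)) {
    sp <- interp_track(track, spike_times)$speed
    spike_times <- spike_times[sp < speed_max]
  }
  if (is.null(t_range)) {
    t_range <- if (length(spike_times)) range(spike_times) + c(-0.1, 0.1) else c(0, 1)
  }
  breaks <- seq(t_range[1], t_range[2] + bin_s, by = bin_s)
  counts <- graphics::hist(spike_times[spike_times >= t_range[1] & spike_times <= t_range[2]],
    breaks = breaks, plot = FALSE
  )$counts
  k <- gaussian_kernel_1d(smooth_s / bin_s)
  sm <- as.numeric(conv_1d_cols(matrix(counts, ncol = 1), k))
  tibble::tibble(time = breaks[-length(breaks)] + bin_s / 2, rate = sm)
}

#' Segment replay events around ripple times
#'
#' An event starts when the population rate exceeds its (nonzero) mean
#' before the ripple and ends when the rate drops below that mean after the
#' ripple. The mean is taken over the nonzero rate bins in a window of
#' `pre_window` seconds preceding the ripple; ripples falling in silent
#' regions (no nonzero pre-ripple rate) are rejected.
#'
#' @param pop_rate Tibble `time, rate` from [population_rate()].
#' @param ripple_times Ripple peak times (s).
#' @param pre_window Pre-ripple window for the mean (s).
#' @return Tibble `ripple, start, end`, one row per accepted ripple.
#' @export
detect_replay_events <- function(pop_rate, ripple_times, pre_window = 0.5) {
  purrr::map(ripple_times, function(tr) {
    pre <- pop_rate$rate[pop_rate$time >= tr - pre_window & pop_rate$time < tr]
    pre <- pre[pre > 0]
    if (length(pre) == 0) {
      return(NULL)
    }
    mu <- mean(pre)
    before <- which(pop_rate$time <= tr & pop_rate$rate <= mu)
    after <- which(pop_rate$time > tr & pop_rate$rate < mu)
    if (length(before) == 0 || length(after) == 0) {
      return(NULL)
    }
    start <- pop_rate$time[max(before)]
    end <- pop_rate$time[min(after)]
    if (start >= end) {
      return(NULL)
    }
    tibble::tibble(ripple = tr, start = start, end = end)
  }) |> purrr::list_rbind()
}

# ---- Bayesian decoding -----------------------------------------------------

#' Prepare a Bayesian decoder from a stack of rate maps
#'
#' Precomputes the log tuning curves and the summed population rate used by
#' the memoryless decoder. Rates are floored at `rate_floor` so the
#' log-likelihood stays finite where a map is zero; masked (`NA`) bins are
#' excluded from the posterior support.
#'
#' @param maps 3D array `nx x ny x n_cells` (Hz) or list of [ratemap()]s.
#' @param bin_cm Bin side (cm).
#' @param rate_floor Minimum rate (Hz) entering the likelihood.
#' @return A `bayes_decoder` object.
#' @export
make_decoder <- function(maps, bin_cm, rate_floor = 0.01) {
  if (is.list(maps) && !is.array(maps)) {
    bin_cm <- maps[[1]]$bin_size
    maps <- array(
      unlist(purrr::map(maps, "rate")),
      dim = c(dim(maps[[1]]$rate), length(maps))
    )
  }
  nx <- dim(maps)[1]
  ny <- dim(maps)[2]
  n_cells <- dim(maps)[3]
  flat <- matrix(maps, nrow = nx * ny, ncol = n_cells)
  valid <- rowSums(is.na(flat)) == 0
  flat <- pmax(flat, rate_floor)
  structure(
    list(
      log_flat = log(flat), flat = flat, sum_rate = rowSums(flat),
      valid = valid, nx = nx, ny = ny, bin_cm = bin_cm, n_cells = n_cells
    ),
    class = "bayes_decoder"
  )
}

#' Memoryless Bayesian position posterior for one decoding window
#'
#' Computes `p(pos | spikes) = F / sum(F)` with
#' `F = prod_i f_i(pos)^{n_i} * exp(-tau * sum_i f_i(pos))`, evaluated in
#' log space for stability, where `f_i` are the rate maps, `n_i` the
#' per-neuron spike counts in the window and `tau` the window width.
#'
#' @param counts Integer vector of spike counts, one per neuron; excluded
#'   neurons simply contribute a zero count and are dropped from both the
#'   product and the exponential via `exclude`.
#' @param decoder A [make_decoder()] object.
#' @param tau Window width (s).
#' @param exclude Optional neuron index excluded from the likelihood.
#' @return Matrix `nx x ny` of posterior probabilities summing to 1 over
#'   unmasked bins (`NA` at masked bins).
#' @export
bayesian_decode <- function(counts, decoder, tau = 0.02, exclude = NULL) {
  stopifnot(length(counts) == decoder$n_cells)
  sum_rate <- decoder$sum_rate
  if (!is.null(exclude)) {
    sum_rate <- sum_rate - decoder$flat[, exclude]
    counts[exclude] <- 0L
  }
  logf <- -tau * sum_rate
  act <- which(counts > 0)
  if (length(act) > 0) {
    logf <- logf + decoder$log_flat[, act, drop = FALSE] %*% counts[act]
  }
  logf[!decoder$valid] <- -Inf
  post <- exp(logf - logsumexp(logf))
  post[!decoder$valid] <- NA_real_
  matrix(post, decoder$nx, decoder$ny)
}

posterior_position <- function(post, bin_cm) {
  mx <- max(post, na.rm = TRUE)
  idx <- which(post >= mx - 1e-12, arr.ind = TRUE)
  # maximum a posteriori; exact ties resolved by the centroid of tied bins
  c(mean(idx[, 1]) - 0.5, mean(idx[, 2]) - 0.5) * bin_cm
}

#' Decode the trajectory of one replay event
#'
#' Slides a 20 ms decoding window through the event in 5 ms steps and
#' decodes each window with [bayesian_decode()], optionally excluding one
#' neuron (for leave-one-neuron-out spike localisation). The decoded
#' position per window is the posterior maximum (ties broken by the centroid
#' of the tied bins).
#'
#' @param spikes Tibble `cell, time` of the event's spikes.
#' @param decoder A [make_decoder()] object.
#' @param t_start,t_end Event boundaries (s).
#' @param window Window width (s).
#' @param step Window step (s).
#' @param exclude Neuron to leave out of the decoding.
#' @return Tibble `t, x, y` with strictly increasing window centres.
#' @export
decode_event_trajectory <- function(spikes, decoder, t_start, t_end,
                                    window = 0.02, step = 0.005,
                                    exclude = NULL) {
  if (t_end - t_start < window) stop("event shorter than one decoding window")
  centers <- seq(t_start + window / 2, t_end - window / 2 + 1e-12, by = step)
  pos <- matrix(NA_real_, length(centers), 2)
  for (w in seq_along(centers)) {
    inw <- spikes$time >= centers[w] - window / 2 & spikes$time < centers[w] + window / 2
    counts <- tabulate(spikes$cell[inw], nbins = decoder$n_cells)
    post <- bayesian_decode(counts, decoder, tau = window, exclude = exclude)
    pos[w, ] <- posterior_position(post, decoder$bin_cm)
  }
  tibble::tibble(t = centers, x = pos[, 1], y = pos[, 2])
}

#' Interpolate a spike's location along a decoded trajectory
#'
#' Finds where the spike time falls between decoding-window centres and
#' linearly interpolates the decoded positions of the bracketing windows.
#' Spikes outside the decoded span snap to the nearest endpoint and are
#' flagged via the `"extrapolated"` attribute.
#'
#' @param spike_time Spike time (s).
#' @param trajectory Tibble `t, x, y` from [decode_event_trajectory()].
#' @return Coordinate `c(x, y)` with attribute `extrapolated`.
#' @export
interpolate_spike_location <- function(spike_time, trajectory) {
  if (nrow(trajectory) == 1) { # event decoded into a single window
    out <- c(trajectory$x[1], trajectory$y[1])
    attr(out, "extrapolated") <- abs(spike_time - trajectory$t[1]) > 1e-12
    return(out)
  }
  out <- c(
    stats::approx(trajectory$t, trajectory$x, spike_time, rule = 2)$y,
    stats::approx(trajectory$t, trajectory$y, spike_time, rule = 2)$y
  )
  attr(out, "extrapolated") <- spike_time < min(trajectory$t) ||
    spike_time > max(trajectory$t)
  out
}

# ---- change maps -----------------------------------------------------------

#' Rate-map change between two maps
#'
#' `after - before`, defined only where both maps are unmasked.
#'
#' @param before,after [ratemap()]s on identical binning, or matrices.
#' @return Matrix of rate change (`NA` where either input is masked).
#' @export
ratemap_change <- function(before, after) {
  if (inherits(before, "ratemap")) {
    if (!same_binning(before, after)) stop("rate maps have mismatched binning")
    before <- before$rate
    after <- after$rate
  }
  after - before
}

#' Replay-spike-aligned change map
#'
#' Translates a cell's change map so the interpolated location of its replay
#' spike sits at the origin. When the cell fired several spikes in the
#' event, the per-spike aligned maps are averaged first, yielding one
#' aligned map per cell and event.
#'
#' @param change Matrix of rate change (e.g. from [ratemap_change()] or
#'   [session_change_map()]).
#' @param spike_locs Matrix (or length-2 vector) of interpolated spike
#'   coordinates (cm).
#' @param bin_cm Bin side (cm).
#' @return `(2n-1) x (2n-1)` matrix with the spike location at the centre
#'   bin; unobserved bins are `NA`. Translation preserves values.
#' @export
align_change_map <- function(change, spike_locs, bin_cm) {
  if (is.null(dim(spike_locs))) spike_locs <- matrix(spike_locs, ncol = 2)
  maps <- purrr::map(seq_len(nrow(spike_locs)), function(k) {
    translate_to_origin(change, spike_locs[k, ], bin_cm)
  })
  if (length(maps) == 1) {
    return(maps[[1]])
  }
  acc <- array(unlist(maps), dim = c(dim(maps[[1]]), length(maps)))
  apply(acc, c(1, 2), mean, na.rm = TRUE)
}

#' Average a list of aligned change maps
#'
#' @param maps List of equally sized matrices (possibly `NA`-padded).
#' @return Matrix of bin-wise means over non-`NA` entries.
#' @export
average_change_maps <- function(maps) {
  acc <- array(unlist(maps), dim = c(dim(maps[[1]]), length(maps)))
  apply(acc, c(1, 2), function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
}

#' Classify a replay event as home, elsewhere or excluded
#'
#' Home replays require all of: the animal within 10 cm of the home well,
#' the decoded position within 30 cm of the home well at least once, and the
#' mean decoded position at least 40 cm from the animal. Elsewhere replays
#' require: the animal more than 10 cm from home, the decoded trajectory
#' staying at least 30 cm from home throughout, and the mean decoded
#' position at least 40 cm from the animal. Events meeting neither triple
#' are excluded.
#'
#' @param trajectory Decoded trajectory tibble `t, x, y`.
#' @param home Home-well coordinate (cm).
#' @param animal Animal position at the time of the event (cm).
#' @param near_cm,pass_cm,away_cm The 10 / 30 / 40 cm criteria.
#' @return `"home"`, `"elsewhere"` or `"excluded"`.
#' @export
classify_replay_event <- function(trajectory, home, animal,
                                  near_cm = 10, pass_cm = 30, away_cm = 40) {
  d_home <- sqrt((trajectory$x - home[1])^2 + (trajectory$y - home[2])^2)
  d_animal_home <- sqrt(sum((animal - home)^2))
  mean_pos <- c(mean(trajectory$x), mean(trajectory$y))
  d_mean_animal <- sqrt(sum((mean_pos - animal)^2))
  if (d_animal_home <= near_cm && any(d_home <= pass_cm) && d_mean_animal >= away_cm) {
    return("home")
  }
  if (d_animal_home > near_cm && all(d_home >= pass_cm) && d_mean_animal >= away_cm) {
    return("elsewhere")
  }
  "excluded"
}

#' Time-matched control sample of elsewhere replays
#'
#' Computes a 5-bin histogram of the home-replay event times, then draws
#' `n_draws` (10,000) random subsamples of the elsewhere replays of equal
#' size, bins them the same way, and keeps the subsample whose histogram
#' correlates best with the home histogram.
#'
#' @param home_times Event times of home replays (s).
#' @param elsewhere_times Event times of elsewhere replays (s).
#' @param n_draws Candidate subsamples.
#' @param n_bins Histogram bins.
#' @return Integer indices into `elsewhere_times` of the retained sample.
#' @export
match_controls <- function(home_times, elsewhere_times, n_draws = 10000,
                           n_bins = 5) {
  n <- length(home_times)
  if (length(elsewhere_times) < n) stop("fewer elsewhere than home events")
  breaks <- seq(min(c(home_times, elsewhere_times)) - 1e-9,
    max(c(home_times, elsewhere_times)) + 1e-9,
    length.out = n_bins + 1
  )
  target <- tabulate(findInterval(home_times, breaks, all.inside = TRUE), n_bins)
  best <- NULL
  best_r <- -Inf
  for (d in seq_len(n_draws)) {
    idx <- sample.int(length(elsewhere_times), n)
    cand <- tabulate(findInterval(elsewhere_times[idx], breaks, all.inside = TRUE), n_bins)
    r <- if (stats::sd(cand) == 0 || stats::sd(target) == 0) {
      if (all(cand == target)) 1 else -1
    } else {
      stats::cor(target, cand)
    }
    if (r > best_r) {
      best_r <- r
      best <- idx
      if (best_r >= 1) break
    }
  }
  structure(best, correlation = best_r)
}

#' Summarise aligned change maps: origin ROI and radial spokes
#'
#' For each aligned map: the average change within `roi_cm` (8 cm) of the
#' origin, and the average change along radial spokes sampled every
#' `step_cm` (2 cm) for `n_steps` (50) steps at `n_angles` (20) uniformly
#' distributed angles (nearest-bin lookup, averaged over angles).
#'
#' @param maps List of origin-centred aligned change maps.
#' @param bin_cm Bin side (cm).
#' @param roi_cm ROI radius (cm).
#' @param n_angles,n_steps,step_cm Spoke sampling parameters.
#' @return List with `roi` (tibble `item, value`) and `profile` (tibble
#'   `item, radius, value`); per-item values retained for s.e.m.
#' @export
summarize_changes <- function(maps, bin_cm, roi_cm = 8, n_angles = 20,
                              n_steps = 50, step_cm = 2) {
  if (length(maps) == 0) stop("no change maps to summarise")
  n <- nrow(maps[[1]])
  ctr <- (n + 1) / 2
  xs <- (seq_len(n) - ctr) * bin_cm
  rr <- outer(xs, xs, function(a, b) sqrt(a^2 + b^2))
  roi_mask <- rr <= roi_cm
  angles <- seq(0, 2 * pi, length.out = n_angles + 1)[-(n_angles + 1)]
  radii <- step_cm * seq_len(n_steps)
  si <- round(outer(radii, cos(angles)) / bin_cm + ctr)
  sj <- round(outer(radii, sin(angles)) / bin_cm + ctr)
  ok <- si >= 1 & si <= n & sj >= 1 & sj <= n
  roi <- purrr::map_dbl(maps, function(M) mean(M[roi_mask], na.rm = TRUE))
  prof <- purrr::imap(maps, function(M, item) {
    v <- matrix(NA_real_, n_steps, n_angles)
    v[ok] <- M[cbind(si[ok], sj[ok])]
    tibble::tibble(
      item = item, radius = radii,
      value = rowMeans(v, na.rm = TRUE)
    )
  }) |> purrr::list_rbind()
  list(
    roi = tibble::tibble(item = seq_along(maps), value = roi),
    profile = prof
  )
}

#' Correlation of a change map aligned on the current versus previous home
#'
#' Translates the total change map so the current home well is at the
#' origin, translates a copy so the previous home well is at the origin, and
#' correlates the two over their jointly observed bins. A generalising
#' landmark cell gains a field at its vector from the new home and loses one
#' at the same vector from the old home, so its correlation is negative.
#'
#' @param total_change Matrix of cumulative rate change.
#' @param home_new,home_prev Home-well coordinates (cm).
#' @param bin_cm Bin side (cm).
#' @param min_overlap Minimum jointly valid bins.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
home_shift_correlation <- function(total_change, home_new, home_prev, bin_cm,
                                   min_overlap = 25) {
  a <- translate_to_origin(total_change, home_new, bin_cm, clamp = FALSE)
  b <- translate_to_origin(total_change, home_prev, bin_cm, clamp = FALSE)
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < min_overlap) stop("insufficient overlap between aligned maps")
  stats::cor(a[ok], b[ok])
}

#' Overlap between a cell's rate-map changes and its replay spike locations
#'
#' The overlap multiplies the absolute change map elementwise by a map of
#' interpolated replay-spike locations smoothed with a 4 cm s.d. kernel,
#' then averages; the location correlation correlates the two maps instead,
#' isolating spatial alignment from the spike count.
#'
#' @param change Matrix of total rate change for the cell.
#' @param spike_locs Matrix of interpolated replay-spike coordinates (cm);
#'   zero rows give overlap 0.
#' @param bin_cm Bin side (cm).
#' @param n_replays Number of (home) replays the cell took part in; passed
#'   through for downstream regression.
#' @param smooth_cm Spike-map kernel s.d. (cm).
#' @return Tibble row `overlap, n_replays, location_correlation`.
#' @export
replay_change_overlap <- function(change, spike_locs, bin_cm,
                                  n_replays = NA_integer_, smooth_cm = 4) {
  n <- nrow(change)
  spike_map <- matrix(0, n, ncol(change))
  if (!is.null(spike_locs) && nrow(spike_locs) > 0) {
    ib <- coord_to_bin(spike_locs[, 1], bin_cm, n)
    jb <- coord_to_bin(spike_locs[, 2], bin_cm, ncol(change))
    for (k in seq_along(ib)) {
      spike_map[ib[k], jb[k]] <- spike_map[ib[k], jb[k]] + 1
    }
    spike_map <- gaussian_smooth(spike_map, smooth_cm / bin_cm, renormalize = FALSE)
  }
  ok <- !is.na(change)
  tibble::tibble(
    overlap = mean(abs(change[ok]) * spike_map[ok]),
    n_replays = n_replays,
    location_correlation = if (any(spike_map[ok] > 0)) {
      stats::cor(abs(change[ok]), spike_map[ok])
    } else {
      NA_real_
    }
  )
}

# ---- nonlocal door spikes --------------------------------------------------

#' Detect nonlocal door spikes and relate replay to new place fields
#'
#' A nonlocal door spike is emitted while (1) the animal is within
#' `door_cm` (10 cm) of a closed door, (2) moving slower than `speed_max`
#' (5 cm/s), and (3) outside every place field of the spiking cell. Cells
#' with at least one such spike count as having replayed. When a
#' `new_field` indicator and mean firing rate are supplied per cell, the
#' new-field indicator is regressed on the replay indicator with the mean
#' rate as covariate, and a one-tailed t-test on the replay coefficient is
#' reported.
#'
#' @param spikes Tibble `cell, time`.
#' @param track Tibble `time, x, y` (cm).
#' @param doors Matrix of closed-door coordinates (one row per door, cm).
#' @param place_fields List, per cell, of logical field masks (`nx x ny`,
#'   `TRUE` inside a field) on `bin_cm` binning.
#' @param bin_cm Field-mask bin size (cm).
#' @param door_cm,speed_max Criteria (1) and (2).
#' @param cells Optional tibble `cell, new_field, mean_rate` enabling the
#'   regression.
#' @return List with `spikes` (input plus `nonlocal_door` flag), `cells`
#'   (per-cell `replayed` indicator) and, when `cells` was given,
#'   `regression` (tibble `term, estimate, statistic, p_one_tailed`).
#' @export
nonlocal_door_spikes <- function(spikes, track, doors, place_fields, bin_cm,
                                 door_cm = 10, speed_max = 5, cells = NULL) {
  if (nrow(doors) == 0) stop("no closed-door epochs")
  at <- interp_track(track, spikes$time)
  d_door <- purrr::map_dbl(seq_len(nrow(spikes)), function(k) {
    min(sqrt((doors[, 1] - at$x[k])^2 + (doors[, 2] - at$y[k])^2))
  })
  n <- nrow(place_fields[[1]])
  ib <- coord_to_bin(at$x, bin_cm, n)
  jb <- coord_to_bin(at$y, bin_cm, ncol(place_fields[[1]]))
  in_field <- purrr::map_lgl(seq_len(nrow(spikes)), function(k) {
    place_fields[[spikes$cell[k]]][ib[k], jb[k]]
  })
  flag <- d_door <= door_cm & at$speed < speed_max & !in_field
  spikes$nonlocal_door <- flag
  cell_ids <- seq_along(place_fields)
  replayed <- tibble::tibble(
    cell = cell_ids,
    replayed = as.integer(cell_ids %in% spikes$cell[flag])
  )
  out <- list(spikes = spikes, cells = replayed)
  if (!is.null(cells)) {
    dat <- dplyr::left_join(cells, replayed, by = "cell")
    fit <- stats::lm(new_field ~ replayed + mean_rate, data = dat)
    sm <- summary(fit)$coefficients
    out$regression <- tibble::tibble(
      term = rownames(sm),
      estimate = sm[, 1],
      statistic = sm[, 3],
      p_one_tailed = stats::pt(sm[, 3], df = fit$df.residual, lower.tail = FALSE)
    )
  }
  out
}
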