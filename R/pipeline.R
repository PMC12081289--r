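# End-to-end validation of the analysis pipeline on synthetic sessions:
# decode every replay event leaving each spiking neuron out, interpolate its
# spike locations, align the ground-truth change maps on them, and summarise
# by replay group.

#' Analyse a synthetic replay session with the empirical pipeline
#'
#' Runs the replay-decoding pipeline over a [simulate_replay_session()]
#' result: for every replay event, each neuron that spiked is localised by
#' decoding the event with that neuron left out (20 ms windows, 5 ms steps)
#' and interpolating its spike times along the decoded trajectory; the
#' cell's ground-truth change map for the event is then translated so the
#' interpolated spike location sits at the origin (multiple spikes of a cell
#' in one event are averaged first).
#'
#' @param pop A `conjunctive_pop`.
#' @param session A `replay_session` simulated from `pop`.
#' @param window,step Decoding window and stride (s).
#' @param noise_hz,noise_smooth_cm Change-map noise passed to
#'   [session_change_map()].
#' @param max_cells_per_event Optional cap on localised cells per event
#'   (cells with most spikes kept), to bound compute.
#' @return List with `items`: tibble (replay_id, type, cell, class,
#'   decode_error) and `aligned`: list of origin-centred change maps, one
#'   per row of `items`.
#' @export
analyze_replay_session <- function(pop, session, window = 0.02, step = 0.005,
                                   noise_hz = 0.5, noise_smooth_cm = 4,
                                   max_cells_per_event = Inf) {
  decoder <- make_decoder(pop$day1, pop$bin_cm)
  dur <- session$params$n_steps * session$params$dt_step
  items <- list()
  aligned <- list()
  k <- 0L
  for (ev in unique(session$spikes$replay_id)) {
    sp <- session$spikes[session$spikes$replay_id == ev, ]
    t_ev <- session$events$t_event[session$events$replay_id == ev]
    type <- session$events$type[session$events$replay_id == ev]
    traj <- session$trajectories[session$trajectories$replay_id == ev, ]
    t_end <- t_ev + max(traj$step) * session$params$dt_step
    if (t_end - t_ev < window) next
    cells <- sp |>
      dplyr::count(.data$cell, sort = TRUE)
    cells <- utils::head(cells, max_cells_per_event)
    for (c_i in cells$cell) {
      dec <- decode_event_trajectory(sp, decoder, t_ev, t_end,
        window = window, step = step, exclude = c_i
      )
      own <- sp[sp$cell == c_i, ]
      locs <- t(vapply(
        own$time,
        function(tt) as.numeric(interpolate_spike_location(tt, dec)),
        numeric(2)
      ))
      change <- session_change_map(session, pop, c_i, ev,
        noise_hz = noise_hz, noise_smooth_cm = noise_smooth_cm
      )
      k <- k + 1L
      aligned[[k]] <- align_change_map(change, locs, pop$bin_cm)
      items[[k]] <- tibble::tibble(
        replay_id = ev, type = type, cell = c_i,
        class = pop$cells$class[c_i],
        decode_error = mean(sqrt((locs[, 1] - own$x)^2 + (locs[, 2] - own$y)^2))
      )
    }
  }
  list(items = purrr::list_rbind(items), aligned = aligned)
}

#' Group-level change summary of an analysed session
#'
#' Adds a time-matched control group (elsewhere replays resampled to match
#' the home replays' event-time histogram via [match_controls()]) and
#' returns the origin-ROI means and radial profiles per group together with
#' the group-averaged aligned maps.
#'
#' @param analysis Result of [analyze_replay_session()].
#' @param session The session that was analysed.
#' @param bin_cm Map bin size (cm).
#' @param n_draws Matched-control draws.
#' @return List with `roi` (tibble `group, item, value`), `profile`
#'   (tibble `group, item, radius, value`) and `mean_maps` (named list of
#'   group-averaged aligned maps).
#' @export
summarize_session_changes <- function(analysis, session, bin_cm,
                                      n_draws = 2000) {
  items <- analysis$items
  ev_home <- unique(items$replay_id[items$type == "home"])
  ev_else <- unique(items$replay_id[items$type == "elsewhere"])
  t_of <- function(ids) {
    session$events$t_event[match(ids, session$events$replay_id)]
  }
  groups <- list(home = ev_home, elsewhere = ev_else)
  if (length(ev_else) >= length(ev_home) && length(ev_home) > 0) {
    idx <- match_controls(t_of(ev_home), t_of(ev_else), n_draws = n_draws)
    groups$matched <- ev_else[idx]
  }
  roi <- list()
  prof <- list()
  mean_maps <- list()
  for (g in names(groups)) {
    rows <- which(items$replay_id %in% groups[[g]])
    if (length(rows) == 0) next
    s <- summarize_changes(analysis$aligned[rows], bin_cm)
    roi[[g]] <- dplyr::mutate(s$roi, group = g, .before = 1)
    prof[[g]] <- dplyr::mutate(s$profile, group = g, .before = 1)
    mean_maps[[g]] <- average_change_maps(analysis$aligned[rows])
  }
  list(
    roi = purrr::list_rbind(roi), profile = purrr::list_rbind(prof),
    mean_maps = mean_maps
  )
}

#' Home-shift generalization signature across the population
#'
#' Builds cumulative day-2 change maps for every cell and correlates each
#' cell's change aligned on the new home with the same change aligned on the
#' previous home. Landmark cells remap with the home well, so their
#' correlations are negative; place cells contribute noise around zero.
#'
#' @param pop A `conjunctive_pop`.
#' @param noise_hz,noise_smooth_cm Change-noise parameters.
#' @return Tibble `cell, class, correlation`.
#' @export
home_shift_population <- function(pop, noise_hz = 0.5, noise_smooth_cm = 4) {
  changes <- day2_change_maps(pop, noise_hz, noise_smooth_cm)
  n_cells <- dim(changes)[3]
  r <- vapply(seq_len(n_cells), function(c_i) {
    home_shift_correlation(
      changes[, , c_i], pop$home_day2, pop$home_day1,
      pop$bin_cm
    )
  }, numeric(1))
  tibble::tibble(cell = seq_len(n_cells), class = pop$cells$class, correlation = r)
}
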