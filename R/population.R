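# Synthetic entorhinal populations (grid, object-vector, sensory cells) and
# their hippocampal conjunctions (landmark and place cells), modelled after
# home-well recordings: per-class population maxima scaled to 20 Hz, grid
# peaks on a triangular lattice, object-vector fields at a fixed vector from
# the home well that follows the home well when it moves across days.
#
# All coordinates are centimetres with the origin at the arena's south-west
# corner; rate maps use 2 cm bins with rows indexing x.

sum_of_gaussians_map <- function(nx, ny, bin, centers, sigma) {
  xs <- bin_centers(nx, bin)
  ys <- bin_centers(ny, bin)
  M <- matrix(0, nx, ny)
  if (nrow(centers) == 0) {
    return(M)
  }
  for (k in seq_len(nrow(centers))) {
    gx <- exp(-(xs - centers[k, 1])^2 / (2 * sigma^2))
    gy <- exp(-(ys - centers[k, 2])^2 / (2 * sigma^2))
    M <- M + outer(gx, gy)
  }
  M
}

triangular_lattice <- function(spacing, rotation_deg, shift, extent) {
  rot <- rotation_deg * pi / 180
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  v1 <- R %*% c(spacing, 0)
  v2 <- R %*% c(spacing / 2, spacing * sqrt(3) / 2)
  m <- ceiling(extent / spacing) + 2L
  ij <- tidyr::expand_grid(i = -m:m, j = -m:m)
  pts <- cbind(
    ij$i * v1[1] + ij$j * v2[1] + shift[1],
    ij$i * v1[2] + ij$j * v2[2] + shift[2]
  )
  pts[pts[, 1] > -spacing & pts[, 1] < extent + spacing &
    pts[, 2] > -spacing & pts[, 2] < extent + spacing, , drop = FALSE]
}

#' Build the synthetic entorhinal populations
#'
#' Generates rate maps for 10 grid cells (triangular lattice, 120 cm peak
#' spacing, rotated 6 degrees, random per-cell translation), 20 object-vector
#' cells (uniform random direction, uniform random distance 0-200 cm from the
#' home well; day-2 maps are the day-1 maps translated with the home well)
#' and 40 sensory cells (uniform random field centres). Each class is scaled
#' so its population maximum firing rate is exactly 20 Hz (object-vector
#' scaling is set on day 1 and shared with day 2 so the across-day
#' translation identity is preserved).
#'
#' @param arena_cm Arena side (cm).
#' @param bin_cm Rate-map bin size (cm).
#' @param home_day1,home_day2 Home-well coordinates (cm) on the two days.
#' @param n_grid,n_ovc,n_sensory Cell counts per class.
#' @param grid_spacing Distance between grid peaks (cm).
#' @param grid_rotation Lattice rotation (degrees).
#' @param grid_sigma,ovc_sigma,sensory_sigma Gaussian field widths (s.d.,
#'   cm). Defaults give firing fields of the size typical of open-field
#'   rodent recordings.
#' @param ovc_dist_range Range of object-vector preferred distances (cm).
#' @param peak_hz Per-class population maximum after scaling.
#' @return An `entorhinal_pop` list of 3D rate-map arrays
#'   (`nx x ny x n_cells`) plus geometry metadata.
#' @export
build_entorhinal_populations <- function(arena_cm = 200, bin_cm = 2,
                                         home_day1 = c(60, 60),
                                         home_day2 = c(140, 140),
                                         n_grid = 10, n_ovc = 20,
                                         n_sensory = 40,
                                         grid_spacing = 120,
                                         grid_rotation = 6,
                                         grid_sigma = 14.1,
                                         ovc_sigma = 11,
                                         sensory_sigma = 14.1,
                                         ovc_dist_range = c(0, 200),
                                         peak_hz = 20) {
  stopifnot(arena_cm > 0, bin_cm > 0)
  nx <- ny <- as.integer(round(arena_cm / bin_cm))
  stack <- function(n) array(0, dim = c(nx, ny, n))
  grid <- stack(n_grid)
  for (c_i in seq_len(n_grid)) {
    shift <- stats::runif(2, 0, grid_spacing)
    pts <- triangular_lattice(grid_spacing, grid_rotation, shift, arena_cm)
    grid[, , c_i] <- sum_of_gaussians_map(nx, ny, bin_cm, pts, grid_sigma)
  }
  ovc_dir <- stats::runif(n_ovc, 0, 2 * pi)
  ovc_dist <- stats::runif(n_ovc, ovc_dist_range[1], ovc_dist_range[2])
  ovc_vec <- cbind(ovc_dist * cos(ovc_dir), ovc_dist * sin(ovc_dir))
  ovc_day <- function(home) {
    a <- stack(n_ovc)
    for (c_i in seq_len(n_ovc)) {
      ctr <- matrix(home + ovc_vec[c_i, ], ncol = 2)
      a[, , c_i] <- sum_of_gaussians_map(nx, ny, bin_cm, ctr, ovc_sigma)
    }
    a
  }
  ovc1 <- ovc_day(home_day1)
  ovc2 <- ovc_day(home_day2)
  sens_ctr <- cbind(
    stats::runif(n_sensory, 0, arena_cm),
    stats::runif(n_sensory, 0, arena_cm)
  )
  sens <- stack(n_sensory)
  for (c_i in seq_len(n_sensory)) {
    sens[, , c_i] <- sum_of_gaussians_map(
      nx, ny, bin_cm,
      sens_ctr[c_i, , drop = FALSE], sensory_sigma
    )
  }
  scale_to <- function(a, mx) a * (peak_hz / mx)
  grid <- scale_to(grid, max(grid))
  ovc_scale <- max(ovc1)
  ovc1 <- scale_to(ovc1, ovc_scale)
  ovc2 <- scale_to(ovc2, ovc_scale)
  sens <- scale_to(sens, max(sens))
  structure(
    list(
      grid = grid, ovc_day1 = ovc1, ovc_day2 = ovc2, sensory = sens,
      arena_cm = arena_cm, bin_cm = bin_cm,
      home_day1 = home_day1, home_day2 = home_day2,
      ovc_vectors = ovc_vec, sensory_centers = sens_ctr
    ),
    class = "entorhinal_pop"
  )
}

#' Build the conjunctive hippocampal population
#'
#' Takes the elementwise product of every grid map with every object-vector
#' map (landmark cells) and with every sensory map (place cells), giving
#' `n_grid * n_ovc` landmark and `n_grid * n_sensory` place cells (200 + 400
#' = 600 with the default counts). Each conjunctive class is scaled to a
#' population maximum of 20 Hz; the landmark scale is set on day 1 and
#' shared with day 2, since the cells are the same across days. Landmark
#' maps track the home well across days; place maps are day-stable.
#'
#' @param ent An `entorhinal_pop`.
#' @param peak_hz Conjunctive population maximum after scaling.
#' @return A `conjunctive_pop`: arrays `day1`/`day2` (`nx x ny x 600`) and a
#'   `cells` tibble with class labels and parent indices.
#' @export
build_conjunctive_population <- function(ent, peak_hz = 20) {
  dims <- dim(ent$grid)
  n_grid <- dims[3]
  n_ovc <- dim(ent$ovc_day1)[3]
  n_sens <- dim(ent$sensory)[3]
  n_lmk <- n_grid * n_ovc
  n_plc <- n_grid * n_sens
  conj <- function(a, b) {
    out <- array(0, dim = c(dims[1], dims[2], dim(a)[3] * dim(b)[3]))
    k <- 0L
    for (j in seq_len(dim(b)[3])) {
      for (i in seq_len(dim(a)[3])) {
        k <- k + 1L
        out[, , k] <- a[, , i] * b[, , j]
      }
    }
    out
  }
  lmk1 <- conj(ent$grid, ent$ovc_day1)
  lmk2 <- conj(ent$grid, ent$ovc_day2)
  plc <- conj(ent$grid, ent$sensory)
  lmk_scale <- peak_hz / max(lmk1)
  plc_scale <- peak_hz / max(plc)
  day1 <- array(0, dim = c(dims[1], dims[2], n_lmk + n_plc))
  day1[, , seq_len(n_lmk)] <- lmk1 * lmk_scale
  day1[, , n_lmk + seq_len(n_plc)] <- plc * plc_scale
  day2 <- day1
  day2[, , seq_len(n_lmk)] <- lmk2 * lmk_scale
  cells <- tibble::tibble(
    cell = seq_len(n_lmk + n_plc),
    class = rep(c("landmark", "place"), c(n_lmk, n_plc)),
    grid_parent = c(
      rep(seq_len(n_grid), times = n_ovc),
      rep(seq_len(n_grid), times = n_sens)
    ),
    other_parent = c(
      rep(seq_len(n_ovc), each = n_grid),
      rep(seq_len(n_sens), each = n_grid)
    )
  )
  structure(
    list(
      day1 = day1, day2 = day2, cells = cells,
      arena_cm = ent$arena_cm, bin_cm = ent$bin_cm,
      home_day1 = ent$home_day1, home_day2 = ent$home_day2
    ),
    class = "conjunctive_pop"
  )
}

#' @export
print.conjunctive_pop <- function(x, ...) {
  cat(sprintf(
    "<conjunctive_pop: %d landmark + %d place cells, %d cm arena>\n",
    sum(x$cells$class == "landmark"), sum(x$cells$class == "place"),
    x$arena_cm
  ))
  invisible(x)
}

# ---- replay session --------------------------------------------------------

sample_replay_path <- function(arena_cm, home, type, len_range = c(100, 300),
                               n_steps = 20, home_excl = 30) {
  start <- if (type == "home") {
    home
  } else {
    repeat {
      s <- stats::runif(2, 0, arena_cm)
      if (sqrt(sum((s - home)^2)) > home_excl) break
    }
    s
  }
  len <- stats::runif(1, len_range[1], len_range[2])
  theta <- stats::runif(1, 0, 2 * pi)
  k <- seq_len(n_steps)
  xs <- start[1] + k * (len / n_steps) * cos(theta)
  ys <- start[2] + k * (len / n_steps) * sin(theta)
  keep <- xs >= 0 & xs <= arena_cm & ys >= 0 & ys <= arena_cm
  if (type == "elsewhere") {
    keep <- keep & sqrt((xs - home)^2 + (ys - home)^2) > home_excl
  }
  cut <- which(!keep)[1]
  if (!is.na(cut)) k <- k[seq_len(cut - 1L)]
  if (length(k) == 0) {
    return(NULL)
  }
  tibble::tibble(step = k, x = xs[k], y = ys[k])
}

#' Simulate a replay session on the synthetic population
#'
#' Samples `n_replays` replay trajectories (one home replay followed by three
#' replays elsewhere, repeating), spread evenly through the session between
#' `t_range[1]` and `t_range[2]` seconds. Each trajectory starts at the home
#' well (home) or a random location (elsewhere), extends 100-300 cm in a
#' random direction over 20 steps of 5 ms, and is cut short at the arena
#' boundary; elsewhere trajectories are also cut before entering the 30 cm
#' home exclusion zone. Spikes are Poisson draws from the day-1 conjunctive
#' rate maps at the replayed locations, with rates scaled up by
#' `rate_scale` (25) to mimic the compressed replay regime. A landmark cell
#' never spikes in a replay elsewhere before its first spike in a replay
#' from home; that first home spike time `t0` is recorded per landmark cell,
#' and the ground-truth rate-map change attributed to a later replay at time
#' `t1` is `t0 / t1` times the cell's full landmark peak (see
#' [session_change_map()]).
#'
#' @param pop A `conjunctive_pop`.
#' @param n_replays Number of replay trajectories.
#' @param t_range Session time span (s).
#' @param len_range Trajectory length range (cm).
#' @param n_steps Steps per trajectory.
#' @param dt_step Step duration (s).
#' @param rate_scale Replay firing-rate scale factor.
#' @param home_excl Home exclusion radius for elsewhere replays (cm).
#' @return A `replay_session`: tibbles `events` (replay_id, type, t_event),
#'   `trajectories` (replay_id, step, t, x, y) and `spikes` (replay_id,
#'   cell, class, time, x, y, first_home flag), plus per-landmark `t0` and
#'   the simulation parameters.
#' @export
simulate_replay_session <- function(pop, n_replays = 100,
                                    t_range = c(10, 3000),
                                    len_range = c(100, 300), n_steps = 20,
                                    dt_step = 0.005, rate_scale = 25,
                                    home_excl = 30) {
  nx <- dim(pop$day1)[1]
  n_cells <- dim(pop$day1)[3]
  is_lmk <- pop$cells$class == "landmark"
  t0 <- rep(NA_real_, n_cells) # first home-replay spike time, landmark cells
  types <- rep(c("home", rep("elsewhere", 3)), length.out = n_replays)
  t_event <- seq(t_range[1], t_range[2], length.out = n_replays)
  flat <- matrix(pop$day1, nrow = nx * nx, ncol = n_cells)
  trajs <- list()
  spikes <- list()
  for (ev in seq_len(n_replays)) {
    path <- sample_replay_path(pop$arena_cm, pop$home_day1, types[ev],
      len_range, n_steps,
      home_excl = home_excl
    )
    if (is.null(path)) next
    path$t <- t_event[ev] + (path$step - 1L) * dt_step
    path$replay_id <- ev
    trajs[[ev]] <- path
    ib <- coord_to_bin(path$x, pop$bin_cm, nx)
    jb <- coord_to_bin(path$y, pop$bin_cm, nx)
    rates <- flat[(jb - 1L) * nx + ib, , drop = FALSE] * rate_scale # steps x cells
    counts <- matrix(
      stats::rpois(length(rates), rates * dt_step),
      nrow(rates), n_cells
    )
    if (types[ev] == "elsewhere") {
      counts[, is_lmk & is.na(t0)] <- 0L
    }
    hit <- which(counts > 0, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      n_sp <- counts[hit]
      sp <- tibble::tibble(
        replay_id = ev,
        cell = rep(hit[, 2], n_sp),
        step = rep(path$step[hit[, 1]], n_sp),
        x = rep(path$x[hit[, 1]], n_sp),
        y = rep(path$y[hit[, 1]], n_sp),
        time = rep(path$t[hit[, 1]], n_sp) + stats::runif(sum(n_sp), 0, dt_step)
      )
      sp$class <- pop$cells$class[sp$cell]
      if (types[ev] == "home") {
        new_first <- setdiff(unique(sp$cell[sp$class == "landmark"]), which(!is.na(t0)))
        t0[new_first] <- t_event[ev]
      }
      sp$first_home <- types[ev] == "home" & sp$class == "landmark" &
        t0[sp$cell] == t_event[ev]
      spikes[[ev]] <- sp
    }
  }
  structure(
    list(
      events = tibble::tibble(replay_id = seq_len(n_replays), type = types, t_event = t_event),
      trajectories = purrr::list_rbind(trajs),
      spikes = purrr::list_rbind(spikes),
      t0 = t0,
      params = list(
        n_steps = n_steps, dt_step = dt_step, rate_scale = rate_scale,
        len_range = len_range, home_excl = home_excl, t_range = t_range
      )
    ),
    class = "replay_session"
  )
}

#' @export
print.replay_session <- function(x, ...) {
  cat(sprintf(
    "<replay_session: %d events (%d home), %d spikes>\n",
    nrow(x$events), sum(x$events$type == "home"), nrow(x$spikes)
  ))
  invisible(x)
}

#' Mean number of replay spikes per trajectory
#' @param session A `replay_session`.
#' @export
mean_spikes_per_replay <- function(session) {
  nrow(session$spikes) / dplyr::n_distinct(session$trajectories$replay_id)
}

#' Ground-truth rate-map change for one cell around one replay event
#'
#' Landmark cells: `t0 / t1` times the cell's full day-1 rate map (the new
#' landmark peak), where `t0` is the cell's first home-replay spike time and
#' `t1` the event time - the first home replay (`t1 == t0`) contributes the
#' full new peak, later replays progressively less. Place cells contribute
#' nothing but noise. Both get additive change noise: standard-normal draws
#' times `noise_hz`, smoothed with a `noise_smooth_cm` Gaussian kernel.
#'
#' @param session A `replay_session`.
#' @param pop The `conjunctive_pop` it was simulated from.
#' @param cell Cell index.
#' @param replay_id Replay event index.
#' @param noise_hz Change-noise amplitude (Hz).
#' @param noise_smooth_cm Change-noise smoothing kernel s.d. (cm).
#' @return Matrix (`nx x ny`) of rate change (Hz).
#' @export
session_change_map <- function(session, pop, cell, replay_id,
                               noise_hz = 0.5, noise_smooth_cm = 4) {
  nx <- dim(pop$day1)[1]
  noise <- gaussian_smooth(
    matrix(stats::rnorm(nx * nx), nx, nx) * noise_hz,
    noise_smooth_cm / pop$bin_cm,
    renormalize = FALSE
  )
  if (pop$cells$class[cell] == "landmark") {
    t0 <- session$t0[cell]
    t1 <- session$events$t_event[session$events$replay_id == replay_id]
    if (!is.na(t0) && t0 <= t1) {
      return(pop$day1[, , cell] * (t0 / t1) + noise)
    }
  }
  noise
}

#' Cumulative day-2 rate-map changes
#'
#' Subtracts each cell's day-1 rate map from its day-2 map and adds change
#' noise. Landmark changes show a positive field at the cell's vector from
#' the new home and a negative field at the same vector from the old home;
#' place-cell changes are noise only.
#'
#' @param pop A `conjunctive_pop`.
#' @param noise_hz,noise_smooth_cm Change-noise parameters as in
#'   [session_change_map()]; set `noise_hz = 0` for the noiseless limit.
#' @return 3D array `nx x ny x n_cells` of day-2 minus day-1 rates.
#' @export
day2_change_maps <- function(pop, noise_hz = 0.5, noise_smooth_cm = 4) {
  nx <- dim(pop$day1)[1]
  n_cells <- dim(pop$day1)[3]
  out <- pop$day2 - pop$day1
  if (noise_hz > 0) {
    for (c_i in seq_len(n_cells)) {
      out[, , c_i] <- out[, , c_i] + gaussian_smooth(
        matrix(stats::rnorm(nx * nx), nx, nx) * noise_hz,
        noise_smooth_cm / pop$bin_cm,
        renormalize = FALSE
      )
    }
  }
  out
}

# ---- behavioural (between-replay) data -------------------------------------

#' Generate a synthetic foraging track
#'
#' Smooth random-walk behaviour for computing occupancy and before/after
#' rate maps: heading diffuses, speed is drawn around `speed_cm_s`, and the
#' track reflects off the arena walls.
#'
#' @param arena_cm Arena side (cm).
#' @param duration Track duration (s).
#' @param dt Sample interval (s).
#' @param speed_cm_s Mean running speed (cm/s).
#' @param start Start coordinate; defaults to the arena centre.
#' @return Tibble `time, x, y`.
#' @export
generate_foraging_track <- function(arena_cm, duration = 600, dt = 0.1,
                                    speed_cm_s = 15, start = NULL) {
  n <- ceiling(duration / dt)
  if (is.null(start)) start <- c(arena_cm / 2, arena_cm / 2)
  x <- numeric(n)
  y <- numeric(n)
  x[1] <- start[1]
  y[1] <- start[2]
  theta <- stats::runif(1, 0, 2 * pi)
  for (i in seq_len(n - 1L)) {
    theta <- theta + stats::rnorm(1, 0, 0.4)
    sp <- max(0, stats::rnorm(1, speed_cm_s, speed_cm_s / 3))
    nx <- x[i] + sp * dt * cos(theta)
    ny <- y[i] + sp * dt * sin(theta)
    if (nx < 0 || nx > arena_cm) {
      theta <- pi - theta
      nx <- pmin(pmax(nx, 0), arena_cm)
    }
    if (ny < 0 || ny > arena_cm) {
      theta <- -theta
      ny <- pmin(pmax(ny, 0), arena_cm)
    }
    x[i + 1L] <- nx
    y[i + 1L] <- ny
  }
  tibble::tibble(time = (seq_len(n) - 1L) * dt, x = x, y = y)
}

#' Sample Poisson spikes along a track from a stack of rate maps
#'
#' @param maps 3D array `nx x ny x n_cells` of rates (Hz).
#' @param track Tibble `time, x, y` (regular sampling).
#' @param bin_cm Map bin size (cm).
#' @return Tibble `cell, time`, sorted by time.
#' @export
simulate_behavior_spikes <- function(maps, track, bin_cm) {
  nx <- dim(maps)[1]
  n_cells <- dim(maps)[3]
  dt <- stats::median(diff(track$time))
  ib <- coord_to_bin(track$x, bin_cm, nx)
  jb <- coord_to_bin(track$y, bin_cm, nx)
  lin <- (jb - 1L) * nx + ib
  flat <- matrix(maps, nrow = nx * nx, ncol = n_cells)
  out <- purrr::map(seq_len(n_cells), function(c_i) {
    counts <- stats::rpois(length(lin), flat[lin, c_i] * dt)
    hit <- which(counts > 0)
    if (length(hit) == 0) {
      return(NULL)
    }
    tibble::tibble(
      cell = c_i,
      time = rep(track$time[hit], counts[hit]) + stats::runif(sum(counts[hit]), 0, dt)
    )
  }) |> purrr::list_rbind()
  dplyr::arrange(out, .data$time)
}
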