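# Reproducible experiment recipes tying the modules together, a config-driven
# runner with a manifest, and programmatic fixtures for tests. The recipes
# double as the package's figure-level entry points (generalization curves,
# latent learning, replay visit efficiency, noisy homing, session analysis,
# home-shift histograms); a thin command-line wrapper lives in
# inst/cli/replaymap.R.

#' Policy-generalization experiment
#'
#' Trains policy networks on compositional versus traditional state
#' representations across many reward-only grid worlds (resampling a fresh
#' batch of worlds every round) and evaluates rollout success on held-out
#' worlds, alongside a uniform-random-policy baseline. Optionally also runs
#' the single-environment protocol (train and test on the same world).
#'
#' @param n_envs Worlds per training round (25).
#' @param samples_per_env Training pairs sampled per world (200).
#' @param n_rounds Rounds of world resampling.
#' @param n_test_envs Held-out evaluation worlds (25).
#' @param width,height World size.
#' @param hidden Hidden layer sizes of the policy network.
#' @param epochs_per_round Adam epochs per round.
#' @param single_env Also run the single-environment protocol.
#' @param single_env_samples Pairs for that protocol (1000).
#' @return Tibble `condition, mode, world, success`.
#' @export
exp_generalization <- function(n_envs = 25, samples_per_env = 200,
                               n_rounds = 10, n_test_envs = 25,
                               width = 6, height = 6, hidden = c(64, 32),
                               epochs_per_round = 15, single_env = FALSE,
                               single_env_samples = 1000) {
  proto <- sample_gridworld(width, height, 0)
  layout <- state_layout(proto, n_wall_slots = 0)
  train_mode <- function(mode) {
    X <- NULL
    y <- NULL
    for (r in seq_len(n_rounds)) {
      batch <- purrr::map(seq_len(n_envs), function(i) {
        sample_training_set(sample_gridworld(width, height, 0),
          samples_per_env,
          mode = mode, layout = layout
        )
      })
      X <- do.call(rbind, c(list(X), purrr::map(batch, "X")))
      y <- c(y, unlist(purrr::map(batch, "y")))
    }
    train_policy_network(X, y,
      hidden = hidden, task = "discrete",
      epochs = n_rounds * epochs_per_round, batch_size = 512
    )
  }
  nets <- list(
    compositional = train_mode("compositional"),
    traditional = train_mode("traditional")
  )
  # the evaluated networks are deterministic (argmax) policies, so the
  # matched null is a deterministic random policy: one fixed uniform-random
  # action per cell, drawn per world
  random_policy_for <- function(world) {
    acts <- sample.int(4L, world$width * world$height, replace = TRUE)
    function(world, loc) acts[loc[2] * world$width + loc[1] + 1L]
  }
  test_worlds <- purrr::map(seq_len(n_test_envs), ~ sample_gridworld(width, height, 0))
  held_out <- purrr::imap(test_worlds, function(w, wi) {
    succ <- c(
      evaluate_policy(nets$compositional, w, mode = "compositional", layout = layout),
      evaluate_policy(nets$traditional, w, mode = "traditional", layout = layout),
      evaluate_policy(random_policy_for(w), w)
    )
    tibble::tibble(
      condition = "held_out",
      mode = c("compositional", "traditional", "random"),
      world = wi,
      success = succ
    )
  }) |> purrr::list_rbind()
  out <- held_out
  if (single_env) {
    single <- purrr::map(seq_len(n_test_envs), function(wi) {
      w <- sample_gridworld(width, height, 0)
      purrr::map(c("compositional", "traditional"), function(md) {
        ts <- sample_training_set(w, single_env_samples, mode = md, layout = layout)
        f <- train_policy_network(ts$X, ts$y,
          hidden = hidden,
          task = "discrete", epochs = 150
        )
        succ <- evaluate_policy(f, w, mode = md, layout = layout)
        tibble::tibble(condition = "single_env", mode = md, world = wi, success = succ)
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
    out <- dplyr::bind_rows(out, single)
  }
  out
}

#' Replay visit-efficiency experiment: all four agent-by-trajectory curves
#'
#' @param ... Passed to [replay_visit_curve()] (world counts, sizes, noise).
#' @return Tibble `agent, mode, visit, success`.
#' @export
exp_replay_visits <- function(...) {
  tidyr::expand_grid(
    agent = c("memory", "q"),
    mode = c("random", "reverse_optimal")
  ) |>
    purrr::pmap(function(agent, mode) {
      replay_visit_curve(agent = agent, mode = mode, ...)
    }) |>
    purrr::list_rbind()
}

#' Session change-map experiment (synthetic pipeline validation)
#'
#' Builds the synthetic population, simulates a replay session, runs the
#' decoding pipeline and summarises aligned change maps by replay group.
#'
#' @param arena_cm,home_day1,home_day2 Geometry passed to the generators.
#' @param n_replays Session replay count.
#' @param max_cells_per_event Compute cap for the leave-one-out decoding.
#' @return List: `summary` from [summarize_session_changes()], `analysis`,
#'   `session`, `pop`.
#' @export
exp_session_changes <- function(arena_cm = 200, home_day1 = c(60, 60),
                                home_day2 = c(140, 140), n_replays = 100,
                                max_cells_per_event = Inf) {
  ent <- build_entorhinal_populations(
    arena_cm = arena_cm,
    home_day1 = home_day1, home_day2 = home_day2
  )
  pop <- build_conjunctive_population(ent)
  session <- simulate_replay_session(pop, n_replays = n_replays)
  analysis <- analyze_replay_session(pop, session,
    max_cells_per_event = max_cells_per_event
  )
  summary <- summarize_session_changes(analysis, session, pop$bin_cm)
  list(summary = summary, analysis = analysis, session = session, pop = pop)
}

#' Home-shift generalization experiment
#'
#' @inheritParams exp_session_changes
#' @return Tibble from [home_shift_population()].
#' @export
exp_home_shift <- function(arena_cm = 200, home_day1 = c(60, 60),
                           home_day2 = c(140, 140)) {
  ent <- build_entorhinal_populations(
    arena_cm = arena_cm,
    home_day1 = home_day1, home_day2 = home_day2
  )
  pop <- build_conjunctive_population(ent)
  home_shift_population(pop)
}

EXPERIMENTS <- list(
  generalization = "exp_generalization",
  latent_learning = "latent_learning_experiment",
  replay_visits = "exp_replay_visits",
  homing = "homing_experiment",
  session_changes = "exp_session_changes",
  home_shift = "exp_home_shift"
)

#' Run an experiment from a config
#'
#' Configs are plain lists (readable from JSON) with fields `experiment`
#' (one of `generalization`, `latent_learning`, `replay_visits`, `homing`,
#' `session_changes`, `home_shift`), optional `seed`,
#' `params` (arguments of the recipe) and `out` (directory for result
#' tables). Unknown fields or parameters raise an error naming the field.
#' Re-running a config with the same seed bit-reproduces the outputs; the
#' manifest records the config hash, seed and package version.
#'
#' @param config List or path to a JSON config file.
#' @return List with `result` and `manifest`. When `out` is set, result
#'   tables are written as CSV along with `manifest.json`.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  allowed <- c("experiment", "seed", "params", "out")
  bad <- setdiff(names(config), allowed)
  if (length(bad)) stop("unknown config field: ", paste(bad, collapse = ", "))
  if (is.null(config$experiment) || !config$experiment %in% names(EXPERIMENTS)) {
    stop("config field 'experiment' must be one of: ", paste(names(EXPERIMENTS), collapse = ", "))
  }
  fn_name <- EXPERIMENTS[[config$experiment]]
  fn <- get(fn_name, envir = asNamespace("replaymap"))
  params <- config$params %||% list()
  fml <- names(formals(fn))
  if (!"..." %in% fml) {
    bad_par <- setdiff(names(params), fml)
    if (length(bad_par)) {
      stop("unknown parameter for ", config$experiment, ": ", paste(bad_par, collapse = ", "))
    }
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  result <- do.call(fn, params)
  manifest <- list(
    experiment = config$experiment,
    config_hash = rlang::hash(config[c("experiment", "seed", "params")]),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("replaymap")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  if (!is.null(config$out)) {
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    tbls <- if (is.data.frame(result)) list(result = result) else purrr::keep(result, is.data.frame)
    purrr::iwalk(tbls, function(tb, nm) {
      utils::write.csv(tb, file.path(config$out, paste0(nm, ".csv")), row.names = FALSE)
    })
    jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
      auto_unbox = TRUE
    )
  }
  list(result = result, manifest = manifest)
}

#' Bundled synthetic fixtures
#'
#' Builds a seeded population-plus-session bundle for tests and examples.
#' The tiny size (20 cells, 10 replays, 300 s) runs the full pipeline in
#' seconds; the standard size matches the simulated-session conditions
#' (600 cells, 100 replays, 3000 s).
#'
#' @param size `"tiny"` or `"standard"`.
#' @return List with `pop`, `session` and `size`.
#' @export
make_fixtures <- function(size = c("tiny", "standard")) {
  size <- match.arg(size)
  if (size == "tiny") {
    ent <- build_entorhinal_populations(
      arena_cm = 100, home_day1 = c(30, 30), home_day2 = c(70, 70),
      n_grid = 2, n_ovc = 4, n_sensory = 6, grid_spacing = 60,
      ovc_dist_range = c(0, 60)
    )
    pop <- build_conjunctive_population(ent)
    session <- simulate_replay_session(pop,
      n_replays = 10, t_range = c(10, 300),
      len_range = c(50, 100)
    )
  } else {
    ent <- build_entorhinal_populations()
    pop <- build_conjunctive_population(ent)
    session <- simulate_replay_session(pop)
  }
  list(pop = pop, session = session, size = size)
}
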