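# Shared fixture builders; everything is generated in code under fixed seeds.

empty_world <- function(width = 5, height = 5, reward = c(0, 0)) {
  sample_gridworld(width, height, 0, reward = reward)
}

# A dense population of Gaussian place-like cells tiling a square arena,
# used to test decoding with known ground truth.
tiling_population <- function(arena_cm = 100, bin_cm = 2, spacing_cm = 12,
                              sigma_cm = 8, peak_hz = 15) {
  n <- as.integer(arena_cm / bin_cm)
  ctrs <- as.matrix(expand.grid(
    x = seq(spacing_cm / 2, arena_cm, by = spacing_cm),
    y = seq(spacing_cm / 2, arena_cm, by = spacing_cm)
  ))
  xs <- (seq_len(n) - 0.5) * bin_cm
  maps <- array(0, dim = c(n, n, nrow(ctrs)))
  for (k in seq_len(nrow(ctrs))) {
    maps[, , k] <- peak_hz * outer(
      exp(-(xs - ctrs[k, 1])^2 / (2 * sigma_cm^2)),
      exp(-(xs - ctrs[k, 2])^2 / (2 * sigma_cm^2))
    )
  }
  list(maps = maps, centers = ctrs, bin_cm = bin_cm, arena_cm = arena_cm)
}
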