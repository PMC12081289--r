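# broom-style tidiers for the package's fitted/derived objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a rate map into a long tibble
#'
#' @param x A [ratemap()].
#' @param ... Unused.
#' @return Tibble `x, y, rate` with bin-centre coordinates.
#' @export
tidy.ratemap <- function(x, ...) {
  nx <- nrow(x$rate)
  ny <- ncol(x$rate)
  tibble::tibble(
    x = rep(x$origin[1] + bin_centers(nx, x$bin_size), times = ny),
    y = rep(x$origin[2] + bin_centers(ny, x$bin_size), each = nx),
    rate = as.numeric(x$rate)
  )
}

#' @rdname tidy.ratemap
#' @export
glance.ratemap <- function(x, ...) {
  tibble::tibble(
    n_bins = length(x$rate), bin_size = x$bin_size,
    peak_rate = max(x$rate, na.rm = TRUE),
    mean_rate = mean(x$rate, na.rm = TRUE),
    masked_frac = mean(is.na(x$rate))
  )
}

#' Tidy a fitted policy network
#'
#' @param x A `policy_net`.
#' @param ... Unused.
#' @return One row per layer with dimensions and weight norms.
#' @export
tidy.policy_net <- function(x, ...) {
  purrr::imap(x$net$layers, function(l, i) {
    tibble::tibble(
      layer = i, d_in = nrow(l$W), d_out = ncol(l$W),
      weight_norm = sqrt(sum(l$W^2))
    )
  }) |> purrr::list_rbind()
}

#' @rdname tidy.policy_net
#' @export
glance.policy_net <- function(x, ...) {
  tibble::tibble(
    task = x$task,
    n_layers = length(x$net$layers),
    n_parameters = sum(purrr::map_dbl(x$net$layers, ~ length(.x$W) + length(.x$b))),
    epochs = nrow(x$loss),
    final_loss = utils::tail(x$loss$loss, 1)
  )
}

#' Tidy a memory dump
#'
#' @param x A [kv_memory()].
#' @param ... Unused.
#' @return The columnar entry table from [memory_tbl()].
#' @export
tidy.kv_memory <- function(x, ...) memory_tbl(x)
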