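#' Tidy an isoquant fit
#'
#' @param x An `isoquant_fit`.
#' @param ... Unused.
#' @return A one-row tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @method tidy isoquant_fit
#' @export
tidy.isoquant_fit <- function(x, ...) {
  tibble::tibble(
    term = "L",
    estimate = x$L_hat,
    std.error = x$se_L,
    statistic = x$t_stat,
    p.value = x$p_value
  )
}

#' Glance at an isoquant fit
#'
#' @param x An `isoquant_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `sse`, `sigma`, `method`, `response`,
#'   `degenerate`.
#' @method glance isoquant_fit
#' @export
glance.isoquant_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    sse = x$sse,
    sigma = if (x$n > 1) sqrt(x$sse / (x$n - 1)) else NA_real_,
    method = x$method,
    response = x$response,
    degenerate = x$degenerate
  )
}
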