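#' Model evaluation metrics
#'
#' The three standard goodness-of-fit indices for paired observed (`o`) and
#' simulated (`p`) series:
#' * `rmse()` — root mean squared error, `sqrt(mean((o - p)^2))`, in the
#'   units of the series;
#' * `nse()` — Nash-Sutcliffe efficiency,
#'   `1 - sum((o - p)^2) / sum((o - mean(o))^2)`, in (-Inf, 1\];
#' * `agreement_index()` — index of agreement,
#'   `1 - sum((o - p)^2) / sum((abs(p - mean(o)) + abs(o - mean(o)))^2)`,
#'   bounded in \[0, 1\].
#'
#' A perfect simulation gives `rmse = 0`, `nse = 1`, `agreement_index = 1`;
#' simulating the observed mean gives `nse = 0`.
#'
#' @param o,p Numeric vectors of observed and simulated values, equal length;
#'   pairs with missing values are dropped.
#' @return A single numeric value.
#' @examples
#' o <- c(1, 3, 5); p <- c(1.2, 2.9, 4.7)
#' rmse(o, p); nse(o, p); agreement_index(o, p)
#' @name eval-metrics
NULL

paired <- function(o, p) {
  if (length(o) != length(p)) {
    abort(paste0("length mismatch: ", length(o), " observed vs ",
                 length(p), " simulated values."))
  }
  keep <- !is.na(o) & !is.na(p)
  list(o = o[keep], p = p[keep])
}

#' @rdname eval-metrics
#' @export
rmse <- function(o, p) {
  s <- paired(o, p)
  if (length(s$o) < 1L) abort("at least one paired value is required.")
  sqrt(mean((s$o - s$p)^2))
}

#' @rdname eval-metrics
#' @export
nse <- function(o, p) {
  s <- paired(o, p)
  if (length(s$o) < 2L) abort("at least two paired values are required.")
  den <- sum((s$o - mean(s$o))^2)
  if (den == 0) abort("constant observations: Nash-Sutcliffe efficiency undefined.")
  1 - sum((s$o - s$p)^2) / den
}

#' @rdname eval-metrics
#' @export
agreement_index <- function(o, p) {
  s <- paired(o, p)
  if (length(s$o) < 2L) abort("at least two paired values are required.")
  obar <- mean(s$o)
  den <- sum((abs(s$p - obar) + abs(s$o - obar))^2)
  if (den == 0) abort("zero potential error: index of agreement undefined.")
  1 - sum((s$o - s$p)^2) / den
}

#' All three evaluation metrics at once
#'
#' @param o,p Observed and simulated vectors.
#' @return A one-row tibble `n, rmse, d, e`.
#' @examples
#' eval_metrics(c(1, 3, 5), c(1.2, 2.9, 4.7))
#' @export
eval_metrics <- function(o, p) {
  s <- paired(o, p)
  tibble::tibble(n = length(s$o), rmse = rmse(s$o, s$p),
                 d = agreement_index(s$o, s$p), e = nse(s$o, s$p))
}
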