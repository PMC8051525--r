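#' Pearson correlation with t statistic
#'
#' Product-moment correlation between out-of-sample predictions and actual
#' scores, with the exact-t significance test:
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom,
#' two-sided.  A constant vector (e.g. the output of a tree pruned to its
#' root) leaves `r` undefined: the row is returned with `NA` correlation
#' and `p = NA`, flagged `degenerate`, with a warning — reported as
#' non-significant, never as a silent zero.  A perfect correlation
#' (`r^2 = 1`) yields `t = +/-Inf` and `p = 0`.
#'
#' @param pred,actual equal-length numeric vectors, `n >= 3`.
#' @return A one-row tibble: `r`, `t`, `df`, `p`, `n`, `degenerate`.
#' @examples
#' pearson_with_t(c(1, 3, 2, 5, 4, 6), c(2, 3, 4, 5, 6, 7))
#' t_from_r(0.68, 12)  # 2.94
#' @export
pearson_with_t <- function(pred, actual) {
  stopifnot(length(pred) == length(actual))
  n <- length(pred)
  if (n < 3L) stop("need n >= 3 for a correlation test", call. = FALSE)
  ok <- is.finite(pred) & is.finite(actual)
  if (!all(ok)) stop("non-finite values in pred/actual", call. = FALSE)
  if (stats::sd(pred) == 0 || stats::sd(actual) == 0) {
    warning("constant vector: Pearson correlation undefined (degenerate model)")
    return(tibble::tibble(r = NA_real_, t = NA_real_, df = n - 2L, p = NA_real_,
                          n = n, degenerate = TRUE))
  }
  r <- stats::cor(pred, actual)
  t <- t_from_r(r, n)
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df = n - 2L)
  tibble::tibble(r = r, t = t, df = n - 2L, p = p, n = n, degenerate = FALSE)
}

#' @rdname pearson_with_t
#' @param r correlation coefficient.
#' @param n sample size.
#' @return `t_from_r()`: the t statistic on `n - 2` degrees of freedom
#'   (`+/-Inf` when `r^2 = 1`).
#' @export
t_from_r <- function(r, n) {
  stopifnot(abs(r) <= 1, n >= 3)
  # 1 - r^2 at rounding level means an exactly collinear pair: cap at Inf
  ifelse(1 - r^2 < 1e-12, sign(r) * Inf, r * sqrt(n - 2) / sqrt(1 - r^2))
}
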