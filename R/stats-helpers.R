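# Internal statistical helpers shared by the screen, deg and survival modules.

#' Two-sample t statistic with explicit degenerate-case contract
#'
#' Closed-form Welch (default) or pooled two-sample t test. Unlike
#' [stats::t.test()], zero-variance inputs are handled by contract rather
#' than by error: when both groups are constant with equal means the result
#' is `t = 0, p = 1`; when the standard error is zero but the means differ,
#' `t` is signed infinity and `p = 0`.
#'
#' @param x,y numeric vectors (NAs removed by the caller), each of length >= 2.
#' @param var_equal pool the variances (classic Student form) instead of the
#'   Welch--Satterthwaite form.
#' @return list with `t_stat`, `df`, `p_value` (two-sided).
#' @keywords internal
#' @noRd
welch_t <- function(x, y, var_equal = FALSE) {
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  d <- m1 - m2
  if (se2 == 0) {
    if (d == 0) return(list(t_stat = 0, df = NA_real_, p_value = 1))
    return(list(t_stat = sign(d) * Inf, df = NA_real_, p_value = 0))
  }
  t <- d / sqrt(se2)
  list(t_stat = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

# -log10(p) with the p floored at the smallest positive double, so volcano
# coordinates stay finite even for underflowed p-values.
neg_log10 <- function(p) -log10(pmax(p, .Machine$double.xmin))

# Derive a per-stream seed from a user seed and a stream index, kept inside
# the 32-bit range set.seed() accepts. Streams stay reproducible when the
# surrounding objects are reordered.
stream_seed <- function(seed, i) {
  (as.numeric(seed) + 7919 * as.numeric(i)) %% 2147483647
}
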