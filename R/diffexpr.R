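#' Per-feature two-sample statistics on a log2 expression matrix
#'
#' Computes, for every feature, group means, the log2 fold change (case
#' minus control), the two-sample t statistic and its two-sided p-value.
#' The default is the pooled-variance Student t, which is exactly calibrated
#' under the equal-variance Gaussian noise model of the synthetic cohorts;
#' with strongly unbalanced designs (such as 23 cases vs 6 controls) the
#' Welch approximation is anti-conservative in the far tail, which inflates
#' the realized false discovery rate, so Welch (`var_equal = FALSE`) is kept
#' as an option rather than the default. A variance floor (`eps`) keeps the
#' statistic finite for degenerate zero-variance features.
#'
#' @param m Numeric matrix, features x samples, log2 scale.
#' @param labels Group label per column of `m`.
#' @param case,control The two label values being contrasted.
#' @param var_equal Pooled-variance Student t (default) or Welch t with
#'   Satterthwaite degrees of freedom.
#' @param eps Variance floor.
#' @return Data frame (one row per feature): `feature`, `mean_case`,
#'   `mean_control`, `log2fc`, `fc` (signed ratio `2^log2fc`), `t`, `df`,
#'   `p`, `direction` (+1/-1).
#' @export
two_sample_stats <- function(m, labels, case = "ILD", control = "control",
                             var_equal = TRUE, eps = 1e-9) {
  if (!is.matrix(m)) stop("'m' must be a matrix")
  if (length(labels) != ncol(m)) stop("'labels' must match the sample columns")
  i1 <- which(labels == case); i2 <- which(labels == control)
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 samples")
  x1 <- m[, i1, drop = FALSE]; x2 <- m[, i2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- pmax(rowSums((x1 - m1)^2) / (n1 - 1L), eps)
  v2 <- pmax(rowSums((x2 - m2)^2) / (n2 - 1L), eps)
  if (var_equal) {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se <- sqrt(pmax(sp2, eps) * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2L, nrow(m))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  }
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  lfc <- m1 - m2
  data.frame(feature = rownames(m) %||% as.character(seq_len(nrow(m))),
             mean_case = m1, mean_control = m2,
             log2fc = lfc, fc = 2^lfc, t = t, df = df, p = p,
             direction = ifelse(lfc >= 0, 1L, -1L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Positive false discovery rate (pFDR) q-values
#'
#' Storey-style q-values: the null proportion is estimated as
#' `pi0 = min(1, mean(p > lambda) / (1 - lambda))` (floored at `1/m`), and
#' `q` for the i-th ordered p-value is the running minimum of
#' `pi0 * m * p_(j) / j` over `j >= i`. With `pi0 = 1` this reduces exactly
#' to Benjamini-Hochberg step-up adjusted p-values.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param lambda Tuning parameter in \[0, 1) for the pi0 estimate.
#' @param pi0 Optional: force the null proportion (e.g. `pi0 = 1` for plain
#'   BH) instead of estimating it.
#' @return Numeric vector of q-values, in the input order, with attribute
#'   `pi0`.
#' @export
qvalues_pfdr <- function(p, lambda = 0.5, pi0 = NULL) {
  if (length(p) == 0L) stop("empty p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (lambda < 0 || lambda >= 1) stop("'lambda' must lie in [0, 1)")
  m <- length(p)
  if (is.null(pi0)) pi0 <- min(1, mean(p > lambda) / (1 - lambda))
  pi0 <- min(1, max(pi0, 1 / m))
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  attr(q, "pi0") <- pi0
  q
}

#' Call differential features by fold change and q-value
#'
#' A feature is differentially expressed when its fold change is at least
#' `fc_min` in either direction (`|log2fc| >= log2(fc_min)`) and its q-value
#' is strictly below `q_max`.
#'
#' @param records Data frame from [two_sample_stats()] with a `q` column
#'   added (see [qvalues_pfdr()]).
#' @param fc_min Minimum fold change (>= 1).
#' @param q_max q-value cutoff (strict inequality).
#' @return List with `records` (input plus logical `is_de`), `up` and `down`
#'   (character vectors of feature ids partitioned by direction).
#' @export
call_differential <- function(records, fc_min = 1.5, q_max = 0.1) {
  if (fc_min < 1) stop("'fc_min' must be >= 1")
  if (is.null(records$q)) stop("records need a 'q' column; see qvalues_pfdr()")
  records$is_de <- abs(records$log2fc) >= log2(fc_min) & records$q < q_max
  list(records = records,
       up = records$feature[records$is_de & records$direction > 0],
       down = records$feature[records$is_de & records$direction < 0])
}

#' One-call differential expression for a matrix
#'
#' Convenience wrapper: [two_sample_stats()] + [qvalues_pfdr()] +
#' [call_differential()].
#'
#' @inheritParams two_sample_stats
#' @inheritParams call_differential
#' @param lambda Passed to [qvalues_pfdr()].
#' @return As [call_differential()], with `q` filled in `records`.
#' @export
differential_expression <- function(m, labels, case = "ILD",
                                    control = "control", var_equal = TRUE,
                                    fc_min = 1.5, q_max = 0.1, lambda = 0.5) {
  rec <- two_sample_stats(m, labels, case = case, control = control,
                          var_equal = var_equal)
  rec$q <- as.numeric(qvalues_pfdr(rec$p, lambda = lambda))
  call_differential(rec, fc_min = fc_min, q_max = q_max)
}
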