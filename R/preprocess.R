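#' Quantile normalization of an expression matrix
#'
#' Forces every sample (column) to share the same intensity distribution:
#' each value is replaced by the cross-sample mean of its rank's order
#' statistic. Ties within a column receive the mean of the reference values
#' over their rank range, so the transform is deterministic and preserves
#' within-column ordering.
#'
#' @param m Numeric matrix, features x samples (>= 2 columns).
#' @return Matrix of the same shape and dimnames. On tie-free input, every
#'   column holds the identical multiset of values.
#' @export
quantile_normalize <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("'m' must be a numeric matrix")
  if (ncol(m) < 2L) stop("quantile normalization requires >= 2 samples")
  if (anyNA(m) || any(!is.finite(m))) stop("'m' contains NA or non-finite values")
  target <- rowMeans(apply(m, 2L, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    o <- order(m[, j])
    xs <- m[o, j]
    grp <- cumsum(c(TRUE, diff(xs) != 0))      # runs of tied values
    out[o, j] <- stats::ave(target, grp)
  }
  out
}

#' Present/absent calls from a two-component Gaussian mixture
#'
#' Fits a one-dimensional, two-component, equal-variance Gaussian mixture to
#' the per-feature mean log2 intensities by EM, and calls a feature
#' "present" when its posterior probability of the high component exceeds
#' 0.5. Initialization splits the data at the median (deterministic, no
#' random restarts). If EM fails to converge within `max_iter`, or the fit
#' is degenerate (components closer than two within-component sds, or one
#' component nearly empty — the spurious splits EM produces on effectively
#' unimodal data), the routine warns and falls back to a median threshold.
#'
#' @param m Numeric matrix, features x samples (>= 10 features).
#' @param em_tol Convergence tolerance on the log-likelihood.
#' @param max_iter Maximum EM iterations.
#' @return Object of class `presence_calls`: data frame with `feature`,
#'   `mean_log2`, `posterior_present`, `call` plus attributes `mu_low`,
#'   `mu_high`, `sigma`, `weight_high`, `loglik_trace`, `converged`,
#'   `degenerate`, `fallback`.
#' @export
call_presence <- function(m, em_tol = 1e-8, max_iter = 500L) {
  if (!is.matrix(m) || nrow(m) < 10L)
    stop("presence calling requires a matrix with >= 10 features")
  y <- rowMeans(m)
  fit <- em_gmm2(y, tol = em_tol, max_iter = max_iter)
  ## a split is only trusted when the components are bimodally separated
  ## (>= 2 within-component sds apart); unimodal data produce spurious
  ## sub-sd splits under the equal-variance EM
  degenerate <- (fit$mu_high - fit$mu_low) < 2 * fit$sigma ||
    min(fit$w, 1 - fit$w) < 1 / (2 * length(y))
  fallback <- degenerate || !fit$converged
  if (fallback) {
    if (!fit$converged)
      warning("EM did not converge; falling back to median threshold")
    else
      warning("degenerate mixture fit; falling back to median threshold")
    post <- as.numeric(y > stats::median(y))
  } else {
    post <- fit$posterior_high
  }
  res <- data.frame(
    feature = rownames(m) %||% as.character(seq_along(y)),
    mean_log2 = y,
    posterior_present = post,
    call = ifelse(post > 0.5, "present", "absent"),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "mu_low") <- fit$mu_low
  attr(res, "mu_high") <- fit$mu_high
  attr(res, "sigma") <- fit$sigma
  attr(res, "weight_high") <- fit$w
  attr(res, "loglik_trace") <- fit$loglik_trace
  attr(res, "converged") <- fit$converged
  attr(res, "degenerate") <- degenerate
  attr(res, "fallback") <- fallback
  class(res) <- c("presence_calls", "data.frame")
  res
}

## EM for a 1-D two-component equal-variance Gaussian mixture.
## w is the weight of the HIGH component.
em_gmm2 <- function(y, tol = 1e-8, max_iter = 500L) {
  med <- stats::median(y)
  lo <- y[y <= med]; hi <- y[y > med]
  mu1 <- mean(lo); mu2 <- if (length(hi)) mean(hi) else mu1
  sigma <- max(stats::sd(y), .Machine$double.eps)
  w <- 0.5
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  post <- rep(0.5, length(y))
  for (it in seq_len(max_iter)) {
    d1 <- (1 - w) * stats::dnorm(y, mu1, sigma)
    d2 <- w * stats::dnorm(y, mu2, sigma)
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    post <- d2 / tot
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    w <- mean(post)
    if (w <= 0 || w >= 1) break
    mu1 <- sum((1 - post) * y) / sum(1 - post)
    mu2 <- sum(post * y) / sum(post)
    sigma <- sqrt(sum((1 - post) * (y - mu1)^2 + post * (y - mu2)^2) /
                    length(y))
    sigma <- max(sigma, .Machine$double.eps)
  }
  if (mu1 > mu2) {        # keep the high component on top
    tmp <- mu1; mu1 <- mu2; mu2 <- tmp
    w <- 1 - w
    post <- 1 - post
  }
  list(mu_low = mu1, mu_high = mu2, sigma = sigma, w = w,
       posterior_high = post, loglik_trace = trace, converged = converged)
}

#' Apply the present-feature filter
#'
#' mRNA matrices are restricted to features called "present"; miRNA matrices
#' are returned unmodified whatever the calls say (all miRNA probes are kept
#' for analysis).
#'
#' @param m Numeric matrix, features x samples.
#' @param calls A [call_presence()] result aligned to `m`.
#' @param kind `"mRNA"` or `"miRNA"`.
#' @return The filtered (or untouched) matrix.
#' @export
apply_presence_filter <- function(m, calls, kind = c("mRNA", "miRNA")) {
  kind <- match.arg(kind)
  if (kind == "miRNA") return(m)
  if (!setequal(calls$feature, rownames(m)))
    stop("presence calls do not match the matrix feature set")
  keep <- calls$feature[calls$call == "present"]
  m[rownames(m) %in% keep, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
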