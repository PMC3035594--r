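test_that("quantile normalization maps columns onto per-rank means", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  rownames(m) <- c("f1", "f2", "f3")
  out <- quantile_normalize(m)
  # per-rank cross-sample means computed by hand from the order statistics
  expect_equal(unname(out[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, "b"]), c(2.5, 3.5, 4.5))

  # identical columns are a fixed point
  m2 <- cbind(x = c(5, 1, 3), y = c(5, 1, 3))
  expect_equal(quantile_normalize(m2), m2)
})

test_that("quantile normalization properties: equal multisets, rank preservation, idempotence", {
  set.seed(21)
  m <- matrix(rnorm(300), 50, 6,
              dimnames = list(sprintf("f%02d", 1:50), sprintf("s%d", 1:6)))
  out <- quantile_normalize(m)
  for (j in 2:ncol(out))
    expect_equal(sort(out[, j]), sort(out[, 1]), ignore_attr = TRUE)
  for (j in seq_len(ncol(out)))
    expect_identical(order(out[, j]), order(m[, j]))
  expect_equal(quantile_normalize(out), out, tolerance = 1e-12)
  expect_error(quantile_normalize(m[, 1, drop = FALSE]), ">= 2")
  m[1, 1] <- NA
  expect_error(quantile_normalize(m), "NA")
})

test_that("tied values receive the mean of their rank-range targets", {
  m <- cbind(a = c(1, 1, 5), b = c(2, 4, 6))
  out <- quantile_normalize(m)
  target <- rowMeans(cbind(sort(m[, 1]), sort(m[, 2])))
  expect_equal(unname(out[, "a"]),
               c(mean(target[1:2]), mean(target[1:2]), target[3]))
  expect_equal(unname(out[, "b"]), unname(target))
})

test_that("quantile normalization agrees with limma on tie-free input", {
  set.seed(31)
  m <- matrix(rnorm(400), 80, 5)
  expect_equal(quantile_normalize(m),
               limma::normalizeQuantiles(m), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("mixture presence calls put the boundary midway for a symmetric mixture", {
  set.seed(41)
  y <- c(rnorm(1500, 4, 1), rnorm(1500, 10, 1))
  m <- matrix(rep(y, 3), ncol = 3)
  rownames(m) <- sprintf("f%04d", seq_along(y))
  calls <- call_presence(m)
  expect_false(attr(calls, "fallback"))
  # equal weights and variances: posterior crosses 0.5 at the midpoint (7)
  boundary <- (max(calls$mean_log2[calls$call == "absent"]) +
                 min(calls$mean_log2[calls$call == "present"])) / 2
  expect_lt(abs(boundary - 7), 0.2)
  # monotone decision in the mean
  expect_true(all(calls$mean_log2[calls$call == "present"] > boundary - 1e-9))
  expect_true(all(calls$mean_log2[calls$call == "absent"] < boundary + 1e-9))
})

test_that("mixture calls agree with an independent equal-variance GMM fit", {
  set.seed(59)
  y <- c(rnorm(800, 3, 1), rnorm(1200, 9, 1))
  m <- matrix(rep(y, 2), ncol = 2)
  rownames(m) <- sprintf("f%04d", seq_along(y))
  calls <- call_presence(m)
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller
  fit <- mclust::Mclust(y, G = 2, modelNames = "E", verbose = FALSE)
  ref <- ifelse(fit$classification ==
                  which.max(fit$parameters$mean), "present", "absent")
  expect_gte(mean(calls$call == ref), 0.995)
})

test_that("EM log-likelihood is monotonically non-decreasing", {
  set.seed(43)
  y <- c(rnorm(300, 3, 0.8), rnorm(500, 9, 0.8))
  m <- matrix(rep(y, 2), ncol = 2)
  rownames(m) <- sprintf("f%03d", seq_along(y))
  calls <- call_presence(m)
  ll <- attr(calls, "loglik_trace")
  expect_gt(length(ll), 2)
  expect_true(all(diff(ll) > -1e-8))
})

test_that("degenerate single-cluster input engages the median fallback", {
  set.seed(47)
  m <- matrix(rnorm(200 * 3, 8, 0.05), 200, 3,
              dimnames = list(sprintf("f%03d", 1:200), NULL))
  expect_warning(calls <- call_presence(m), "fallback|median|degenerate")
  expect_true(attr(calls, "fallback"))
  expect_equal(sort(unique(calls$call)), c("absent", "present"))
})

test_that("simulated absent features are recalled at high accuracy", {
  cfg <- sim_config(n_genes = 2000, n_mirnas = 10, n_de_genes = 20,
                    n_de_mirnas = 0, n_target_pairs_true = 0,
                    n_regulons = 0, n_ffls_planted = 0,
                    frac_absent = 0.3, baseline_mean = 8, absent_mean = 2,
                    baseline_sd = 1, seed = 13)
  co <- simulate_cohort(cfg)
  calls <- call_presence(co$mrna)
  planted <- ifelse(rownames(co$mrna) %in% co$truth$absent_genes,
                    "absent", "present")
  expect_gte(mean(calls$call == planted), 0.99)
})

test_that("the presence filter is an mRNA-only policy", {
  set.seed(53)
  m <- matrix(rnorm(600, 8), 100, 6,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%d", 1:6)))
  calls <- data.frame(feature = rownames(m),
                      mean_log2 = rowMeans(m),
                      posterior_present = rep(c(1, 0), 50),
                      call = rep(c("present", "absent"), 50))
  filtered <- apply_presence_filter(m, calls, kind = "mRNA")
  expect_equal(nrow(filtered), 50)
  expect_true(all(calls$call[match(rownames(filtered), calls$feature)] ==
                    "present"))
  # miRNA matrices pass through unmodified regardless of calls
  expect_identical(apply_presence_filter(m, calls, kind = "miRNA"), m)
  # all present -> identity
  calls$call <- "present"
  expect_identical(apply_presence_filter(m, calls, kind = "mRNA"), m)
  expect_error(apply_presence_filter(m[1:10, ], calls, kind = "mRNA"),
               "match")
})
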