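test_that("SAM d reproduces hand-computed values", {
  g <- toy_groups()
  expect_equal(unname(sam_statistic(g$x_t, g$x_n, s0 = 0)), -3.674235,
               tolerance = 1e-6)
  # s = 0.8165 here, so doubling the denominator halves d
  expect_equal(unname(sam_statistic(g$x_t, g$x_n, s0 = 0.8165)), -1.837,
               tolerance = 1e-3)
  same <- matrix(c(1, 2, 3), 1)
  expect_equal(unname(sam_statistic(same, same, s0 = 0.5)), 0)
  const <- matrix(c(1, 1, 1), 1)
  expect_error(sam_statistic(const, const, s0 = 0), "zero-variance")
})

test_that("SAM d with s0 = 0 equals the pooled t statistic exactly", {
  set.seed(31)
  for (i in 1:20) {
    x_t <- matrix(rnorm(40), 4)
    x_n <- matrix(rnorm(48), 4)
    d <- sam_statistic(x_t, x_n, s0 = 0)
    t_ref <- vapply(1:4, function(f) {
      stats::t.test(x_t[f, ], x_n[f, ], var.equal = TRUE)$statistic
    }, numeric(1L))
    expect_equal(unname(d), unname(t_ref), tolerance = 1e-12)
  }
})

test_that("sam_test flags planted shifts and is seed-deterministic", {
  set.seed(5)
  x_t <- matrix(rnorm(300), 30)
  x_n <- matrix(rnorm(300), 30)
  x_t[1:5, ] <- x_t[1:5, ] + 3
  rownames(x_t) <- rownames(x_n) <- paste0("f", 1:30)
  res <- sam_test(x_t, x_n, n_perm = 50L, seed = 9L)
  expect_true(all(res$significant[1:5]))
  expect_lt(mean(res$significant[6:30]), 0.2)
  res2 <- sam_test(x_t, x_n, n_perm = 50L, seed = 9L)
  expect_identical(res, res2)
})

test_that("moderated t matches limma's empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(41)
  scale_f <- exp(rnorm(100, 0, 0.5))
  x_t <- matrix(rnorm(100 * 5), 100) * scale_f
  x_n <- matrix(rnorm(100 * 6), 100) * scale_f
  x_t[1:10, ] <- x_t[1:10, ] + 2
  rownames(x_t) <- rownames(x_n) <- paste0("f", 1:100)
  res <- moderated_t(x_t, x_n)

  design <- cbind(1, c(rep(1, 5), rep(0, 6)))
  fit <- limma::eBayes(limma::lmFit(cbind(x_t, x_n), design))
  expect_equal(unname(res$t), unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 1e-4)
  expect_equal(attr(res, "s0_sq"), fit$s2.prior, tolerance = 1e-4)
})

test_that("moderated t limits and degenerate inputs behave", {
  g <- toy_groups()
  two <- rbind(g$x_t, f2 = c(2, 3, 4))
  two_n <- rbind(g$x_n, f2 = c(5, 6, 7))
  res <- moderated_t(two, two_n)
  # identical per-feature variances: the prior has zero spread, d0 = Inf,
  # and both features share one moderated t on infinite df
  expect_equal(res$t[1], res$t[2], tolerance = 1e-12)
  expect_true(all(is.infinite(res$df)))
  expect_lt(res$t[1], -3)

  same <- matrix(rnorm(20), 2)
  rownames(same) <- c("a", "b")
  res0 <- moderated_t(same, same)
  expect_equal(res0$t, c(0, 0))
  expect_equal(res0$p, c(1, 1))

  const <- matrix(1, 2, 4, dimnames = list(c("a", "b"), NULL))
  expect_error(moderated_t(const, const), "zero variance")
})

test_that("AUC matches brute-force pair counting, including ties", {
  expect_equal(unname(auc_roc(c(5, 6, 7, 1, 2, 8),
                              c("tumor", "tumor", "tumor",
                                "normal", "normal", "normal"))),
               6 / 9, tolerance = 1e-12)
  expect_equal(unname(auc_roc(c(10, 11, 1, 2),
                              c("tumor", "tumor", "normal", "normal"))), 1)
  expect_equal(unname(auc_roc(c(3, 3, 3, 3),
                              c("tumor", "tumor", "normal", "normal"))),
               0.5)
  set.seed(17)
  labels <- rep(c("tumor", "normal"), c(12, 13))
  for (i in 1:25) {
    v <- sample(1:8, 25, replace = TRUE)  # heavy ties
    expect_equal(unname(auc_roc(v, labels)),
                 auc_pairs(v[labels == "tumor"], v[labels == "normal"]),
                 tolerance = 1e-12)
  }
  expect_error(auc_roc(1:3, rep("tumor", 3)), "both classes")
})

test_that("vote requires at least two of three methods and is monotone", {
  mk_sam <- function(sig) data.frame(feature = paste0("f", 1:3),
                                     d = 1, q = ifelse(sig, 0.01, 0.5),
                                     significant = sig)
  mk_modt <- function(sig) data.frame(feature = paste0("f", 1:3),
                                      t = 1, df = 5, p = 0.5,
                                      p_adj = ifelse(sig, 0.01, 0.5))
  x_t <- matrix(2, 3, 3, dimnames = list(paste0("f", 1:3), NULL))
  x_n <- matrix(1, 3, 3, dimnames = list(paste0("f", 1:3), NULL))
  auc <- stats::setNames(c(0.9, 0.5, 0.1), paste0("f", 1:3))
  # f1: sam+auc (T,F,T) -> vote; f2: sam only -> no; f3: modt+auc -> vote
  calls <- vote_calls(mk_sam(c(TRUE, TRUE, FALSE)),
                      mk_modt(c(FALSE, FALSE, TRUE)), auc, x_t, x_n)
  expect_identical(calls$vote, c(TRUE, FALSE, TRUE))
  expect_true(all(calls$direction == "up"))
  # adding a method flag never un-flags a feature
  more <- vote_calls(mk_sam(c(TRUE, TRUE, TRUE)),
                     mk_modt(c(TRUE, TRUE, TRUE)), auc, x_t, x_n)
  expect_true(all(more$vote >= calls$vote))
  # all three agree
  expect_true(all(vote_calls(mk_sam(rep(TRUE, 3)), mk_modt(rep(TRUE, 3)),
                             stats::setNames(rep(0.95, 3),
                                             paste0("f", 1:3)),
                             x_t, x_n)$vote))
  bad <- mk_modt(rep(TRUE, 3))
  bad$feature[1] <- "other"
  expect_error(vote_calls(mk_sam(rep(TRUE, 3)), bad, auc, x_t, x_n),
               "feature ids differ")
})

test_that("vote recovers planted DE features on the synthetic cohort", {
  b <- test_bundle()
  de <- differential_analysis(b$cohort$expr, b$cohort$group, seed = 11L)
  called <- de$feature[de$vote]
  sens <- mean(b$truth$de_genes %in% called)
  fdr <- if (length(called) > 0) mean(!(called %in% b$truth$de_genes)) else 0
  expect_gte(sens, 0.90)
  expect_lte(fdr, 0.10)
  # directions match the planted truth for the called true positives
  tp <- intersect(called, b$truth$de_genes)
  dir_called <- de$direction[match(tp, de$feature)]
  expect_gte(mean(dir_called == b$truth$de_direction[tp]), 0.95)
})
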