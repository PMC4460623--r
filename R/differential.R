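## Two-group differential analysis by three methods -- a SAM-type
## permutation statistic, an empirical-Bayes moderated t-test, and
## AUC-ROC -- combined by a two-of-three majority vote. The vote, not any
## single cutoff, is the decision mechanism; per-method thresholds are
## conventional defaults and fully configurable.

pooled_se <- function(x_tumor, x_normal) {
  n1 <- ncol(x_tumor)
  n2 <- ncol(x_normal)
  v1 <- apply(x_tumor, 1L, stats::var)
  v2 <- apply(x_normal, 1L, stats::var)
  pooled <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  sqrt(pooled * (1 / n1 + 1 / n2))
}

#' SAM relative-difference statistic
#'
#' `d = (mean_tumor - mean_normal) / (s + s0)` where `s` is the pooled
#' two-sample standard error and `s0` a variance-stabilizing fudge factor.
#' With `s0 = 0`, `d` is the ordinary pooled t statistic.
#'
#' @param x_tumor,x_normal Numeric matrices (features x samples), same
#'   rownames.
#' @param s0 Non-negative fudge factor.
#' @return Named numeric vector of d statistics.
#' @export
sam_statistic <- function(x_tumor, x_normal, s0 = 0) {
  stopifnot(ncol(x_tumor) >= 2L, ncol(x_normal) >= 2L, s0 >= 0)
  s <- pooled_se(x_tumor, x_normal)
  if (s0 == 0 && any(s == 0)) {
    stop("zero-variance feature with s0 = 0; supply a positive fudge factor")
  }
  (rowMeans(x_tumor) - rowMeans(x_normal)) / (s + s0)
}

#' SAM significance by label-permutation FDR
#'
#' For every feature's `|d|` taken as a cutoff, the observed count is the
#' number of features at or beyond the cutoff and the expected false count
#' is the median over label permutations of the same tally; their ratio is
#' the feature's q-value (capped at 1).
#'
#' @param x_tumor,x_normal Feature matrices.
#' @param s0 Fudge factor; `NULL` means the median of per-feature pooled
#'   standard errors (`s0_quantile` of them, default the median).
#' @param n_perm Number of label permutations.
#' @param q_threshold Significance cutoff on the q-value.
#' @param s0_quantile Quantile of `s` used when `s0` is `NULL`.
#' @param seed Integer seed for the permutation draw.
#' @return Data frame: feature, d, q, significant.
#' @export
sam_test <- function(x_tumor, x_normal, s0 = NULL, n_perm = 100L,
                     q_threshold = 0.05, s0_quantile = 0.5, seed = 1L) {
  stopifnot(n_perm >= 1L)
  if (is.null(s0)) {
    s0 <- stats::quantile(pooled_se(x_tumor, x_normal), s0_quantile,
                          names = FALSE)
  }
  d <- sam_statistic(x_tumor, x_normal, s0)
  x <- cbind(x_tumor, x_normal)
  n1 <- ncol(x_tumor)
  n <- ncol(x)
  abs_d <- abs(d)
  perm_counts <- matrix(0L, nrow = n_perm, ncol = length(d))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n)
      dp <- sam_statistic(x[, idx[seq_len(n1)], drop = FALSE],
                          x[, idx[-seq_len(n1)], drop = FALSE], s0)
      # count permuted |d| >= each observed cutoff via sorted lookup
      sdp <- sort(abs(dp))
      perm_counts[b, ] <- length(dp) -
        findInterval(abs_d, sdp, left.open = TRUE)
    }
  })
  expected_false <- apply(perm_counts, 2L, stats::median)
  observed <- vapply(abs_d, function(cut) sum(abs_d >= cut), integer(1L))
  q <- pmin(1, expected_false / observed)
  data.frame(feature = names(d), d = unname(d), q = unname(q),
             significant = unname(q < q_threshold),
             stringsAsFactors = FALSE)
}

# Newton inversion of trigamma, used by the moderated-t prior fit
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif) / y < 1e-8) break
    }
    y
  }, numeric(1L))
}

#' Empirical-Bayes moderated t-test
#'
#' Per-feature pooled variances are shrunk toward a prior fitted by method
#' of moments on `log(s^2)` under a scaled-F model (`s^2 ~ s0^2 F(d, d0)`):
#' `s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d)`, with the t statistic on
#' `d0 + d` degrees of freedom and Benjamini-Hochberg adjustment across
#' features.
#'
#' @param x_tumor,x_normal Feature matrices with >= 2 samples per group;
#'   >= 2 features are needed to estimate the prior.
#' @return Data frame: feature, t, df, p, p_adj, plus attributes `d0` and
#'   `s0_sq` (the fitted prior).
#' @export
moderated_t <- function(x_tumor, x_normal) {
  stopifnot(nrow(x_tumor) >= 2L, ncol(x_tumor) >= 2L, ncol(x_normal) >= 2L)
  n1 <- ncol(x_tumor)
  n2 <- ncol(x_normal)
  d <- n1 + n2 - 2
  v1 <- apply(x_tumor, 1L, stats::var)
  v2 <- apply(x_normal, 1L, stats::var)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
  ok <- s2 > 0
  if (!any(ok)) stop("all features have zero variance")
  z <- log(s2[ok])
  e_logF <- digamma(d / 2) - log(d / 2)
  resid_var <- stats::var(z) - trigamma(d / 2)
  if (is.na(resid_var) || resid_var <= 0) {
    d0 <- Inf
    s0_sq <- exp(mean(z) - e_logF)
  } else {
    d0 <- 2 * trigamma_inverse(resid_var)
    s0_sq <- exp(mean(z) - e_logF + digamma(d0 / 2) - log(d0 / 2))
  }
  if (is.finite(d0)) {
    s2_tilde <- (d0 * s0_sq + d * s2) / (d0 + d)
  } else {
    s2_tilde <- rep(s0_sq, length(s2))
  }
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  t_mod <- (rowMeans(x_tumor) - rowMeans(x_normal)) / se
  df_total <- d0 + d
  p <- 2 * stats::pt(abs(t_mod), df = df_total, lower.tail = FALSE)
  out <- data.frame(feature = rownames(x_tumor), t = unname(t_mod),
                    df = df_total, p = unname(p),
                    p_adj = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

#' Per-feature AUC-ROC between tumor and normal samples
#'
#' Mann-Whitney rank-sum form with ties counted one half; tumor is the
#' positive class, so AUC > 0.5 means higher values in tumors.
#'
#' @param values Numeric matrix (features x samples) or vector.
#' @param labels Character/factor vector over samples with levels tumor /
#'   normal (tumor positive).
#' @return Named numeric vector of AUCs.
#' @export
auc_roc <- function(values, labels) {
  if (is.vector(values)) values <- matrix(values, nrow = 1L)
  pos <- labels == "tumor"
  n1 <- sum(pos)
  n2 <- sum(!pos)
  if (n1 == 0L || n2 == 0L) stop("both classes must be present")
  apply(values, 1L, function(v) {
    r <- rank(v)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  })
}

#' Two-of-three majority vote over the three methods
#'
#' @param sam Data frame from [sam_test()].
#' @param modt Data frame from [moderated_t()].
#' @param auc Named AUC vector from [auc_roc()].
#' @param x_tumor,x_normal Feature matrices (for the direction call).
#' @param modt_p Adjusted-p cutoff for the moderated t flag.
#' @param auc_hi,auc_lo AUC flag thresholds (flag iff `auc >= auc_hi` or
#'   `auc <= auc_lo`).
#' @return `DifferentialCall` data frame: feature, d_sam, q_sam, t_mod,
#'   p_mod_adj, auc, sig_sam, sig_modt, sig_auc, vote, direction.
#' @export
vote_calls <- function(sam, modt, auc, x_tumor, x_normal,
                       modt_p = 0.05, auc_hi = 0.8, auc_lo = 0.2) {
  feats <- sam$feature
  if (!identical(sort(feats), sort(modt$feature)) ||
      !identical(sort(feats), sort(names(auc)))) {
    stop("feature ids differ between the three methods")
  }
  modt <- modt[match(feats, modt$feature), ]
  auc <- auc[feats]
  sig_auc <- auc >= auc_hi | auc <= auc_lo
  sig_modt <- modt$p_adj < modt_p
  n_flags <- sam$significant + sig_modt + sig_auc
  delta <- rowMeans(x_tumor)[feats] - rowMeans(x_normal)[feats]
  data.frame(
    feature = feats,
    d_sam = sam$d, q_sam = sam$q,
    t_mod = modt$t, p_mod_adj = modt$p_adj,
    auc = unname(auc),
    sig_sam = sam$significant, sig_modt = sig_modt,
    sig_auc = unname(sig_auc),
    vote = n_flags >= 2L,
    direction = ifelse(delta >= 0, "up", "down"),
    stringsAsFactors = FALSE
  )
}

#' Run the full three-method differential analysis on one omics layer
#'
#' @param mat Feature matrix (features x samples).
#' @param group Named group vector over the matrix columns
#'   (tumor/normal).
#' @param sam_q,modt_p,auc_hi,auc_lo,n_perm,s0 Method parameters; see
#'   [sam_test()] and [vote_calls()].
#' @param seed Seed for SAM permutations.
#' @return `DifferentialCall` data frame (see [vote_calls()]).
#' @export
differential_analysis <- function(mat, group, sam_q = 0.05, modt_p = 0.05,
                                  auc_hi = 0.8, auc_lo = 0.2,
                                  n_perm = 100L, s0 = NULL, seed = 1L) {
  group <- group[colnames(mat)]
  x_t <- mat[, group == "tumor", drop = FALSE]
  x_n <- mat[, group == "normal", drop = FALSE]
  sam <- sam_test(x_t, x_n, s0 = s0, n_perm = n_perm,
                  q_threshold = sam_q, seed = seed)
  modt <- moderated_t(x_t, x_n)
  auc <- auc_roc(mat, group)
  vote_calls(sam, modt, auc, x_t, x_n, modt_p = modt_p,
             auc_hi = auc_hi, auc_lo = auc_lo)
}
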