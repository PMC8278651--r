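#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties). Returns `NA`
#' with a warning when either variable has zero rank variance.
#'
#' @param x,y numeric vectors
#' @return rho
#' @export
spearman_rho <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (var(rank(x)) == 0 || var(rank(y)) == 0) {
    warning("zero variance: Spearman correlation undefined")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' Partial Spearman correlation
#'
#' All variables are rank-transformed (mid-ranks); the partial correlation
#' of x and y given the covariates is read off the inverse of the rank
#' correlation matrix: rho = -P12 / sqrt(P11 P22).
#'
#' @param x,y numeric vectors
#' @param covariates data frame or matrix of control variables
#' @return list with `rho`, `n` (complete cases), `s` (number of covariates)
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  cov_m <- if (is.null(covariates)) NULL else as.matrix(covariates)
  s <- if (is.null(cov_m)) 0L else ncol(cov_m)
  dat <- cbind(x, y, cov_m)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n <= s + 3) stop("need n > s + 3 complete observations")
  if (s == 0)
    return(list(rho = spearman_rho(dat[, 1], dat[, 2]), n = n, s = 0L))
  ranks <- apply(dat, 2, rank)
  R <- cor(ranks)
  P <- tryCatch(solve(R), error = function(e)
    stop("singular rank-correlation matrix (condition number ",
         signif(kappa(R), 3), ")"))
  list(rho = -P[1, 2] / sqrt(P[1, 1] * P[2, 2]), n = n, s = s)
}

# Paule-Mandel tau2: solve sum w_i(t) (y_i - ybar(t))^2 = k - 1 with
# w_i = 1/(v_i + t); the generalized Q is decreasing in t, so tau2 = 0
# whenever Q(0) <= k - 1, otherwise a root exists and is found by uniroot
paule_mandel_tau2 <- function(y, v, tol = 1e-12) {
  k <- length(y)
  qfun <- function(t) {
    w <- 1 / (v + t)
    yb <- sum(w * y) / sum(w)
    sum(w * (y - yb)^2) - (k - 1)
  }
  if (qfun(0) <= 0) return(0)
  upper <- var(y)
  while (qfun(upper) > 0) upper <- upper * 2
  uniroot(qfun, c(0, upper), tol = tol)$root
}

# inverse-variance pooling with the given tau2; returns effect, se
pool_fixed <- function(y, v, tau2 = 0) {
  w <- 1 / (v + tau2)
  est <- sum(w * y) / sum(w)
  list(est = est, se = sqrt(1 / sum(w)))
}

#' Random-effects meta-analysis of (partial) correlations
#'
#' Per-study correlations are Fisher-Z transformed (z = atanh(rho)) with
#' variance 1/(n - s - 3) (the partial-correlation convention of `pcor`-style
#' tooling; the small Spearman-specific variance inflation is deliberately
#' omitted, see the package vignette); between-study variance is estimated
#' with the Paule-Mandel moment estimator; the pooled effect is
#' back-transformed with tanh and the Wald CI and p-value are computed on the
#' Z scale.
#'
#' @param studies data frame with columns `rho`, `n` and optionally `s`
#'   (covariates controlled; default 0)
#' @param conf_level confidence level (default 0.95)
#' @return an object of class `akk_meta`: per-study table, `pooled_rho`,
#'   `ci`, `p`, `tau2`, `k`
#' @export
meta_pool_correlations <- function(studies, conf_level = 0.95) {
  stopifnot(all(c("rho", "n") %in% names(studies)))
  s <- if ("s" %in% names(studies)) studies$s else rep(0L, nrow(studies))
  ok <- studies$n > s + 3
  if (!all(ok)) {
    warning(sum(!ok), " study(ies) dropped: n <= s + 3")
    studies <- studies[ok, , drop = FALSE]; s <- s[ok]
  }
  k <- nrow(studies)
  if (k == 0) stop("no usable studies")
  z <- atanh(studies$rho)
  v <- 1 / (studies$n - s - 3)
  if (k == 1) {
    est <- z[1]; se <- sqrt(v[1]); tau2 <- NA_real_
  } else {
    tau2 <- paule_mandel_tau2(z, v)
    p <- pool_fixed(z, v, tau2)
    est <- p$est; se <- p$se
  }
  zcrit <- qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    studies = data.frame(rho = studies$rho, n = studies$n, s = s, z = z, v = v),
    pooled_rho = tanh(est), pooled_z = est, se_z = se,
    ci = tanh(c(est - zcrit * se, est + zcrit * se)),
    p = 2 * pnorm(-abs(est / se)), tau2 = tau2, k = k,
    method = "Fisher-Z / Paule-Mandel random effects"), class = "akk_meta")
}

#' @export
print.akk_meta <- function(x, ...) {
  cat("<akk_meta>", x$method, "\n")
  cat(sprintf("k = %d, pooled effect = %.4f [%.4f, %.4f], tau2 = %s, p = %.3g\n",
              x$k, x$pooled_rho, x$ci[1], x$ci[2],
              ifelse(is.na(x$tau2), "NA", sprintf("%.4f", x$tau2)), x$p))
  invisible(x)
}

#' Pool covariate-adjusted standardized mean differences across studies
#'
#' Per study, the outcome (e.g. clade abundance) is regressed on the
#' covariates plus the binary group indicator by OLS; the standardized mean
#' difference is the group coefficient divided by the residual SD, with the
#' usual SMD variance 1/n1 + 1/n2 + d^2/(2(n1+n2)). Studies with collinear
#' designs are dropped with a warning. Pooling uses the same Paule-Mandel
#' random-effects machinery as [meta_pool_correlations()].
#'
#' @param study_data list of data frames, each with columns `outcome`,
#'   `group` (two levels) and any covariate columns
#' @param covariates character vector of covariate column names
#' @param conf_level confidence level
#' @return an object of class `akk_meta` (effects on the SMD scale)
#' @export
adjusted_smd_pool <- function(study_data, covariates = character(0),
                              conf_level = 0.95) {
  eff <- lapply(study_data, function(d) {
    stopifnot(all(c("outcome", "group") %in% names(d)))
    g <- as.integer(factor(d$group)) - 1L
    if (length(unique(g)) < 2) return(NULL)
    rhs <- if (length(covariates))
      paste(c(covariates, "g"), collapse = " + ") else "g"
    d$g <- g
    fit <- lm(stats::as.formula(paste("outcome ~", rhs)), data = d)
    b <- coef(fit)[["g"]]
    if (is.na(b)) return(NULL)
    sigma <- sqrt(sum(fit$residuals^2) / fit$df.residual)
    d_smd <- b / sigma
    n1 <- sum(g == 0); n2 <- sum(g == 1)
    v <- 1 / n1 + 1 / n2 + d_smd^2 / (2 * (n1 + n2))
    c(d_smd, v, n1 + n2)
  })
  drop_n <- sum(vapply(eff, is.null, logical(1)))
  if (drop_n) warning(drop_n, " study(ies) dropped (single group or collinear)")
  eff <- do.call(rbind, eff[!vapply(eff, is.null, logical(1))])
  if (is.null(eff) || nrow(eff) == 0) stop("no usable studies")
  y <- eff[, 1]; v <- eff[, 2]
  k <- length(y)
  if (k == 1) { est <- y[1]; se <- sqrt(v[1]); tau2 <- NA_real_ }
  else {
    tau2 <- paule_mandel_tau2(y, v)
    p <- pool_fixed(y, v, tau2)
    est <- p$est; se <- p$se
  }
  zcrit <- qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    studies = data.frame(smd = y, v = v, n = eff[, 3]),
    pooled_rho = est, pooled_z = est, se_z = se,
    ci = c(est - zcrit * se, est + zcrit * se),
    p = 2 * pnorm(-abs(est / se)), tau2 = tau2, k = k,
    method = "adjusted SMD / Paule-Mandel random effects"),
    class = "akk_meta")
}

#' Pairwise co-exclusion analysis of clade abundances
#'
#' With `restrict = "genus_positive"` (the published design) correlations are
#' computed on the samples in which at least one clade (any column) is
#' present, mirroring the 4171-genus-positive-sample analysis. Note that this
#' conditioning makes even independent sparse clades appear negatively
#' correlated (a Berkson-type selection effect), so it overstates exclusion
#' under the null; `restrict = "all"` evaluates the same test on every sample
#' and is calibrated under independence. Each clade pair gets a Spearman
#' correlation on the chosen sample set, with Benjamini-Hochberg correction
#' at `fdr`; plus the co-occurrence summary: how many samples carry at least
#' one clade, exactly two, more than two, and the co-occurrence rate (samples
#' with two or more clades over samples with at least one).
#'
#' @param abund samples x clades abundance matrix
#' @param fdr FDR level for the BH correction (default 0.10)
#' @param restrict sample set for the correlations: `"genus_positive"`
#'   (default) or `"all"`
#' @return list with `pairs` (data frame: clade_a, clade_b, rho, n, p, q,
#'   significant) and `summary`
#' @export
coexclusion <- function(abund, fdr = 0.10,
                        restrict = c("genus_positive", "all")) {
  restrict <- match.arg(restrict)
  stopifnot(ncol(abund) >= 2)
  cl <- colnames(abund) %||% paste0("clade", seq_len(ncol(abund)))
  colnames(abund) <- cl
  genus_pos <- if (restrict == "genus_positive")
    rowSums(abund > 0) >= 1 else rep(TRUE, nrow(abund))
  cmb <- combn(cl, 2)
  rows <- lapply(seq_len(ncol(cmb)), function(i) {
    a <- abund[, cmb[1, i]]; b <- abund[, cmb[2, i]]
    keep <- genus_pos
    n <- sum(keep)
    if (n < 3 || var(rank(a[keep])) == 0 || var(rank(b[keep])) == 0)
      return(data.frame(clade_a = cmb[1, i], clade_b = cmb[2, i],
                        rho = NA_real_, n = n, p = NA_real_,
                        stringsAsFactors = FALSE))
    ct <- suppressWarnings(cor.test(a[keep], b[keep], method = "spearman"))
    data.frame(clade_a = cmb[1, i], clade_b = cmb[2, i],
               rho = unname(ct$estimate), n = n, p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  pairs$q <- p.adjust(pairs$p, method = "BH")
  pairs$significant <- !is.na(pairs$q) & pairs$q <= fdr
  npos <- rowSums(abund > 0)
  summary <- list(
    n_samples = nrow(abund),
    n_with_any = sum(npos >= 1),
    n_with_two = sum(npos == 2),
    n_with_more = sum(npos > 2),
    cooccurrence_rate = if (sum(npos >= 1) > 0)
      sum(npos >= 2) / sum(npos >= 1) else NA_real_)
  list(pairs = pairs, summary = summary)
}

#' Wilcoxon rank-sum test with generalized fold change
#'
#' Two-sided rank-sum test of abundances between samples where a viral
#' cluster is detected and samples where it is not (exact enumeration when
#' both groups have at most 10 samples and no ties; otherwise the normal
#' approximation with tie correction). The generalized fold change is the
#' mean difference of the log10(abundance + eps) quantiles
#' (0.05, 0.10, ..., 0.95), absent minus present, so a negative gFC means
#' the clade is more abundant when the VC is detected.
#'
#' @param abund numeric abundances
#' @param detected logical (or 0/1) VC detection flag per sample
#' @param probs quantile grid
#' @param eps pseudocount (default 1e-5)
#' @return list with `p`, `gfc`, `n_present`, `n_absent`
#' @export
wilcoxon_gfc <- function(abund, detected, probs = seq(0.05, 0.95, by = 0.05),
                         eps = 1e-5) {
  detected <- as.logical(detected)
  pres <- abund[detected]; abs_ <- abund[!detected]
  if (length(pres) == 0 || length(abs_) == 0) {
    warning("one group is empty; returning NA")
    return(list(p = NA_real_, gfc = NA_real_, n_present = length(pres),
                n_absent = length(abs_)))
  }
  exact <- length(pres) <= 10 && length(abs_) <= 10 &&
    !any(duplicated(c(pres, abs_)))
  wt <- suppressWarnings(wilcox.test(abs_, pres, exact = exact,
                                     correct = !exact))
  gfc <- mean(quantile(log10(abs_ + eps), probs) -
                quantile(log10(pres + eps), probs))
  list(p = wt$p.value, gfc = gfc, n_present = length(pres),
       n_absent = length(abs_))
}

#' Benjamini-Hochberg adjusted p-values and rejections
#'
#' @param pvalues numeric vector in `[0, 1]`
#' @param q FDR level (default 0.10)
#' @return list with `adjusted` and logical `rejected`
#' @export
bh_fdr <- function(pvalues, q = 0.10) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  adj <- p.adjust(pvalues, method = "BH")
  list(adjusted = adj, rejected = !is.na(adj) & adj <= q)
}
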