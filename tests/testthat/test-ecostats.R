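test_that("Spearman correlation matches hand-ranked values", {
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  set.seed(80)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(15)
    expect_equal(spearman_rho(x, y),
                 cor(rank(x), rank(y)), tolerance = 1e-12)
  }
  expect_warning(r <- spearman_rho(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(r))
})

test_that("partial Spearman reduces, absorbs and recovers planted structure", {
  set.seed(81)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(partial_spearman(x, y)$rho, spearman_rho(x, y))

  # covariate nearly equal to y absorbs the association with y
  z <- y + rnorm(50, 0, 0.2)
  ps <- partial_spearman(x, y, data.frame(z = z))
  expect_lt(abs(ps$rho), 0.2)

  # planted conditional structure: x and y share z, plus direct link
  reps <- replicate(40, {
    z <- rnorm(400)
    e1 <- rnorm(400); e2 <- 0.5 * e1 + sqrt(1 - 0.25) * rnorm(400)
    x <- z + e1; y <- z + e2
    partial_spearman(x, y, data.frame(z = z))$rho
  })
  # latent partial Pearson is 0.5; its Spearman analogue is (6/pi)asin(rho/2)
  expect_lt(abs(mean(reps) - 6 / pi * asin(0.5 / 2)), 0.05)
  expect_error(partial_spearman(1:4, 1:4, data.frame(a = 1:4)), "n > s")
})

test_that("Paule-Mandel pooling matches closed forms and metafor", {
  # identical studies: tau2 = 0, pooled = common rho
  st <- data.frame(rho = rep(0.3, 5), n = rep(100, 5))
  res <- meta_pool_correlations(st)
  expect_equal(res$tau2, 0)
  expect_equal(res$pooled_rho, 0.3, tolerance = 1e-12)

  # two studies, tau2 = 0 case equals the inverse-variance mean
  st2 <- data.frame(rho = c(0.2, 0.25), n = c(60, 200), s = 0)
  res2 <- meta_pool_correlations(st2)
  z <- atanh(st2$rho); v <- 1 / (st2$n - 3)
  expect_equal(res2$tau2, 0)
  expect_equal(res2$pooled_z, sum(z / v) / sum(1 / v), tolerance = 1e-10)

  skip_if_not_installed("metafor")
  set.seed(82)
  for (i in 1:10) {
    k <- sample(4:12, 1)
    rho <- tanh(rnorm(k, 0.2, 0.25))
    n <- sample(30:400, k, replace = TRUE)
    mine <- meta_pool_correlations(data.frame(rho = rho, n = n))
    rf <- metafor::rma(yi = atanh(rho), vi = 1 / (n - 3), method = "PM")
    # metafor's PM root-finder has its own convergence tolerance
    expect_equal(mine$tau2, unname(rf$tau2), tolerance = 5e-3)
    expect_equal(mine$pooled_z, unname(coef(rf)), tolerance = 1e-4)
  }
})

test_that("PM iteration satisfies its estimating equation", {
  set.seed(83)
  for (i in 1:20) {
    k <- sample(3:15, 1)
    y <- rnorm(k, 0, 0.4); v <- runif(k, 0.005, 0.1)
    t2 <- akkpop:::paule_mandel_tau2(y, v)
    w <- 1 / (v + t2)
    q <- sum(w * (y - sum(w * y) / sum(w))^2)
    if (t2 > 0) expect_lt(abs(q - (k - 1)), 1e-8)
    else expect_lte(q, k - 1 + 1e-8)
  }
})

test_that("adjusted SMD equals Cohen's d without covariates", {
  set.seed(84)
  x1 <- rnorm(40, 0); x2 <- rnorm(35, 0.6)
  d <- data.frame(outcome = c(x1, x2),
                  group = rep(c("a", "b"), c(40, 35)))
  res <- adjusted_smd_pool(list(d))
  sp <- sqrt(((40 - 1) * var(x1) + (35 - 1) * var(x2)) / (40 + 35 - 2))
  cohend <- (mean(x2) - mean(x1)) / sp
  expect_equal(res$pooled_rho, cohend, tolerance = 1e-10)

  # null effect, several studies -> pooled SMD near zero; planted sex-like
  # effect recovered in sign and rough magnitude
  studies0 <- lapply(1:5, function(i)
    data.frame(outcome = rnorm(300), group = rep(c("a", "b"), 150),
               age = rnorm(300)))
  expect_lt(abs(adjusted_smd_pool(studies0, "age")$pooled_rho), 0.1)
  studies1 <- lapply(1:5, function(i) {
    g <- rep(0:1, 150)
    age <- rnorm(300)
    data.frame(outcome = 0.3 * age - 0.5 * g + rnorm(300),
               group = g, age = age)
  })
  res1 <- adjusted_smd_pool(studies1, "age")
  expect_lt(res1$ci[2], 0)
  expect_lt(abs(res1$pooled_rho - (-0.5)), 0.12)
})

test_that("co-exclusion analysis counts and flags planted structure", {
  # arithmetic of the co-occurrence rate on a constructed presence matrix
  m <- matrix(0, 5000, 3, dimnames = list(NULL, c("A", "B", "C")))
  m[1:4125, 1] <- 1          # single-positive
  m[4126:4171, 1:2] <- 1     # exactly two
  cx <- coexclusion(m)
  expect_equal(cx$summary$n_with_any, 4171)
  expect_equal(cx$summary$n_with_two, 46)
  expect_equal(cx$summary$n_with_more, 0)
  expect_equal(cx$summary$cooccurrence_rate, 46 / 4171, tolerance = 1e-12)

  # planted mutual exclusion: negative and significant
  set.seed(85)
  co <- simulate_cohorts(cohort_sim_spec(n_studies = 1, n_per_study = 800,
                                         coexclusion_odds = 0.02, seed = 9))
  ab <- as.matrix(co$table[, co$truth$species])
  cx2 <- coexclusion(ab)
  # also significant without the genus-positive restriction
  cx3 <- coexclusion(ab, restrict = "all")
  lead <- cx2$pairs[cx2$pairs$clade_a == "sp01" & cx2$pairs$clade_b == "sp02", ]
  expect_lt(lead$rho, 0)
  expect_true(lead$significant)
  lead3 <- cx3$pairs[cx3$pairs$clade_a == "sp01" & cx3$pairs$clade_b == "sp02", ]
  expect_lt(lead3$rho, 0)
  expect_true(lead3$significant)
})

test_that("rank-sum test matches exact enumeration and gFC sign convention", {
  set.seed(86)
  x <- c(1.2, 3.4, 0.4, 5.5); y <- c(2.2, 6.1, 7.3, 8.9)
  res <- wilcoxon_gfc(abund = c(x, y), detected = rep(c(TRUE, FALSE), each = 4))
  # exact two-sided rank-sum p over all C(8,4) labelings
  ranks <- rank(c(x, y)); w_obs <- sum(ranks[1:4])
  combs <- combn(8, 4)
  ws <- apply(combs, 2, function(idx) sum(ranks[idx]))
  mu <- mean(ws)
  p_exact <- mean(abs(ws - mu) >= abs(w_obs - mu))
  expect_equal(res$p, p_exact, tolerance = 1e-12)

  idg <- wilcoxon_gfc(c(1, 2, 3, 1, 2, 3), c(TRUE, TRUE, TRUE, FALSE, FALSE,
                                             FALSE))
  expect_equal(idg$gfc, 0)
  expect_gt(idg$p, 0.99)

  # planted 2x shift in VC-positive samples: negative gFC, p < 0.01
  set.seed(87)
  base <- rlnorm(200, -3, 0.5)
  det <- rep(c(TRUE, FALSE), each = 100)
  ab <- ifelse(det, base * 2, base)
  shift <- wilcoxon_gfc(ab, det)
  expect_lt(shift$gfc, 0)
  expect_lt(shift$p, 0.01)
  expect_warning(w0 <- wilcoxon_gfc(1:5, rep(TRUE, 5)), "empty")
  expect_true(is.na(w0$p))
})

test_that("BH correction follows the step-up rule", {
  res <- bh_fdr(c(0.01, 0.02, 0.03, 0.5), q = 0.1)
  expect_identical(res$rejected, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(res$adjusted, p.adjust(c(0.01, 0.02, 0.03, 0.5), "BH"))
  expect_true(all(bh_fdr(rep(0, 5))$rejected))
})
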