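#' Specification for synthetic multi-study host cohorts
#'
#' Emulates the statistical structure of multi-cohort microbiome association
#' studies: a focal clade whose abundance has a planted partial rank
#' correlation with BMI given age and sex, with between-study heterogeneity
#' on the Fisher-Z scale, plus a block of sparse clade abundances whose
#' pairwise co-presence is controlled by an odds ratio (co-exclusion when
#' `coexclusion_odds` is far below 1).
#'
#' @param n_studies number of studies
#' @param n_per_study samples per study (recycled)
#' @param true_partial_rho planted partial Spearman correlation between the
#'   focal clade's abundance and BMI given age and sex (|rho| < 1)
#' @param tau2 between-study variance of the study effects on the Fisher-Z
#'   scale (>= 0)
#' @param coexclusion_odds odds multiplier on a clade's presence when another
#'   clade is already present (1 = independence)
#' @param seed integer seed
#' @param n_species clades in the co-exclusion block
#' @param prevalences marginal presence probabilities of those clades
#' @param sex_effect planted coefficient of sex on the focal clade's latent
#'   abundance (standardized scale)
#' @return an object of class `cohort_sim_spec`
#' @export
cohort_sim_spec <- function(n_studies = 10, n_per_study = 300,
                            true_partial_rho = -0.2, tau2 = 0.02,
                            coexclusion_odds = 0.05, seed = 1,
                            n_species = 5,
                            prevalences = c(0.35, 0.12, 0.10, 0.08, 0.06),
                            sex_effect = -0.15) {
  stopifnot(abs(true_partial_rho) < 1, tau2 >= 0, coexclusion_odds > 0,
            length(prevalences) >= n_species)
  structure(list(n_studies = n_studies,
                 n_per_study = rep_len(n_per_study, n_studies),
                 true_partial_rho = true_partial_rho, tau2 = tau2,
                 coexclusion_odds = coexclusion_odds, seed = seed,
                 n_species = n_species,
                 prevalences = prevalences[seq_len(n_species)],
                 sex_effect = sex_effect), class = "cohort_sim_spec")
}

#' Simulate multi-study cohort tables with planted associations
#'
#' Per study, a latent effect is drawn as N(atanh(rho), tau2) on the Fisher-Z
#' scale; abundance and BMI are built on a Gaussian copula whose latent
#' Pearson correlation is 2 sin(pi * rho_study / 6), so the conditional
#' *rank* correlation given age and sex converges to the study effect. The
#' focal abundance is a log-normal (monotone) transform of the latent score,
#' so rank-based statistics are unaffected by the transform. Clade
#' presence/absence in the co-exclusion block is sequential-logit with an
#' odds multiplier when any other clade is already present; abundances of
#' present clades are log-normal (zeros otherwise).
#'
#' @param spec a [cohort_sim_spec()]
#' @return list with `table` (data frame: study, age, sex, bmi,
#'   focal_abundance, sp01...) and `truth` (study effects and generator
#'   parameters)
#' @export
simulate_cohorts <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  set.seed(spec$seed)
  theta <- rnorm(spec$n_studies, atanh(spec$true_partial_rho), sqrt(spec$tau2))
  rho_s <- tanh(theta)          # per-study conditional Spearman target
  rho_lat <- 2 * sin(pi * rho_s / 6)  # latent Pearson giving that Spearman
  sp_names <- sprintf("sp%02d", seq_len(spec$n_species))
  tabs <- lapply(seq_len(spec$n_studies), function(i) {
    n <- spec$n_per_study[i]
    age <- rnorm(n, 45, 12)
    sex <- rbinom(n, 1, 0.5)
    z_age <- (age - 45) / 12
    e_b <- rnorm(n)
    e_x <- rho_lat[i] * e_b + sqrt(1 - rho_lat[i]^2) * rnorm(n)
    bmi <- 25 + 0.9 * z_age + 0.8 * sex + 3 * e_b
    x_lat <- 0.25 * z_age + spec$sex_effect * sex + e_x
    focal <- exp(-3 + x_lat)   # monotone transform; ranks preserved
    # co-exclusion block
    pres <- matrix(0L, n, spec$n_species)
    logodds <- log(spec$coexclusion_odds)
    for (j in seq_len(spec$n_species)) {
      base <- qlogis(spec$prevalences[j])
      any_prev <- if (j > 1) rowSums(pres[, seq_len(j - 1), drop = FALSE]) > 0
                  else rep(FALSE, n)
      p <- plogis(base + logodds * any_prev)
      pres[, j] <- rbinom(n, 1, p)
    }
    ab <- matrix(0, n, spec$n_species, dimnames = list(NULL, sp_names))
    for (j in seq_len(spec$n_species)) {
      idx <- pres[, j] == 1
      ab[idx, j] <- rlnorm(sum(idx), -3, 1)
    }
    cbind(data.frame(study = sprintf("study%02d", i), age = age, sex = sex,
                     bmi = bmi, focal_abundance = focal,
                     stringsAsFactors = FALSE),
          as.data.frame(ab))
  })
  list(table = do.call(rbind, tabs),
       truth = list(theta = theta, rho_study = rho_s,
                    true_partial_rho = spec$true_partial_rho,
                    tau2 = spec$tau2, coexclusion_odds = spec$coexclusion_odds,
                    sex_effect = spec$sex_effect, species = sp_names))
}
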