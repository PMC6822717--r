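#' Configuration for a synthetic biobank population
#'
#' Bundles the population-level parameters of the synthetic cohort: the size,
#' the instrument SNP's effect-allele frequency, the prevalence of the binary
#' stratifying phenotype (ever vs never smoking), the per-allele odds ratios
#' of the SNP on smoking status and on smoking heaviness, and the covariate
#' layout (age range, sex ratio, number of genetic principal components).
#'
#' The defaults emulate a UK-Biobank-like cohort of unrelated European-ancestry
#' adults: 334,968 participants of whom 45.2% are ever smokers, an instrument
#' with effect-allele frequency 0.33 whose smoking-heaviness-increasing allele
#' carries odds 1.21 per allele of being in a higher heaviness band among ever
#' smokers and odds 0.98 per allele of being an ever (vs never) smoker.
#'
#' @param n_participants Cohort size.
#' @param allele_freq Effect-allele frequency of the instrument SNP, in (0,1).
#' @param ever_prevalence Marginal prevalence of the "ever" stratum, in (0,1).
#' @param or_snp_status Odds ratio per allele of the SNP on ever-smoking.
#' @param or_snp_heaviness Odds ratio per allele of the SNP on being in a
#'   higher smoking-heaviness band (proportional odds), among ever smokers.
#' @param heaviness_props Marginal proportions of the four cigarettes-per-day
#'   bands (0-10, 11-20, 21-30, 31+) among ever smokers; must sum to 1.
#' @param age_range Two-element numeric; ages are drawn uniformly in between.
#' @param sex_ratio Probability of being male.
#' @param n_pcs Number of genetic principal components to simulate (standard
#'   normal, independent of genotype).
#'
#' @return A list of class `population_config`.
#' @export
#' @examples
#' cfg <- population_config(n_participants = 1000)
population_config <- function(n_participants = 334968,
                              allele_freq = 0.33,
                              ever_prevalence = 0.452,
                              or_snp_status = 0.98,
                              or_snp_heaviness = 1.21,
                              heaviness_props = c(0.33, 0.45, 0.14, 0.08),
                              age_range = c(40, 69),
                              sex_ratio = 0.5,
                              n_pcs = 10) {
  n_participants <- check_count(n_participants, "n_participants")
  check_probability(allele_freq, "allele_freq")
  check_probability(ever_prevalence, "ever_prevalence")
  check_positive(or_snp_status, "or_snp_status")
  check_positive(or_snp_heaviness, "or_snp_heaviness")
  check_probability(sex_ratio, "sex_ratio")
  n_pcs <- check_count(n_pcs, "n_pcs", min = 0L)
  stopifnot(length(age_range) == 2L, age_range[1] < age_range[2])
  if (length(heaviness_props) < 2L || any(heaviness_props <= 0) ||
      abs(sum(heaviness_props) - 1) > 1e-8) {
    abort("`heaviness_props` must be positive proportions summing to 1")
  }
  structure(
    list(n_participants = n_participants, allele_freq = allele_freq,
         ever_prevalence = ever_prevalence, or_snp_status = or_snp_status,
         or_snp_heaviness = or_snp_heaviness,
         heaviness_props = heaviness_props, age_range = age_range,
         sex_ratio = sex_ratio, n_pcs = n_pcs),
    class = "population_config")
}

#' Simulate instrument genotypes under Hardy-Weinberg equilibrium
#'
#' Each dosage is the sum of two independent Bernoulli(`allele_freq`) draws,
#' i.e. the number of effect alleles carried under random mating.
#'
#' @param n Number of participants.
#' @param allele_freq Effect-allele frequency, in (0,1).
#' @param seed Optional integer seed; when given, the draw is reproducible and
#'   the caller's RNG stream is left untouched.
#'
#' @return Integer vector of dosages in \{0, 1, 2\}.
#' @export
#' @examples
#' g <- simulate_genotypes(1000, 0.33, seed = 1)
#' table(g)
simulate_genotypes <- function(n, allele_freq, seed = NULL) {
  n <- check_count(n, "n")
  check_probability(allele_freq, "allele_freq")
  with_seed_if(seed, rbinom(n, 2L, allele_freq))
}

#' Simulate smoking status and heaviness given instrument dosage
#'
#' Ever/never status is drawn from a logistic model in dosage whose intercept
#' is calibrated by bisection so the realized marginal prevalence matches the
#' configured one.  Among ever smokers, the four-band cigarettes-per-day
#' heaviness variable is generated from a proportional-odds latent-logistic
#' model with the configured per-allele odds ratio; never smokers have missing
#' heaviness.
#'
#' @param dosage Integer dosage vector in \{0, 1, 2\}.
#' @param config A [population_config()].
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `smoking_status` (factor, never/ever) and
#'   `smoking_heaviness` (ordered factor `0-10 < 11-20 < 21-30 < 31+`, `NA`
#'   for never smokers).
#' @export
simulate_smoking <- function(dosage, config, seed = NULL) {
  stopifnot(inherits(config, "population_config"))
  b <- log(config$or_snp_status)
  with_seed_if(seed, {
    a <- calibrate_intercept(b * dosage, config$ever_prevalence)
    ever <- rbinom(length(dosage), 1L, plogis(a + b * dosage)) == 1L
    status <- factor(ifelse(ever, "ever", "never"), levels = c("never", "ever"))
    bands <- c("0-10", "11-20", "21-30", "31+")
    k <- length(config$heaviness_props)
    heav <- rep(NA_character_, length(dosage))
    if (any(ever)) {
      bh <- log(config$or_snp_heaviness)
      latent <- bh * dosage[ever] + rlogis(sum(ever))
      cuts <- quantile(latent, cumsum(config$heaviness_props)[-k],
                       names = FALSE)
      heav[ever] <- bands[seq_len(k)][findInterval(latent, cuts) + 1L]
    }
    tibble::tibble(
      smoking_status = status,
      smoking_heaviness = factor(heav, levels = bands[seq_len(k)],
                                 ordered = TRUE))
  })
}

#' Specification of one synthetic outcome
#'
#' Describes a single outcome field to inject into the synthetic biobank: its
#' target data type, the per-stratum SNP effect (in SD units for continuous
#' outcomes and on the log-odds scale otherwise), the number of categories for
#' categorical types, and the missing-completely-at-random fraction.
#'
#' @param id Field identifier (coerced to character).
#' @param type One of `"continuous"`, `"binary"`, `"ordered"`, `"unordered"`.
#' @param effect_ever,effect_never Injected SNP effect per allele within the
#'   ever / never stratum.
#' @param n_categories Number of categories (>= 2) for non-continuous types.
#' @param prevalence Baseline case prevalence for binary outcomes.
#' @param missingness Fraction of values set missing at random, in \[0, 1).
#'
#' @return A list of class `outcome_spec`.
#' @export
outcome_spec <- function(id, type = c("continuous", "binary", "ordered",
                                      "unordered"),
                         effect_ever = 0, effect_never = 0,
                         n_categories = if (type == "binary") 2L else 3L,
                         prevalence = 0.2, missingness = 0) {
  type <- match.arg(type)
  if (type != "continuous") {
    n_categories <- check_count(n_categories, "n_categories", min = 2L)
    if (type == "binary" && n_categories != 2L) {
      abort("binary outcomes have exactly 2 categories")
    }
  }
  if (!is.numeric(missingness) || missingness < 0 || missingness >= 1) {
    abort("`missingness` must be in [0, 1)")
  }
  structure(
    list(id = as.character(id), type = type, effect_ever = effect_ever,
         effect_never = effect_never, n_categories = n_categories,
         prevalence = prevalence, missingness = missingness),
    class = "outcome_spec")
}

# per-participant linear predictor of the injected SNP effect
injected_effect <- function(dosage, ever, spec) {
  dosage * ifelse(ever, spec$effect_ever, spec$effect_never)
}

#' Inject synthetic outcomes into a participant skeleton
#'
#' Continuous outcomes are generated as per-stratum SNP effect plus
#' standard-normal noise; binary outcomes from a logistic model; ordered
#' outcomes by cutting a latent logistic variable at thresholds implied by
#' equal category proportions; unordered outcomes from a multinomial-logit
#' model in which the injected effect acts on the last category relative to
#' the first.  The emitted field metadata lets the typing rules rediscover the
#' intended data type, and the truth table records every injected effect.
#'
#' @param data Participant table containing at least `snp` (dosage) and
#'   `smoking_status`.
#' @param specs List of [outcome_spec()] objects.
#' @param seed Optional integer seed.
#'
#' @return A list with `phenotypes` (the input plus one `f<id>` column per
#'   spec), `metadata` (field-metadata tibble) and `truth` (field id, stratum,
#'   injected effect, scale).
#' @export
simulate_outcomes <- function(data, specs, seed = NULL) {
  stopifnot(is.data.frame(data), all(c("snp", "smoking_status") %in%
                                       names(data)))
  if (inherits(specs, "outcome_spec")) specs <- list(specs)
  bad <- !vapply(specs, inherits, logical(1), "outcome_spec")
  if (any(bad)) abort("`specs` must be a list of outcome_spec objects")
  n <- nrow(data)
  dosage <- data$snp
  ever <- data$smoking_status == "ever"
  with_seed_if(seed, {
    cols <- list()
    meta <- list()
    truth <- list()
    for (sp in specs) {
      eta <- injected_effect(dosage, ever, sp)
      y <- switch(
        sp$type,
        continuous = eta + rnorm(n),
        binary = rbinom(n, 1L, plogis(qlogis(sp$prevalence) + eta)),
        ordered = {
          latent <- eta + rlogis(n)
          cuts <- quantile(latent, seq_len(sp$n_categories - 1L) /
                             sp$n_categories, names = FALSE)
          findInterval(latent, cuts) + 1L
        },
        unordered = {
          # reference category 1; injected effect on the last category
          eta_k <- matrix(0, n, sp$n_categories)
          eta_k[, sp$n_categories] <- eta
          pr <- exp(eta_k)
          pr <- pr / rowSums(pr)
          cp <- t(apply(pr, 1, cumsum))
          u <- runif(n)
          max.col(cp >= u, ties.method = "first")
        })
      if (sp$missingness > 0) {
        y[runif(n) < sp$missingness] <- NA
      }
      colname <- paste0("f", sp$id)
      cols[[colname]] <- y
      meta[[sp$id]] <- tibble::tibble(
        field_id = sp$id,
        field_type = switch(sp$type,
                            continuous = "continuous",
                            "categorical-single"),
        ordering = switch(sp$type, ordered = "ordered",
                          unordered = "unordered", "unspecified"),
        reference = switch(sp$type, binary = "0", unordered = "1",
                           NA_character_),
        category_order = if (sp$type == "ordered") {
          paste(seq_len(sp$n_categories), collapse = ",")
        } else NA_character_)
      scale <- if (sp$type == "continuous") "sd" else "log-odds"
      truth[[sp$id]] <- tibble::tibble(
        field_id = sp$id, stratum = c("ever", "never"),
        effect = c(sp$effect_ever, sp$effect_never), scale = scale)
    }
    list(phenotypes = dplyr::bind_cols(data, tibble::as_tibble(cols)),
         metadata = dplyr::bind_rows(meta),
         truth = dplyr::bind_rows(truth))
  })
}

#' Simulate a complete synthetic biobank
#'
#' Assembles genotypes, covariates (age, sex, genetic principal components),
#' smoking status and heaviness, and the requested outcome fields into a
#' single dataset with known ground truth.
#'
#' @param config A [population_config()].
#' @param specs List of [outcome_spec()] objects (may be empty).
#' @param seed Optional integer seed; fixed seeds give bit-identical datasets.
#'
#' @return A list of class `synthetic_biobank` with elements `phenotypes`,
#'   `metadata`, `truth` and `config`.
#' @export
#' @examples
#' bb <- simulate_biobank(population_config(n_participants = 2000),
#'                        list(outcome_spec("101", "continuous",
#'                                          effect_ever = 0.1)),
#'                        seed = 1)
#' names(bb$phenotypes)
simulate_biobank <- function(config = population_config(), specs = list(),
                             seed = NULL) {
  stopifnot(inherits(config, "population_config"))
  with_seed_if(seed, {
    n <- config$n_participants
    dosage <- simulate_genotypes(n, config$allele_freq)
    covars <- tibble::tibble(
      participant_id = sprintf("P%07d", seq_len(n)),
      snp = dosage,
      age = runif(n, config$age_range[1], config$age_range[2]),
      sex = rbinom(n, 1L, config$sex_ratio))
    if (config$n_pcs > 0) {
      pcs <- rnorm_matrix(n, config$n_pcs)
      colnames(pcs) <- paste0("pc", seq_len(config$n_pcs))
      covars <- dplyr::bind_cols(covars, tibble::as_tibble(pcs))
    }
    smoking <- simulate_smoking(dosage, config)
    skeleton <- dplyr::bind_cols(covars, smoking)
    out <- simulate_outcomes(skeleton, specs)
    structure(
      list(phenotypes = out$phenotypes, metadata = out$metadata,
           truth = out$truth, config = config),
      class = "synthetic_biobank")
  })
}

#' Simulate a matrix of continuous phenome outcomes
#'
#' High-throughput variant of [simulate_outcomes()] for simulation studies
#' that need thousands of continuous outcomes: returns an `n x m` matrix in
#' which column `j` equals `effects_ever[j]` (resp. `effects_never[j]`) times
#' dosage within the corresponding stratum plus standard-normal noise.
#'
#' @param dosage Dosage vector.
#' @param ever Logical vector marking the ever stratum.
#' @param effects_ever,effects_never Per-outcome injected effects (recycled to
#'   a common length).
#' @param seed Optional integer seed.
#'
#' @return Numeric matrix with one column per outcome.
#' @export
simulate_outcome_matrix <- function(dosage, ever, effects_ever = 0,
                                    effects_never = 0, seed = NULL) {
  stopifnot(length(dosage) == length(ever))
  m <- max(length(effects_ever), length(effects_never))
  effects_ever <- rep_len(effects_ever, m)
  effects_never <- rep_len(effects_never, m)
  n <- length(dosage)
  with_seed_if(seed, {
    Y <- rnorm_matrix(n, m)
    nz <- which(effects_ever != 0 | effects_never != 0)
    for (j in nz) {
      Y[, j] <- Y[, j] + dosage * ifelse(ever, effects_ever[j],
                                         effects_never[j])
    }
    Y
  })
}

#' Simulate a cohort for instrumental-variable follow-up
#'
#' Generates a panel of independent biallelic SNPs, the unweighted allele
#' score over the panel, a continuous exposure ("lifetime smoking") driven by
#' the standardized score, and a binary outcome generated from a probit model
#' in the true exposure.  The defaults emulate the follow-up conditions of a
#' large biobank analysis: a 126-SNP unweighted score explaining a first-stage
#' coefficient of 0.105 SD exposure per SD score, and a probit-scale causal
#' effect of 0.16 per SD exposure on the binary outcome.
#'
#' @param n Cohort size.
#' @param n_snps Number of SNPs in the instrument panel.
#' @param first_stage SD change in exposure per SD of allele score.
#' @param probit_effect Probit-scale effect of a 1 SD exposure increase on the
#'   binary outcome's latent liability.
#' @param outcome_prevalence Marginal prevalence of the binary outcome.
#' @param confounding SD effect of a shared normal confounder on the exposure
#'   and (same scale) on the outcome liability; 0 for none.
#' @param seed Optional integer seed.
#'
#' @return A list with `data` (tibble: `score`, `exposure`, `outcome`, `age`,
#'   `sex`), `dosages` (n x n_snps matrix), `flipped` (logical panel
#'   orientation flags) and the generating parameters.
#' @export
simulate_iv_cohort <- function(n = 305662, n_snps = 126, first_stage = 0.105,
                               probit_effect = 0.16,
                               outcome_prevalence = 0.05, confounding = 0,
                               seed = NULL) {
  n <- check_count(n, "n")
  n_snps <- check_count(n_snps, "n_snps")
  with_seed_if(seed, {
    freqs <- runif(n_snps, 0.1, 0.9)
    G <- vapply(freqs, function(f) rbinom(n, 2L, f), integer(n))
    flipped <- runif(n_snps) < 0.5
    # stored dosages count the *other* allele for flipped SNPs
    stored <- G
    stored[, flipped] <- 2L - stored[, flipped]
    score <- rowSums(G)
    zscore <- as.numeric(scale(score))
    u <- if (confounding > 0) rnorm(n) else numeric(n)
    exposure <- first_stage * zscore + confounding * u +
      sqrt(max(1 - first_stage^2 - confounding^2, 0.1)) * rnorm(n)
    zexp <- as.numeric(scale(exposure))
    liability <- probit_effect * zexp + confounding * u + rnorm(n)
    thr <- quantile(liability, 1 - outcome_prevalence, names = FALSE)
    outcome <- as.integer(liability > thr)
    list(
      data = tibble::tibble(score = score, exposure = exposure,
                            outcome = outcome,
                            age = runif(n, 40, 69), sex = rbinom(n, 1L, 0.5)),
      dosages = stored, flipped = flipped,
      params = list(first_stage = first_stage, probit_effect = probit_effect))
  })
}
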