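#' Simulation configuration
#'
#' Describes a synthetic allo-HSCT case/control cohort: biallelic variants
#' with a uniform MAF spectrum and AR(1) latent-Gaussian LD blocks, clinical
#' covariates mirroring the marginals of a sibling-donor transplant cohort,
#' and a logistic outcome model with planted genotype and covariate effects.
#'
#' @param n_samples Cohort size (default 151, a realistic single-centre
#'   discovery cohort).
#' @param n_variants Number of biallelic variants (default 5000, a
#'   desk-scale stand-in for the hundreds of thousands in targeted
#'   sequencing panels).
#' @param maf_range Length-2 vector inside (0, 0.5]; per-variant target MAF
#'   is drawn uniformly on this range.
#' @param ld_block_size Variants per LD block.
#' @param ld_rho Adjacent-variant latent correlation in \[0, 1); haplotypes
#'   within a block share an AR(1) latent Gaussian before thresholding.
#' @param n_causal Number of causal variants (positions drawn uniformly).
#' @param causal_beta Per-ALT-allele log-odds, recycled to `n_causal`.
#' @param intercept_beta0 Logistic intercept; `NULL` (default) calibrates it
#'   by root finding on a 10,000-draw pilot sample so the realized
#'   prevalence approximates `prevalence_target`.
#' @param covariate_effects Named log-odds for covariates. Valid names:
#'   `donor_age` (per reference SD of 12 years), `graft_type` (peripheral
#'   blood vs bone marrow), `sex` (male recipient), `batch`, and
#'   `diagnosis_<group>` for groups `ALL`, `lymphoma_myeloma`, `other`
#'   (reference `AML`).
#' @param prevalence_target Target relapse fraction (default 0.31, the
#'   prevalence the generator emulates).
#' @param seed Integer seed; identical configs give bit-identical cohorts.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 151, n_variants = 5000,
                       maf_range = c(0.05, 0.5), ld_block_size = 10,
                       ld_rho = 0.5, n_causal = 0, causal_beta = 1.0,
                       intercept_beta0 = NULL, covariate_effects = NULL,
                       prevalence_target = 0.31, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_variants = as.integer(n_variants),
              maf_range = as.numeric(maf_range),
              ld_block_size = as.integer(ld_block_size),
              ld_rho = as.numeric(ld_rho),
              n_causal = as.integer(n_causal),
              causal_beta = as.numeric(causal_beta),
              intercept_beta0 = intercept_beta0,
              covariate_effects = covariate_effects,
              prevalence_target = as.numeric(prevalence_target),
              seed = as.integer(seed))
  stop_if_not(cfg$n_causal <= cfg$n_variants, "n_causal exceeds n_variants")
  stop_if_not(length(cfg$maf_range) == 2 && cfg$maf_range[1] > 0 &&
                cfg$maf_range[2] <= 0.5 && cfg$maf_range[1] <= cfg$maf_range[2],
              "maf_range must lie within (0, 0.5]")
  stop_if_not(cfg$ld_rho >= 0 && cfg$ld_rho < 1, "ld_rho must be in [0,1)")
  stop_if_not(cfg$prevalence_target > 0 && cfg$prevalence_target < 1,
              "prevalence_target must be in (0,1)")
  stop_if_not(cfg$ld_block_size >= 1, "ld_block_size must be >= 1")
  if (!is.null(cfg$covariate_effects)) {
    stop_if_not(!is.null(names(cfg$covariate_effects)) &&
                  all(nzchar(names(cfg$covariate_effects))),
                "covariate_effects must be a named numeric vector")
  }
  structure(cfg, class = "sim_config")
}

# Reference marginals the generator emulates (sibling-donor HSCT cohort):
# donor age ~ N(49, 12) truncated to [7, 72]; recipient age correlated 0.8;
# diagnosis collapsed to 4 groups; graft type 76% peripheral blood; batch
# split ~30/70 across two centres; donor-recipient sex pairs near-uniform.
.sim_ref <- list(
  donor_age = list(mean = 49, sd = 12, lo = 7, hi = 72),
  recip_age = list(mean = 51, sd = 13, lo = 3, hi = 70, r = 0.8),
  dx_levels = c("AML", "ALL", "lymphoma_myeloma", "other"),
  dx_probs = c(0.36, 0.17, 0.26, 0.21),
  graft_pb = 0.76,
  batch_hus = 0.30,
  sex_pairs = c("male-male" = 0.29, "male-female" = 0.28,
                "female-female" = 0.21, "female-male" = 0.22)
)

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

# Haplotype-level latent AR(1) threshold model: one Gaussian per haplotype
# per block, thresholded at qnorm(maf) so the marginal ALT frequency is
# exactly the target MAF while adjacent variants stay correlated.
simulate_block_dosages <- function(n, mafs, rho) {
  L <- length(mafs)
  nh <- 2L * n
  z <- matrix(rnorm(nh * L), nh, L)
  if (L > 1 && rho > 0) {
    for (k in 2:L) z[, k] <- rho * z[, k - 1] + sqrt(1 - rho^2) * z[, k]
  }
  thr <- qnorm(mafs)
  alt <- sweep(z, 2, thr, `<`)
  alt[1:n, , drop = FALSE] + alt[(n + 1):nh, , drop = FALSE]
}

simulate_covariates <- function(n) {
  ref <- .sim_ref
  da <- ref$donor_age
  z1 <- rnorm(n)
  donor_age <- qnorm(
    pnorm(da$lo, da$mean, da$sd) +
      pnorm(z1) * (pnorm(da$hi, da$mean, da$sd) - pnorm(da$lo, da$mean, da$sd)),
    da$mean, da$sd)
  ra <- ref$recip_age
  z2 <- ra$r * z1 + sqrt(1 - ra$r^2) * rnorm(n)
  recipient_age <- qnorm(
    pnorm(ra$lo, ra$mean, ra$sd) +
      pnorm(z2) * (pnorm(ra$hi, ra$mean, ra$sd) - pnorm(ra$lo, ra$mean, ra$sd)),
    ra$mean, ra$sd)
  diagnosis <- sample(ref$dx_levels, n, replace = TRUE, prob = ref$dx_probs)
  graft_type <- ifelse(runif(n) < ref$graft_pb, "peripheral_blood", "bone_marrow")
  pair <- sample(names(ref$sex_pairs), n, replace = TRUE, prob = ref$sex_pairs)
  sex <- ifelse(grepl("-male$", pair), "male", "female")
  batch <- ifelse(runif(n) < ref$batch_hus, "HUS", "TUCH")
  data.frame(donor_age = round(donor_age, 1),
             recipient_age = round(recipient_age, 1),
             diagnosis = diagnosis, graft_type = graft_type, sex = sex,
             transplant_direction = pair, batch = batch,
             stringsAsFactors = FALSE)
}

# Numeric design used by the simulator's logistic outcome model; fixed
# reference scaling so planted effects do not depend on the sampled cohort.
sim_effect_design <- function(cov_df) {
  ref <- .sim_ref$donor_age
  cbind(
    donor_age = (cov_df$donor_age - ref$mean) / ref$sd,
    graft_type = as.numeric(cov_df$graft_type == "peripheral_blood"),
    sex = as.numeric(cov_df$sex == "male"),
    batch = as.numeric(cov_df$batch == "HUS"),
    diagnosis_ALL = as.numeric(cov_df$diagnosis == "ALL"),
    diagnosis_lymphoma_myeloma = as.numeric(cov_df$diagnosis == "lymphoma_myeloma"),
    diagnosis_other = as.numeric(cov_df$diagnosis == "other")
  )
}

#' Simulate a synthetic allo-HSCT cohort with known causal structure
#'
#' Draws genotypes (LD-blocked, MAF-calibrated), clinical covariates, and a
#' relapse outcome from the logistic model
#' \deqn{\mathrm{logit}\,P(y=1) = \beta_0 + \sum_j \beta_j g_j + \sum_c \gamma_c x_c,}
#' with the intercept calibrated on a pilot sample when a prevalence target
#' is requested. Per-call GQ values are attached from a low/high mixture so
#' that GQ-threshold filtering has a visible effect; DP is Poisson.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genotypes` ([genotype_matrix()]),
#'   `metadata` ([cohort_metadata()]), and `truth` (a `sim_truth` list with
#'   `causal_indices`, `causal_ids`, `causal_betas`, `covariate_betas`,
#'   `intercept`, and `realized_prevalence`, which equals the mean of the
#'   generated outcomes exactly).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_samples = 60, n_variants = 200, seed = 7))
#' cohort$truth$realized_prevalence
#' @export
simulate_cohort <- function(config) {
  stop_if_not(inherits(config, "sim_config"), "config must be a sim_config")
  n <- config$n_samples
  m <- config$n_variants
  with_seed(config$seed, {
    mafs <- runif(m, config$maf_range[1], config$maf_range[2])
    block_id <- ((seq_len(m) - 1L) %/% config$ld_block_size) + 1L
    G <- matrix(0, n, m)
    for (b in unique(block_id)) {
      idx <- which(block_id == b)
      G[, idx] <- simulate_block_dosages(n, mafs[idx], config$ld_rho)
    }
    cov_df <- simulate_covariates(n)
    C <- sim_effect_design(cov_df)

    gamma <- setNames(numeric(ncol(C)), colnames(C))
    if (!is.null(config$covariate_effects)) {
      bad <- setdiff(names(config$covariate_effects), colnames(C))
      stop_if_not(length(bad) == 0, "unknown covariate_effects name(s): %s",
                  paste(bad, collapse = ", "))
      gamma[names(config$covariate_effects)] <- config$covariate_effects
    }

    causal_idx <- if (config$n_causal > 0) {
      sort(sample.int(m, config$n_causal))
    } else {
      integer(0)
    }
    causal_beta <- rep_len(config$causal_beta, config$n_causal)

    eta0 <- as.numeric(C %*% gamma)
    if (config$n_causal > 0) {
      eta0 <- eta0 + as.numeric(G[, causal_idx, drop = FALSE] %*% causal_beta)
    }

    b0 <- config$intercept_beta0
    if (is.null(b0)) {
      b0 <- calibrate_intercept(config, mafs, block_id, causal_idx, causal_beta,
                                gamma)
    }
    y <- rbinom(n, 1, plogis(b0 + eta0))

    gq <- matrix(ifelse(runif(n * m) < 0.3,
                        sample(5:17, n * m, replace = TRUE),
                        sample(19:60, n * m, replace = TRUE)), n, m)
    dp <- matrix(rpois(n * m, 30) + 1L, n, m)

    variants <- make_variant_table(m, block_id, mafs)
    nonmiss <- colSums(!is.na(G))
    variants$alt_frequency <- colSums(G, na.rm = TRUE) / (2 * nonmiss)

    ids <- sprintf("S%03d", seq_len(n))
    gm <- genotype_matrix(G, ids, variants, gq = gq, dp = dp)
    meta <- cohort_metadata(cbind(
      data.frame(sample_id = ids, relapse = y, stringsAsFactors = FALSE),
      cov_df))
    truth <- structure(
      list(causal_indices = causal_idx, causal_ids = variants$id[causal_idx],
           causal_betas = causal_beta, covariate_betas = gamma,
           intercept = b0, realized_prevalence = mean(y),
           target_mafs = mafs),
      class = "sim_truth")
    list(genotypes = gm, metadata = meta, truth = truth)
  })
}

# 1-D root finding for the intercept on a 10,000-draw pilot cohort; only
# blocks containing causal variants are simulated (other blocks do not
# enter the linear predictor).
calibrate_intercept <- function(config, mafs, block_id, causal_idx,
                                causal_beta, gamma, n_pilot = 10000L) {
  eta0 <- with_seed(derive_seed(config$seed, 999L), {
    Cp <- sim_effect_design(simulate_covariates(n_pilot))
    e <- as.numeric(Cp %*% gamma)
    if (length(causal_idx) > 0) {
      for (b in unique(block_id[causal_idx])) {
        idx <- which(block_id == b)
        Gb <- simulate_block_dosages(n_pilot, mafs[idx], config$ld_rho)
        keep <- idx %in% causal_idx
        e <- e + as.numeric(Gb[, keep, drop = FALSE] %*%
                              causal_beta[match(idx[keep], causal_idx)])
      }
    }
    e
  })
  f <- function(b0) mean(plogis(b0 + eta0)) - config$prevalence_target
  # bracket centered on -mean(eta0) so strong planted effects (which shift
  # the linear predictor far from zero) remain calibratable
  ctr <- -mean(eta0)
  lo <- f(ctr - 30); hi <- f(ctr + 30)
  if (lo > 0 || hi < 0) {
    stop(sprintf(
      "prevalence_target %.3f infeasible under the given effects; achievable range on the pilot is [%.4f, %.4f]",
      config$prevalence_target, lo + config$prevalence_target,
      hi + config$prevalence_target), call. = FALSE)
  }
  uniroot(f, c(ctr - 30, ctr + 30), tol = 1e-8)$root
}

make_variant_table <- function(m, block_id, mafs) {
  chrom <- as.character(((block_id - 1L) %% 22L) + 1L)
  pos <- integer(m)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    pos[i] <- 1000000L + (seq_along(i) - 1L) * 5000L
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  data.frame(chrom = chrom, pos = pos, id = sprintf("sv%06d", seq_len(m)),
             ref = ref, alt = unname(alt), alt_frequency = mafs,
             stringsAsFactors = FALSE)
}

#' GQ-dependent duplicate genotyping error model
#'
#' A step function mapping genotype quality (GQ) to the probability that a
#' re-genotyped call disagrees with the original; must be nonincreasing in
#' GQ, emulating the empirical pattern that low-quality calls drive
#' duplicate discordance.
#'
#' @param gq_grid Increasing integer GQ breakpoints; calls with
#'   `GQ >= gq_grid[k]` (and below the next breakpoint) use
#'   `error_rate[k]`. Calls below `gq_grid[1]` also use `error_rate[1]`.
#' @param error_rate Per-genotype discordance probabilities in \[0, 1\],
#'   nonincreasing.
#' @return A `duplicate_error_model`.
#' @export
duplicate_error_model <- function(gq_grid, error_rate) {
  stop_if_not(length(gq_grid) == length(error_rate),
              "gq_grid and error_rate lengths differ")
  stop_if_not(!is.unsorted(gq_grid, strictly = TRUE), "gq_grid must increase")
  stop_if_not(all(error_rate >= 0 & error_rate <= 1),
              "error rates must be in [0,1]")
  stop_if_not(all(diff(error_rate) <= 0),
              "error_rate must be nonincreasing in GQ")
  structure(list(gq_grid = as.integer(gq_grid),
                 error_rate = as.numeric(error_rate)),
            class = "duplicate_error_model")
}

error_at_gq <- function(model, gq) {
  k <- findInterval(gq, model$gq_grid)
  model$error_rate[pmax(k, 1L)]
}

#' Append duplicated samples with GQ-dependent genotyping error
#'
#' For each listed sample a duplicate column is appended (id suffixed
#' `_dup`); every non-missing call of the duplicate is flipped to one of
#' the two other genotypes with probability `error_rate_at_gq(GQ)` of the
#' original call. GQ/DP are copied from the original.
#'
#' @param gm A [genotype_matrix()] with GQ attached.
#' @param sample_ids Samples to duplicate.
#' @param model A [duplicate_error_model()].
#' @param seed Integer seed.
#' @return A [genotype_matrix()] with the duplicates appended.
#' @export
inject_duplicates <- function(gm, sample_ids, model, seed = 1L) {
  stop_if_not(inherits(model, "duplicate_error_model"),
              "model must be a duplicate_error_model")
  stop_if_not(!is.null(gm$gq), "genotype matrix has no GQ information")
  miss <- setdiff(sample_ids, gm$sample_ids)
  stop_if_not(length(miss) == 0, "unknown sample id(s): %s",
              paste(miss, collapse = ", "))
  with_seed(seed, {
    rows <- match(sample_ids, gm$sample_ids)
    dup <- gm$dosages[rows, , drop = FALSE]
    gq <- gm$gq[rows, , drop = FALSE]
    err <- matrix(error_at_gq(model, gq), nrow(dup), ncol(dup))
    flip <- !is.na(dup) & matrix(runif(length(dup)), nrow(dup)) < err
    if (any(flip)) {
      # move to one of the two other genotype values, uniformly
      shift <- 1L + (runif(sum(flip)) < 0.5)
      dup[flip] <- (dup[flip] + shift) %% 3
    }
    genotype_matrix(
      rbind(gm$dosages, dup),
      c(gm$sample_ids, paste0(sample_ids, "_dup")),
      gm$variants,
      gq = rbind(gm$gq, gq),
      dp = if (!is.null(gm$dp)) rbind(gm$dp, gm$dp[rows, , drop = FALSE])
    )
  })
}

#' Set an exact number of calls per variant to missing
#'
#' @param gm A [genotype_matrix()].
#' @param per_variant_missing Integer vector (length = number of variants,
#'   or named by variant id; unnamed variants default to 0) of calls to
#'   blank per variant; samples are chosen uniformly without replacement.
#' @param seed Integer seed.
#' @return A [genotype_matrix()] with the requested missingness pattern.
#' @export
inject_missingness <- function(gm, per_variant_missing, seed = 1L) {
  n <- nrow(gm$dosages); m <- ncol(gm$dosages)
  counts <- if (!is.null(names(per_variant_missing))) {
    out <- setNames(integer(m), gm$variants$id)
    bad <- setdiff(names(per_variant_missing), gm$variants$id)
    stop_if_not(length(bad) == 0, "unknown variant id(s): %s",
                paste(bad, collapse = ", "))
    out[names(per_variant_missing)] <- per_variant_missing
    as.integer(out)
  } else {
    stop_if_not(length(per_variant_missing) == m,
                "per_variant_missing length (%d) != n_variants (%d)",
                length(per_variant_missing), m)
    as.integer(per_variant_missing)
  }
  stop_if_not(all(counts >= 0 & counts <= n),
              "missingness counts must be in [0, n_samples]")
  with_seed(seed, {
    d <- gm$dosages
    for (j in which(counts > 0)) {
      rows <- sample.int(n, counts[j])
      d[rows, j] <- NA
      if (!is.null(gm$gq)) gm$gq[rows, j] <- NA
      if (!is.null(gm$dp)) gm$dp[rows, j] <- NA
    }
    genotype_matrix(d, gm$sample_ids, gm$variants, gq = gm$gq, dp = gm$dp)
  })
}

#' Simulate imputation output: posterior genotype probabilities and dosages
#'
#' Emulates the probabilistic genotype estimates produced by imputation:
#' for each call a Dirichlet-perturbed posterior over \{0, 1, 2\} centred on
#' the true genotype (`alpha = 1 + concentration * onehot(g)`), the
#' expected dosage, and the per-call dosage standard deviation
#' `sd = sqrt(E[g^2] - E[g]^2)`. Higher concentration gives sharper
#' posteriors; `Inf` gives a point mass (sd 0). Missing true genotypes are
#' centred on the variant's Hardy-Weinberg genotype frequencies instead.
#'
#' @param gm A [genotype_matrix()].
#' @param quality Positive concentration, scalar or per-variant.
#' @param seed Integer seed.
#' @return A `dosage_table`: list with matrices `p0`, `p1`, `p2`, `dosage`
#'   (posterior mean), `sd`, plus `sample_ids` and `variants`.
#' @export
simulate_imputed_dosages <- function(gm, quality, seed = 1L) {
  m <- ncol(gm$dosages); n <- nrow(gm$dosages)
  conc <- rep_len(as.numeric(quality), m)
  stop_if_not(all(conc > 0), "concentration must be > 0")
  with_seed(seed, {
    p <- array(NA_real_, c(n, m, 3))
    for (j in seq_len(m)) {
      g <- gm$dosages[, j]
      f <- sum(g, na.rm = TRUE) / (2 * max(sum(!is.na(g)), 1))
      hwe <- c((1 - f)^2, 2 * f * (1 - f), f^2)
      alpha <- matrix(1, n, 3)
      known <- !is.na(g)
      if (is.finite(conc[j])) {
        alpha[cbind(which(known), g[known] + 1L)] <- 1 + conc[j]
        if (any(!known)) {
          alpha[!known, ] <- rep(1 + conc[j] * hwe, each = sum(!known))
        }
        draws <- matrix(rgamma(n * 3L, shape = alpha), n, 3)
        p[, j, ] <- draws / rowSums(draws)
      } else {
        pm <- matrix(0, n, 3)
        pm[cbind(which(known), g[known] + 1L)] <- 1
        if (any(!known)) pm[!known, ] <- rep(hwe, each = sum(!known))
        p[, j, ] <- pm
      }
    }
    eg <- p[, , 2, drop = FALSE][, , 1] + 2 * p[, , 3, drop = FALSE][, , 1]
    eg2 <- p[, , 2, drop = FALSE][, , 1] + 4 * p[, , 3, drop = FALSE][, , 1]
    sd_mat <- sqrt(pmax(eg2 - eg^2, 0))
    structure(list(p0 = p[, , 1, drop = FALSE][, , 1],
                   p1 = p[, , 2, drop = FALSE][, , 1],
                   p2 = p[, , 3, drop = FALSE][, , 1],
                   dosage = eg, sd = sd_mat,
                   sample_ids = gm$sample_ids, variants = gm$variants),
              class = "dosage_table")
  })
}
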