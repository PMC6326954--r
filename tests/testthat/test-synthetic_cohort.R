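test_that("sim_config validates its invariants", {
  expect_error(sim_config(n_variants = 10, n_causal = 11), "n_causal")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(ld_rho = 1), "ld_rho")
  expect_error(sim_config(prevalence_target = 0), "prevalence")
  expect_error(sim_config(covariate_effects = c(0.5)), "named")
})

test_that("identical config gives bit-identical cohorts", {
  cfg <- sim_config(n_samples = 60, n_variants = 120, n_causal = 5,
                    causal_beta = 0.8, seed = 11,
                    covariate_effects = c(donor_age = 0.3))
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$genotypes$gq, b$genotypes$gq)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth, b$truth)
})

test_that("realized prevalence tracks the target and is recorded exactly", {
  # beta0 = 0 with no effects => expit(0) = 0.5 up to binomial error
  flat <- simulate_cohort(sim_config(n_samples = 1000, n_variants = 50,
                                     intercept_beta0 = 0, seed = 21))
  expect_lt(abs(flat$truth$realized_prevalence - 0.5), 3 * sqrt(0.25 / 1000))

  # calibrated intercept: within 3 * sqrt(p(1-p)/n) of 0.31
  cal <- simulate_cohort(sim_config(n_samples = 1000, n_variants = 50,
                                    prevalence_target = 0.31, seed = 22,
                                    n_causal = 5, causal_beta = 0.7,
                                    covariate_effects = c(graft_type = 0.4)))
  expect_lt(abs(cal$truth$realized_prevalence - 0.31),
            3 * sqrt(0.31 * 0.69 / 1000))

  expect_identical(cal$truth$realized_prevalence, mean(cal$metadata$relapse))
})

test_that("prevalence targets outside the achievable range are diagnosed", {
  expect_error(
    simulate_cohort(sim_config(n_samples = 50, n_variants = 20,
                               prevalence_target = 0.01,
                               covariate_effects = c(batch = 60), seed = 5)),
    "achievable range")
})

test_that("LD blocks induce within-block genotype correlation", {
  sim <- simulate_cohort(sim_config(n_samples = 10000, n_variants = 100,
                                    ld_block_size = 10, ld_rho = 0.9,
                                    seed = 31))
  G <- sim$genotypes$dosages
  block <- rep(1:10, each = 10)
  adj <- vapply(1:99, function(j) cor(G[, j], G[, j + 1]), 0)
  within <- adj[block[1:99] == block[2:100]]
  set.seed(1)
  across_pairs <- cbind(sample(1:50, 200, TRUE), sample(51:100, 200, TRUE))
  across <- vapply(seq_len(200), function(k)
    cor(G[, across_pairs[k, 1]], G[, across_pairs[k, 2]]), 0)
  expect_gt(mean(within), mean(abs(across)) + 0.2)
})

test_that("empirical MAF matches the target MAF spectrum", {
  n <- 800
  sim <- simulate_cohort(sim_config(n_samples = n, n_variants = 1000,
                                    maf_range = c(0.05, 0.5), seed = 41))
  p <- sim$truth$target_mafs
  emp <- colMeans(sim$genotypes$dosages) / 2
  bound <- 4 * sqrt(p * (1 - p) / (2 * n))
  expect_true(all(abs(emp - p) < bound))
})

test_that("null cohorts have uniform per-variant association p-values", {
  sim <- simulate_cohort(sim_config(n_samples = 300, n_variants = 2000,
                                    maf_range = c(0.1, 0.5), ld_rho = 0,
                                    seed = 51))
  sel <- association_filter(sim$genotypes, sim$metadata,
                            covariates = character(0), p_threshold = 0.001)
  p <- attr(sel, "pvalues")
  p <- p[!is.na(p)]
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("duplicate injection follows the GQ-dependent error model", {
  sim <- simulate_cohort(sim_config(n_samples = 40, n_variants = 400, seed = 61))
  gm <- sim$genotypes

  zero <- duplicate_error_model(c(0L), 0)
  d0 <- inject_duplicates(gm, c("S001", "S002"), zero, seed = 1)
  expect_identical(d0$dosages["S001_dup", ], d0$dosages["S001", ])
  expect_equal(nrow(d0$dosages), 42)

  one <- duplicate_error_model(c(0L), 1)
  d1 <- inject_duplicates(gm, "S001", one, seed = 1)
  expect_true(all(d1$dosages["S001_dup", ] != d1$dosages["S001", ],
                  na.rm = TRUE))

  expect_error(inject_duplicates(gm, "nope", zero), "nope")
  expect_error(duplicate_error_model(c(0L, 18L), c(0.001, 0.05)),
               "nonincreasing")
})

test_that("missingness injection is exact per variant", {
  sim <- simulate_cohort(sim_config(n_samples = 151, n_variants = 3, seed = 71))
  gm0 <- inject_missingness(sim$genotypes, c(0L, 0L, 0L), seed = 1)
  expect_identical(gm0$dosages, sim$genotypes$dosages)

  # the documented endpoint pattern: between 1 and all 151 samples missing
  gm <- inject_missingness(sim$genotypes, c(0L, 1L, 151L), seed = 2)
  expect_identical(unname(colSums(is.na(gm$dosages))), c(0, 1, 151))
  expect_error(inject_missingness(sim$genotypes, c(0L, 0L, 152L)), "counts")
})

test_that("imputed dosage posteriors have correct moments and sharpness", {
  sim <- simulate_cohort(sim_config(n_samples = 50, n_variants = 20, seed = 81))

  dt <- simulate_imputed_dosages(sim$genotypes, quality = 5, seed = 1)
  # sd identity against the posterior itself, all calls
  eg <- dt$p1 + 2 * dt$p2
  eg2 <- dt$p1 + 4 * dt$p2
  expect_equal(dt$dosage, eg, tolerance = 1e-12)
  expect_equal(dt$sd, sqrt(eg2 - eg^2), tolerance = 1e-12)
  # worked moment example: posterior (0.25, 0.5, 0.25)
  expect_equal(sqrt((0.25 * 0 + 0.5 * 1 + 0.25 * 4) - 1^2), sqrt(0.5))

  inf <- simulate_imputed_dosages(sim$genotypes, quality = Inf, seed = 1)
  expect_true(all(inf$sd == 0))
  expect_equal(inf$dosage, unname(sim$genotypes$dosages), ignore_attr = TRUE)

  msd <- vapply(c(1, 10, 100), function(conc)
    mean(simulate_imputed_dosages(sim$genotypes, conc, seed = 3)$sd), 0)
  expect_true(all(diff(msd) < 0))
  expect_error(simulate_imputed_dosages(sim$genotypes, quality = 0), "> 0")
})
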