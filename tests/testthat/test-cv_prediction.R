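test_that("association filter matches a glm oracle", {
  sim <- simulate_cohort(sim_config(n_samples = 120, n_variants = 150,
                                    n_causal = 5, causal_beta = 1.2,
                                    seed = 401))
  gm <- sim$genotypes; meta <- sim$metadata
  sel <- association_filter(gm, meta, p_threshold = 0.05)
  p_lrt <- attr(sel, "pvalues")
  p_wald <- attr(sel, "p_wald")

  cd <- relapseRF:::covariate_design(meta, c("donor_age", "diagnosis",
                                             "graft_type"))$X
  f0 <- glm(meta$relapse ~ cd, family = binomial())
  for (j in c(1, 7, 42, sim$truth$causal_indices[1])) {
    fit <- glm(meta$relapse ~ gm$dosages[, j] + cd, family = binomial())
    expect_equal(p_wald[j], summary(fit)$coefficients[2, 4],
                 tolerance = 1e-5)
    expect_equal(p_lrt[j],
                 pchisq(f0$deviance - fit$deviance, 1, lower.tail = FALSE),
                 tolerance = 1e-6)
  }
  # strict threshold semantics and p_threshold = 1 selects all converging
  all_sel <- association_filter(gm, meta, p_threshold = 1)
  st <- attr(all_sel, "diagnostics")
  expect_equal(length(all_sel),
               st[["n_tested"]] - st[["n_not_converged"]] -
                 st[["n_unstable"]] - st[["n_zero_variance"]] -
                 st[["n_too_few"]])
})

test_that("null selection count concentrates around m * alpha", {
  counts <- vapply(1:10, function(r) {
    sim <- simulate_cohort(sim_config(n_samples = 200, n_variants = 4000,
                                      ld_rho = 0, maf_range = c(0.1, 0.5),
                                      seed = 410 + r))
    length(association_filter(sim$genotypes, sim$metadata,
                              p_threshold = 0.001))
  }, 0)
  m_alpha <- 4000 * 0.001
  expect_lt(abs(mean(counts) - m_alpha), 4 * sqrt(m_alpha * 0.999 / 10))
})

test_that("a strongly associated variant is selected with high power", {
  hits <- vapply(1:60, function(r) {
    set.seed(420 + r)
    n <- 150
    g <- rbinom(n, 2, 0.4)
    y <- rbinom(n, 1, plogis(-1.5 + 1.5 * g))
    if (length(unique(y)) < 2) return(NA)
    gm <- tiny_gm(cbind(g, matrix(rbinom(n * 3, 2, 0.3), n, 3)))
    meta <- tiny_meta(y, donor_age = rnorm(n, 49, 12),
                      diagnosis = sample(c("AML", "ALL"), n, TRUE),
                      graft_type = sample(c("pb", "bm"), n, TRUE))
    1 %in% association_filter(gm, meta, p_threshold = 0.001)
  }, NA)
  expect_gt(mean(hits, na.rm = TRUE), 0.8)
})

test_that("random forest: determinism, resubstitution, OOB on noise", {
  set.seed(430)
  n <- 120
  y <- rbinom(n, 1, 0.4)
  x_perfect <- cbind(feat = y + rnorm(n, 0, 1e-6))
  cfg <- cv_config(rf_n_trees = 300)
  mod <- fit_classifier(x_perfect, y, cfg, seed = 7)
  expect_equal(as.numeric(predict(mod, x_perfect) > 0.5), y)

  mod2 <- fit_classifier(x_perfect, y, cfg, seed = 7)
  expect_identical(predict(mod, x_perfect), predict(mod2, x_perfect))
  mod3 <- fit_classifier(x_perfect, y, cfg, seed = 8)
  expect_false(identical(mod$forest$thr, mod3$forest$thr))

  x_noise <- matrix(rnorm(n * 10), n, 10)
  modn <- fit_classifier(x_noise, y, cfg, seed = 9)
  oob_acc <- mean((modn$oob_pred > 0.5) == y)
  expect_lt(abs(oob_acc - max(mean(y), 1 - mean(y))), 0.12)

  expect_error(fit_classifier(x_noise, rep(1, n), cfg), "single-class")
  expect_error(fit_classifier(x_noise[, 0], y, cfg), "at least one")
})

test_that("LOOCV structure: one out-of-fold score per sample, deterministic", {
  sim <- simulate_cohort(sim_config(n_samples = 40, n_variants = 150,
                                    n_causal = 10, causal_beta = 1.2,
                                    seed = 441))
  cfg <- cv_config(rf_n_trees = 60, base_seed = 5, p_threshold = 0.05)
  ps <- loocv_predict(sim$genotypes, sim$metadata, cfg)
  expect_length(ps$scores, 40)
  expect_identical(vapply(ps$fold_results, `[[`, "", "held_out_sample"),
                   sim$genotypes$sample_ids)
  ps2 <- loocv_predict(sim$genotypes, sim$metadata, cfg)
  expect_identical(ps$scores, ps2$scores)

  # per-fold selection really re-runs: selected lists differ somewhere
  sels <- lapply(ps$fold_results, `[[`, "selected_variants")
  jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  jmin <- min(vapply(2:40, function(i) jaccard(sels[[1]], sels[[i]]), 0))
  expect_lt(jmin, 1)
})

test_that("zero-variant folds fall back and are flagged", {
  sim <- simulate_cohort(sim_config(n_samples = 30, n_variants = 5,
                                    seed = 442))
  cfg <- cv_config(p_threshold = 1e-12, rf_n_trees = 50)
  ps <- loocv_predict(sim$genotypes, sim$metadata, cfg)
  fb <- vapply(ps$fold_results, `[[`, "", "fallback")
  expect_true(all(fb == "train_prevalence"))
  y <- sim$metadata$relapse
  expect_equal(ps$scores,
               vapply(seq_along(y), function(i) mean(y[-i]), 0))

  # with covariates enabled the fallback is a covariate-only forest
  cfg2 <- cv_config(p_threshold = 1e-12, rf_n_trees = 50,
                    include_covariates_in_rf = TRUE)
  ps2 <- loocv_predict(sim$genotypes, sim$metadata, cfg2)
  expect_true(all(vapply(ps2$fold_results, `[[`, "", "fallback") ==
                    "covariates_only"))
})

test_that("selection leakage inflates AUC relative to the nested pipeline", {
  # small-scale version of the central design property; the full-size
  # contrast runs in test-acceptance.R
  aucs <- t(vapply(1:3, function(r) {
    sim <- simulate_cohort(sim_config(n_samples = 80, n_variants = 1500,
                                      ld_rho = 0, seed = 450 + r))
    cfg <- cv_config(rf_n_trees = 80, base_seed = r, p_threshold = 0.01)
    nested <- loocv_predict(sim$genotypes, sim$metadata, cfg)
    leaky <- loocv_predict_leaky(sim$genotypes, sim$metadata, cfg)
    c(roc_auc(nested$scores, nested$labels),
      roc_auc(leaky$scores, leaky$labels))
  }, c(0, 0)))
  expect_gt(mean(aucs[, 2]), mean(aucs[, 1]) + 0.1)
})

test_that("subgroup factorization partitions the prediction set", {
  sim <- simulate_cohort(sim_config(n_samples = 80, n_variants = 50,
                                    seed = 460))
  cfg <- cv_config(rf_n_trees = 40, p_threshold = 0.2)
  ps <- loocv_predict(sim$genotypes, sim$metadata, cfg)
  groups <- unique(sim$metadata$diagnosis)
  parts <- lapply(groups, function(g)
    tryCatch(subgroup_loocv(sim$genotypes, sim$metadata, cfg, g,
                            mode = "factorize", prediction_set_in = ps),
             error = function(e) NULL))
  kept <- parts[!vapply(parts, is.null, NA)]
  ids <- unlist(lapply(kept, `[[`, "sample_ids"))
  expect_false(anyDuplicated(ids) > 0)
  for (pp in kept) {
    expect_identical(pp$scores,
                     ps$scores[match(pp$sample_ids, ps$sample_ids)])
  }

  # a single-class stratum raises an error naming it
  meta2 <- sim$metadata
  meta2$diagnosis <- "ALL"
  meta2$diagnosis[which(ps$labels == 1)[1:5]] <- "AML"
  expect_error(subgroup_loocv(sim$genotypes, meta2, cfg, "AML",
                              mode = "factorize", prediction_set_in = ps),
               "single-class")
})
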