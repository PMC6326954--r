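test_that("variant matching: identity, allele swap, palindromes", {
  disc <- data.frame(chrom = c("1", "1", "2", "3"),
                     pos = c(100L, 200L, 300L, 400L),
                     id = c("a", "b", "c", "d"),
                     ref = c("A", "C", "A", "G"),
                     alt = c("G", "T", "T", "C"),
                     stringsAsFactors = FALSE)
  panel_d <- matrix(c(0, 1, 2,
                      2, 1, 0,
                      1, 1, 2), 3, 3)
  panel <- tiny_gm(panel_d, chrom = c("1", "1", "3"),
                   pos = c(100, 200, 400),
                   ref = c("A", "T", "G"), alt = c("G", "C", "C"))
  rep <- match_variants(disc, panel)
  expect_equal(rep$requested_variants, 4)
  expect_equal(rep$found_on_panel, 3)
  expect_identical(rep$unmatched, "c")
  m <- rep$matches
  expect_false(m$flip[m$id == "a"])
  expect_true(m$flip[m$id == "b"])      # C/T on panel as T/C
  expect_true(m$ambiguous[m$id == "d"]) # G/C palindrome
  expect_false(m$ambiguous[m$id == "a"])

  # flip consistency: flipped dosages reproduce discovery orientation
  out <- apply_matches(panel, rep)
  expect_identical(unname(out$dosages[, out$variants$pos == 200]),
                   2 - panel_d[, 2])
  expect_identical(out$variants$ref[out$variants$pos == 200], "C")
})

test_that("missingness filter: worked example and complete-case removal", {
  n <- 151
  d <- matrix(1, n, 5)
  miss_counts <- c(0L, 0L, 3L, 12L, 80L)
  gm <- inject_missingness(tiny_gm(d), miss_counts, seed = 7)

  kept1 <- missingness_filter(gm, max_missing = 1)
  expect_equal(ncol(kept1$dosages), 2)
  expect_equal(nrow(kept1$dosages), 151)

  kept13 <- missingness_filter(gm, max_missing = 13)
  expect_equal(ncol(kept13$dosages), 4)
  # brute force on the mask: complete cases over the four kept variants
  expected_samples <- sum(rowSums(is.na(gm$dosages[, 1:4])) == 0)
  expect_equal(nrow(kept13$dosages), expected_samples)
  expect_equal(sum(is.na(kept13$dosages)), 0)

  # samples kept is nonincreasing as max_missing grows (random masks)
  set.seed(71)
  for (rep in 1:5) {
    counts <- sample(0:30, 8, replace = TRUE)
    gmr <- inject_missingness(tiny_gm(matrix(1, 40, 8)),
                              as.integer(pmin(counts, 40)), seed = rep)
    kept <- vapply(c(1, 5, 15, 31), function(mm) {
      res <- tryCatch(missingness_filter(gmr, mm), error = function(e) NULL)
      if (is.null(res)) 0L else nrow(res$dosages)
    }, 0L)
    nonzero <- kept[kept > 0]
    expect_true(all(diff(nonzero) <= 0))
  }
})

test_that("dosage SD filter thresholds per-variant mean uncertainty", {
  dt <- structure(list(
    sd = cbind(matrix(0.1, 10, 1), matrix(0.25, 10, 1), matrix(0.35, 10, 1)),
    variants = data.frame(id = c("x", "y", "z"))), class = "dosage_table")
  kept <- dosage_sd_filter(dt, sd_max = 0.3)
  expect_identical(as.integer(kept), c(1L, 2L))

  zero <- dt; zero$sd[] <- 0
  expect_length(dosage_sd_filter(zero, 0.01), 3)

  counts <- vapply(c(0.05, 0.2, 0.3, 0.5), function(s)
    length(dosage_sd_filter(dt, s)), 0L)
  expect_true(all(diff(counts) >= 0))
  expect_error(dosage_sd_filter(list(), 0.3), "dosage")
})

test_that("fixed-set replication LOOCV never reselects variants", {
  sim <- simulate_cohort(sim_config(n_samples = 40, n_variants = 30,
                                    n_causal = 8, causal_beta = 1.2,
                                    seed = 701))
  cfg <- replication_config(cv = cv_config(rf_n_trees = 50))
  ps <- replicate_loocv(sim$genotypes, sim$metadata,
                        sim$truth$causal_ids, cfg)
  sels <- unique(lapply(ps$fold_results, `[[`, "selected_variants"))
  expect_length(sels, 1)
  expect_setequal(sels[[1]], sim$truth$causal_ids)
})

test_that("replication recovers shared effects and stays null without them", {
  cfg_sig <- sim_config(n_samples = 260, n_variants = 60, n_causal = 12,
                        causal_beta = 1.2, maf_range = c(0.2, 0.5),
                        seed = 702)
  sim <- simulate_cohort(cfg_sig)
  # split one generated cohort so discovery and replication share SimTruth
  repl_idx <- 131:260
  gm_rep <- subset_genotypes(sim$genotypes, samples = repl_idx)
  meta_rep <- cohort_metadata(sim$metadata[repl_idx, , drop = FALSE])
  rcfg <- replication_config(cv = cv_config(rf_n_trees = 150, base_seed = 3))
  ps <- replicate_loocv(gm_rep, meta_rep, sim$truth$causal_ids, rcfg)
  expect_gt(roc_auc(ps$scores, ps$labels), 0.62)

  null <- simulate_cohort(sim_config(n_samples = 130, n_variants = 60,
                                     seed = 703))
  ps0 <- replicate_loocv(null$genotypes, null$metadata,
                         null$genotypes$variants$id[1:12], rcfg)
  auc0 <- roc_auc(ps0$scores, ps0$labels)
  expect_true(auc0 > 0.3 && auc0 < 0.65)
})

test_that("imputed-dosage replication uses expected dosages", {
  sim <- simulate_cohort(sim_config(n_samples = 60, n_variants = 25,
                                    n_causal = 10, causal_beta = 1.3,
                                    seed = 704))
  dt <- simulate_imputed_dosages(sim$genotypes, quality = 60, seed = 5)
  cfg <- replication_config(use_dosages = TRUE,
                            cv = cv_config(rf_n_trees = 80))
  ps <- replicate_loocv(sim$genotypes, sim$metadata, sim$truth$causal_ids,
                        cfg, dosage_table = dt)
  expect_length(ps$scores, 60)
  expect_true(all(ps$scores >= 0 & ps$scores <= 1))
})
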