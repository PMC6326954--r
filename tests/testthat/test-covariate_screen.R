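test_that("compute_pcs agrees with a dense eigendecomposition oracle", {
  set.seed(301)
  d <- matrix(rbinom(20 * 50, 2, 0.4), 20, 50)
  d[, 1] <- 1  # zero variance, must be excluded with a note
  gm <- tiny_gm(d)
  pca <- compute_pcs(gm, k = 5)
  expect_equal(attr(pca, "excluded_variants"), "v001")

  X <- scale(d[, -1])
  ev_oracle <- eigen(crossprod(X) / (nrow(X) - 1), symmetric = TRUE)$values
  expect_equal(pca$eigenvalues[seq_len(ncol(pca$scores))],
               ev_oracle[seq_len(ncol(pca$scores))], tolerance = 1e-8)
  # scores = standardized matrix %*% loadings
  expect_equal(unname(pca$scores), unname(X %*% pca$loadings),
               tolerance = 1e-8)
  # orthogonality of scores
  G <- crossprod(pca$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  # eigenvalue sum equals total variance of the standardized matrix
  expect_equal(sum(pca$eigenvalues), ncol(X), tolerance = 1e-8)
})

test_that("PC1 separates two constructed clusters", {
  set.seed(302)
  base <- matrix(rbinom(40 * 30, 2, 0.5), 40, 30)
  base[1:20, 1:15] <- base[1:20, 1:15] * 0  # cluster offset
  pca <- compute_pcs(tiny_gm(base), k = 2)
  cl <- pca$scores[, 1] > median(pca$scores[, 1])
  expect_true(all(cl[1:20] == cl[1]) && all(cl[21:40] == cl[21]) &&
                cl[1] != cl[21])
  expect_gt(pca$eigenvalues[1] / pca$eigenvalues[2], 2)
})

test_that("scree stabilization rule matches direct evaluation", {
  expect_equal(select_pc_count(c(10, 5, 2, 1, 1, 1, 1), tol = 0.02), 4)
  expect_equal(select_pc_count(rep(3, 6)), 1)

  ev <- 2^-(1:10)
  # closed-form normalized gaps: gap_j = 2^-(j+1) / (2^-1 - 2^-10)
  gaps <- 2^-((1:9) + 1) / (2^-1 - 2^-10)
  expected <- min(which(rev(cumprod(rev(gaps < 0.02))) > 0))
  expect_equal(select_pc_count(ev, tol = 0.02), expected)
  expect_equal(expected, 6)

  expect_error(select_pc_count(3), "at least 2")
})

test_that("collinearity pruning drops the lower-priority of correlated pairs", {
  set.seed(303)
  n <- 300
  donor <- rnorm(n, 49, 12)
  recip <- 0.8 * scale(donor)[, 1] * 13 + sqrt(1 - 0.64) * rnorm(n, 0, 13) + 51
  meta <- tiny_meta(rbinom(n, 1, 0.3), donor_age = donor,
                    recipient_age = recip,
                    graft_type = sample(c("pb", "bm"), n, TRUE),
                    batch = sample(c("A", "B"), n, TRUE))
  res <- collinearity_prune(meta, r_threshold = 0.45)
  expect_true("donor_age" %in% res$kept_covariates)
  expect_true("recipient_age" %in% res$dropped_collinear$dropped)
  expect_equal(res$dropped_collinear$r[1], 0.8, tolerance = 0.1)
  # no kept pair remains above the threshold
  sub <- res$r_matrix[res$kept_covariates, res$kept_covariates]
  diag(sub) <- 0
  expect_lt(max(sub), 0.45)

  # identical columns: r = 1, one dropped
  meta2 <- tiny_meta(rbinom(50, 1, 0.5), a = rnorm(50))
  meta2$b <- meta2$a
  res2 <- collinearity_prune(meta2, covariates = c("a", "b"),
                             priority = c("a", "b"))
  expect_identical(res2$kept_covariates, "a")
  expect_equal(res2$dropped_collinear$r, 1.0)

  # nothing correlated: nothing dropped
  set.seed(304)
  meta3 <- tiny_meta(rbinom(200, 1, 0.5), a = rnorm(200), b = rnorm(200))
  res3 <- collinearity_prune(meta3, covariates = c("a", "b"))
  expect_equal(nrow(res3$dropped_collinear), 0)
})

test_that("nominal screen keeps p < alpha and flags degenerate covariates", {
  set.seed(305)
  n <- 400
  y <- rbinom(n, 1, 0.4)
  meta <- tiny_meta(y, strong = y + rnorm(n, 0, 0.1), noise = rnorm(n),
                    const = rep(1, n))
  res <- nominal_screen(meta, c("strong", "noise", "const"), alpha = 0.1)
  expect_true("strong" %in% res$kept_covariates)
  expect_identical(res$flagged[["const"]], "zero-variance")
  expect_true(is.na(res$nominal_pvalues[["const"]]))

  # alpha = 1 keeps every non-degenerate covariate; alpha = 0 keeps none
  expect_setequal(nominal_screen(meta, c("strong", "noise"), 1)$kept_covariates,
                  c("strong", "noise"))
  expect_length(nominal_screen(meta, c("strong", "noise"), 0)$kept_covariates,
                0)
})

test_that("null covariates are selected at roughly rate alpha", {
  set.seed(306)
  hits <- vapply(1:300, function(r) {
    y <- rbinom(300, 1, 0.3)
    meta <- tiny_meta(y, x = rnorm(300))
    "x" %in% nominal_screen(meta, "x", alpha = 0.1)$kept_covariates
  }, NA)
  expect_equal(mean(hits), 0.1, tolerance = 0.055)
})

test_that("PC loading report localizes constructed MHC structure", {
  set.seed(307)
  n <- 60; m <- 100
  d <- matrix(rbinom(n * m, 2, 0.4), n, m)
  latent <- rnorm(n)
  d[, 1:20] <- pmin(pmax(round(d[, 1:20] + latent), 0), 2)  # chr6 block
  chrom <- c(rep("6", 20), rep("2", 80))
  pos <- c(seq(29e6, by = 1e5, length.out = 20),
           seq(1e6, by = 1e5, length.out = 80))
  gm <- tiny_gm(d, chrom = chrom, pos = pos)
  pca <- compute_pcs(gm, k = 3)
  rep1 <- pc_loading_report(pca, gm$variants, component = 1, top_q = 15)
  expect_equal(rep1$fraction_in_region, 1.0)

  # uniform loadings: fraction near the region's share of variants
  set.seed(308)
  d2 <- matrix(rbinom(200 * 400, 2, 0.4), 200, 400)
  chrom2 <- rep(c("6", "2"), each = 200)
  pos2 <- c(seq(29e6, by = 1e4, length.out = 200),
            seq(1e6, by = 1e4, length.out = 200))
  gm2 <- tiny_gm(d2, chrom = chrom2, pos = pos2)
  pca2 <- compute_pcs(gm2, k = 2)
  rep2 <- pc_loading_report(pca2, gm2$variants, component = 1, top_q = 400)
  expect_equal(rep2$fraction_in_region, 0.5, tolerance = 1e-12)

  rep3 <- pc_loading_report(pca2, gm2$variants, component = 1, top_q = 1000)
  expect_true(rep3$truncated)
})
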