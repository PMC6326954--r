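# Small in-code fixture builders shared across test files.

# genotype matrix from a dosage matrix with auto-filled variant table
tiny_gm <- function(d, chrom = NULL, pos = NULL, ref = NULL, alt = NULL,
                    gq = NULL, dp = NULL, ids = NULL) {
  d <- as.matrix(d)
  m <- ncol(d)
  variants <- data.frame(
    chrom = chrom %||% rep("1", m),
    pos = pos %||% seq(1000, by = 1000, length.out = m),
    id = sprintf("v%03d", seq_len(m)),
    ref = ref %||% rep("A", m),
    alt = alt %||% rep("G", m),
    stringsAsFactors = FALSE)
  genotype_matrix(d, ids %||% sprintf("S%03d", seq_len(nrow(d))), variants,
                  gq = gq, dp = dp)
}

tiny_meta <- function(y, ...) {
  extra <- list(...)
  df <- data.frame(sample_id = sprintf("S%03d", seq_along(y)), relapse = y,
                   stringsAsFactors = FALSE)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  cohort_metadata(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force enumeration oracle for the one-sided Mann-Whitney p-value:
# all C(N, n1) assignments of the pooled scores to the positive group.
mw_enum_p <- function(pos, neg) {
  pooled <- c(pos, neg)
  n1 <- length(pos)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(length(pooled), n1)
  mean(apply(combos, 2, u_of) >= u_obs)
}

# fabricated prediction_set with given per-fold selections/importances
fake_ps <- function(folds, universe, scores = NULL, labels = NULL) {
  n <- length(folds)
  prediction_set(sprintf("S%03d", seq_len(n)),
                 scores %||% rep(0.5, n),
                 labels %||% rep(c(0, 1), length.out = n),
                 fold_results = folds, variant_universe = universe)
}
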