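#' Write a genotype matrix as VCF 4.2
#'
#' Emits one record per variant with FORMAT `GT:GQ:DP` (GQ/DP written when
#' attached, `.` otherwise). Dosages 0/1/2 map to `0/0`, `0/1`, `1/1`;
#' missing calls to `./.`.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path (plain text, uncompressed).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  n <- nrow(gm$dosages); m <- ncol(gm$dosages)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=relapseRF",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$sample_ids), collapse = "\t")
  ), con)
  gt_map <- c("0/0", "0/1", "1/1")
  has_q <- !is.null(gm$gq)
  has_d <- !is.null(gm$dp)
  lines <- character(m)
  for (j in seq_len(m)) {
    g <- gm$dosages[, j]
    gt <- ifelse(is.na(g), "./.", gt_map[g + 1L])
    gq <- if (has_q) ifelse(is.na(gm$gq[, j]), ".", gm$gq[, j]) else rep(".", n)
    dp <- if (has_d) ifelse(is.na(gm$dp[, j]), ".", gm$dp[, j]) else rep(".", n)
    v <- gm$variants[j, ]
    lines[j] <- paste(c(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".",
                        "GT:GQ:DP", paste(gt, gq, dp, sep = ":")),
                      collapse = "\t")
  }
  writeLines(lines, con)
  invisible(path)
}

#' Write a genotype matrix as a PLINK 1.9 .bed/.bim/.fam triplet
#'
#' SNP-major .bed (magic bytes `6c 1b 01`); A1 is the ALT allele, so the
#' 2-bit codes encode the ALT dosage (00 = 2, 10 = 1, 11 = 0, 01 = missing).
#' Multi-allelic records cannot be represented and raise an error.
#'
#' @param gm A [genotype_matrix()].
#' @param prefix Output path prefix (files `<prefix>.bed/.bim/.fam`).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(gm, prefix) {
  stop_if_not(!any(grepl(",", gm$variants$alt)),
              "PLINK output requires biallelic variants; run filter_biallelic()")
  n <- nrow(gm$dosages); m <- ncol(gm$dosages)
  v <- gm$variants
  write.table(
    data.frame(v$chrom, v$id, 0, v$pos, v$alt, v$ref),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  write.table(
    data.frame(gm$sample_ids, gm$sample_ids, 0, 0, 0, -9),
    paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  # dosage -> 2-bit code: 2->0, missing->1, 1->2, 0->3
  code_map <- c(3L, 2L, 0L)
  codes <- matrix(1L, n, m)
  ok <- !is.na(gm$dosages)
  codes[ok] <- code_map[gm$dosages[ok] + 1L]
  npad <- 4L * ceiling(n / 4L)
  if (npad > n) codes <- rbind(codes, matrix(0L, npad - n, m))
  i1 <- seq(1, npad, by = 4)
  bytes <- codes[i1, , drop = FALSE] + 4L * codes[i1 + 1, , drop = FALSE] +
    16L * codes[i1 + 2, , drop = FALSE] + 64L * codes[i1 + 3, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}

read_plink <- function(prefix) {
  bim <- data.table::fread(paste0(prefix, ".bim"), header = FALSE,
                           colClasses = list(character = c(1, 2, 5, 6)))
  fam <- data.table::fread(paste0(prefix, ".fam"), header = FALSE,
                           colClasses = list(character = c(1, 2)))
  m <- nrow(bim); n <- nrow(fam)
  bed <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + ceiling(n / 4) * m)
  stop_if_not(length(bed) >= 3 && bed[1] == as.raw(0x6c) &&
                bed[2] == as.raw(0x1b) && bed[3] == as.raw(0x01),
              "not a SNP-major PLINK 1.9 .bed file: %s.bed", prefix)
  body <- as.integer(bed[-(1:3)])
  stop_if_not(length(body) == ceiling(n / 4) * m,
              ".bed size inconsistent with .bim/.fam")
  bytes <- matrix(body, ceiling(n / 4), m)
  codes <- rbind(bytes %% 4L, (bytes %/% 4L) %% 4L,
                 (bytes %/% 16L) %% 4L, (bytes %/% 64L) %% 4L)
  # interleave: rows come out grouped by bit position, reorder to samples
  ord <- as.vector(t(matrix(seq_len(4 * ceiling(n / 4)), ncol = 4)))
  codes <- codes[ord, , drop = FALSE][seq_len(n), , drop = FALSE]
  dose_map <- c(2, NA, 1, 0)
  d <- matrix(dose_map[codes + 1L], n, m)
  variants <- data.frame(chrom = bim$V1, pos = bim$V4, id = bim$V2,
                         ref = bim$V6, alt = bim$V5, stringsAsFactors = FALSE)
  variants$alt_frequency <- colSums(d, na.rm = TRUE) /
    (2 * pmax(colSums(!is.na(d)), 1))
  genotype_matrix(d, fam$V2, variants)
}

read_vcf_genotypes <- function(path) {
  stop_if_not(requireNamespace("VariantAnnotation", quietly = TRUE),
              "reading VCF requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt_list <- VariantAnnotation::alt(vcf)
  alt <- vapply(seq_along(alt_list),
                function(i) paste(as.character(alt_list[[i]]), collapse = ","),
                "")
  variants <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    id = names(rr) %||% sprintf("v%06d", seq_along(rr)),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = unname(alt), stringsAsFactors = FALSE)
  geno <- VariantAnnotation::geno(vcf)
  stop_if_not("GT" %in% names(geno), "VCF has no GT field: %s", path)
  gt <- geno$GT  # variants x samples, strings like "0/1"
  d <- apply(gt, c(1, 2), function(s) {
    if (is.na(s) || s %in% c("./.", ".", ".|.")) return(NA_real_)
    al <- strsplit(s, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    sum(al != "0")
  })
  d <- t(d)
  samp <- colnames(gt)
  stop_if_not(!anyDuplicated(samp), "duplicate sample ids in VCF: %s", path)
  to_int_mat <- function(x) {
    if (is.null(x)) return(NULL)
    mm <- t(matrix(as.integer(x), nrow(gt), ncol(gt)))
    mm
  }
  gq <- if ("GQ" %in% names(geno)) to_int_mat(geno$GQ)
  dp <- if ("DP" %in% names(geno)) to_int_mat(geno$DP)
  variants$alt_frequency <- colSums(d, na.rm = TRUE) /
    (2 * pmax(colSums(!is.na(d)), 1))
  rownames(d) <- samp
  genotype_matrix(d, samp, variants, gq = gq, dp = dp)
}

#' Load genotype data from standard formats
#'
#' @param path File path (VCF or dosage TSV) or PLINK prefix.
#' @param format One of `"vcf"` (4.2, GT/GQ/DP), `"plink"`
#'   (PLINK 1.9 SNP-major bed/bim/fam), or `"dosage"` (a long-format TSV as
#'   written by [write_dosage_table()]; expected dosages are rounded to
#'   hard calls only when loading into a genotype matrix is requested).
#' @return A [genotype_matrix()] (for `"dosage"`, a `dosage_table`).
#' @export
load_genotypes <- function(path, format = c("vcf", "plink", "dosage")) {
  format <- match.arg(format)
  if (format != "plink") {
    stop_if_not(file.exists(path), "file not found: %s", path)
  }
  switch(format,
         vcf = read_vcf_genotypes(path),
         plink = read_plink(path),
         dosage = read_dosage_table(path))
}

#' Write cohort metadata as TSV
#' @param meta A [cohort_metadata()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cohort metadata from TSV
#' @param path Input path.
#' @return A [cohort_metadata()].
#' @export
read_metadata <- function(path) {
  cohort_metadata(as.data.frame(data.table::fread(path, sep = "\t")))
}

#' Write an imputed dosage table (long TSV)
#'
#' Columns: sample_id, variant_id, p0, p1, p2, dosage, sd.
#' @param dt A `dosage_table` from [simulate_imputed_dosages()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosage_table <- function(dt, path) {
  n <- length(dt$sample_ids); m <- nrow(dt$variants)
  out <- data.frame(
    sample_id = rep(dt$sample_ids, m),
    variant_id = rep(dt$variants$id, each = n),
    p0 = as.vector(dt$p0), p1 = as.vector(dt$p1), p2 = as.vector(dt$p2),
    dosage = as.vector(dt$dosage), sd = as.vector(dt$sd))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_dosage_table <- function(path) {
  x <- as.data.frame(data.table::fread(path, sep = "\t"))
  samp <- unique(x$sample_id)
  vids <- unique(x$variant_id)
  shape <- function(col) {
    m <- matrix(NA_real_, length(samp), length(vids),
                dimnames = list(samp, vids))
    m[cbind(match(x$sample_id, samp), match(x$variant_id, vids))] <- x[[col]]
    m
  }
  structure(list(p0 = shape("p0"), p1 = shape("p1"), p2 = shape("p2"),
                 dosage = shape("dosage"), sd = shape("sd"),
                 sample_ids = samp,
                 variants = data.frame(id = vids, stringsAsFactors = FALSE)),
            class = "dosage_table")
}

#' Write simulation ground truth as a JSON sidecar
#' @param truth A `sim_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
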