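#' Genotype matrix for inbred accessions
#'
#' Container for biallelic genotypes of fully homozygous (inbred) lines,
#' coded 0 and 2 for the two homozygotes with `NA` for missing calls.
#' Heterozygous calls, if present in the input, are recoded according to the
#' heterozygote policy of the loader (default: set missing).
#'
#' @param codes integer matrix, accessions in rows and SNPs in columns, values
#'   in `{0, 2, NA}`.
#' @param accession_ids character vector of unique accession identifiers.
#' @param snps data frame with one row per SNP: `snp_id`, `chrom`, `pos`
#'   (1-based bp), `ref`, `alt`. A `maf` column is (re)computed from `codes`.
#' @return An object of class `genotype_matrix`: a list with elements `codes`
#'   (dimnames set to accession and SNP ids) and `snps` (per-SNP metadata
#'   including `maf`).
#' @export
genotype_matrix <- function(codes, accession_ids, snps) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (anyDuplicated(accession_ids))
    stop("accession ids must be unique", call. = FALSE)
  if (length(accession_ids) != nrow(codes))
    stop("length(accession_ids) must equal nrow(codes)", call. = FALSE)
  if (nrow(snps) != ncol(codes))
    stop("nrow(snps) must equal ncol(codes)", call. = FALSE)
  bad <- !(codes %in% c(0L, 2L, NA_integer_))
  if (any(bad))
    stop("genotype codes must be 0, 2 or NA", call. = FALSE)
  for (ch in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == ch]
    if (any(diff(p) <= 0))
      stop(sprintf("positions not strictly increasing on chromosome %s", ch),
           call. = FALSE)
  }
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  snps$maf <- compute_maf(codes)
  dimnames(codes) <- list(accession_ids, snps$snp_id)
  structure(list(codes = codes, snps = snps), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d accessions x %d SNPs (codes 0/2, %d missing)\n",
              nrow(x$codes), ncol(x$codes), sum(is.na(x$codes))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

#' Minor allele frequencies from 0/2 codes
#'
#' @param codes matrix of 0/2/NA genotype codes (accessions x SNPs).
#' @return numeric vector of per-SNP minor allele frequencies in `[0, 0.5]`,
#'   computed from non-missing calls.
#' @export
compute_maf <- function(codes) {
  if (inherits(codes, "genotype_matrix")) codes <- codes$codes
  p <- colMeans(codes, na.rm = TRUE) / 2   # alt-allele frequency
  p[is.nan(p)] <- 0
  pmin(p, 1 - p)
}

#' Exclude SNPs with minor allele frequency below a threshold
#'
#' SNPs with MAF strictly less than `threshold` are excluded; a SNP at exactly
#' the threshold is kept. SNP order is preserved.
#'
#' @param G a [genotype_matrix].
#' @param threshold MAF cutoff in `[0, 0.5]`; default 0.05.
#' @return the filtered [genotype_matrix].
#' @export
maf_filter <- function(G, threshold = 0.05) {
  stopifnot(inherits(G, "genotype_matrix"))
  stopifnot_scalar_number(threshold, "threshold")
  if (threshold < 0 || threshold > 0.5)
    stop("'threshold' must lie in [0, 0.5]", call. = FALSE)
  keep <- G$snps$maf >= threshold
  subset_genotypes(G, snps = keep)
}

#' Subset a genotype matrix by accessions and/or SNPs
#'
#' @param G a [genotype_matrix].
#' @param accessions,snps index vectors (logical, integer or names); `NULL`
#'   keeps everything.
#' @return the subsetted [genotype_matrix] with MAF recomputed.
#' @export
subset_genotypes <- function(G, accessions = NULL, snps = NULL) {
  codes <- G$codes
  meta <- G$snps
  if (!is.null(snps)) {
    if (is.character(snps)) snps <- match(snps, meta$snp_id)
    codes <- codes[, snps, drop = FALSE]
    meta <- meta[snps, , drop = FALSE]
  }
  if (!is.null(accessions)) {
    if (is.character(accessions)) accessions <- match(accessions, rownames(G$codes))
    codes <- codes[accessions, , drop = FALSE]
  }
  genotype_matrix(codes, rownames(codes), meta)
}

# ---------------------------------------------------------------------------
# readers / writers

parse_snp_ids <- function(ids) {
  # ids written by this package are "chrom:pos:ref:alt"; also accept
  # "chrom:pos" and "chrom_pos"; anything else gets running positions
  m <- regmatches(ids, regexec("^(.+?)[:_](\\d+)(?::([A-Za-z*]+):([A-Za-z*]+))?$", ids))
  ok <- lengths(m) > 0
  chrom <- rep("un", length(ids)); pos <- seq_along(ids)
  ref <- rep("A", length(ids)); alt <- rep("T", length(ids))
  if (all(ok)) {
    chrom <- vapply(m, `[`, "", 2L)
    pos <- as.integer(vapply(m, `[`, "", 3L))
    r <- vapply(m, `[`, "", 4L); a <- vapply(m, `[`, "", 5L)
    ref <- ifelse(nzchar(r), r, "A")
    alt <- ifelse(nzchar(a), a, "T")
  }
  data.frame(snp_id = ids, chrom = chrom, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

#' Load a genotype matrix from PLINK, VCF or CSV
#'
#' CSV dialect: header row of SNP ids, first column the accession id, cells in
#' `{0, 2, NA}`. SNP ids of the form `chrom:pos[:ref:alt]` (or `chrom_pos`)
#' carry the metadata. VCF genotypes `0/0` map to 0, `1/1` to 2; heterozygous
#' calls follow `het_policy`; non-biallelic records are skipped with a
#' warning. PLINK input expects the `.bed`/`.bim`/`.fam` triple (SNP-major
#' bed); the A1 allele of the bim file is counted as the alternative allele.
#'
#' @param path file path (for PLINK, the `.bed` path or the common prefix).
#' @param format one of `"csv"`, `"vcf"`, `"plink"`; guessed from the file
#'   extension when `NULL`.
#' @param het_policy what to do with heterozygous calls: `"missing"`
#'   (default, appropriate for inbred lines). The strict 0/2 coding cannot
#'   hold a midpoint, so `"midpoint"` is accepted for interface
#'   compatibility but behaves as `"missing"` with a warning; a missing
#'   call is mean-imputed at standardization time, which recovers the
#'   midpoint on average.
#' @return a [genotype_matrix].
#' @export
load_genotypes <- function(path, format = NULL, het_policy = c("missing", "midpoint")) {
  het_policy <- match.arg(het_policy)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", vcf = "vcf", gz = "vcf",
                     bed = "plink", bim = "plink", fam = "plink",
                     stop("cannot guess genotype format from ", path, call. = FALSE))
  }
  format <- match.arg(format, c("csv", "vcf", "plink"))
  if (!format == "plink" && !file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  switch(format,
         csv = read_genotypes_csv(path),
         vcf = read_genotypes_vcf(path, het_policy),
         plink = read_genotypes_plink(path, het_policy))
}

read_genotypes_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("genotype CSV needs an accession column and >=1 SNP",
                         call. = FALSE)
  acc <- as.character(df[[1]])
  codes <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(codes) <- "integer"
  if (any(!codes %in% c(0L, 2L, NA_integer_)))
    stop("genotype CSV cells must be 0, 2 or NA", call. = FALSE)
  genotype_matrix(codes, acc, parse_snp_ids(colnames(df)[-1]))
}

#' Write a genotype matrix to the package CSV dialect
#'
#' @param G a [genotype_matrix].
#' @param path output path.
#' @return `path`, invisibly. Reading the file back with [load_genotypes]
#'   reproduces codes and SNP metadata exactly.
#' @export
write_genotypes_csv <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  ids <- with(G$snps, paste(chrom, pos, ref, alt, sep = ":"))
  df <- data.frame(accession_id = rownames(G$codes), G$codes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("accession_id", ids)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

read_genotypes_vcf <- function(path, het_policy) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & !grepl(",", alt, fixed = TRUE)
  if (any(!biallelic))
    warning(sum(!biallelic), " non-biallelic site(s) skipped", call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  g <- gsub("|", "/", gt, fixed = TRUE)
  codes <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt))
  codes[t(g == "0/0")] <- 0L
  codes[t(g == "1/1")] <- 2L
  if (het_policy == "midpoint")
    warning("0/2 coding cannot hold heterozygote midpoints; treating as missing",
            call. = FALSE)
  snps <- data.frame(
    snp_id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                    paste(fix[, "CHROM"], fix[, "POS"], sep = ":"), fix[, "ID"]),
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"], stringsAsFactors = FALSE)
  genotype_matrix(codes, colnames(gt), snps)
}

# minimal SNP-major PLINK .bed reader (no installed R package provides one)
read_genotypes_plink <- function(path, het_policy) {
  prefix <- sub("\\.(bed|bim|fam)$", "", path)
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  famdf <- utils::read.table(fam, stringsAsFactors = FALSE)
  bimdf <- utils::read.table(bim, stringsAsFactors = FALSE,
                             col.names = c("chrom", "snp_id", "cm", "pos", "a1", "a2"))
  n <- nrow(famdf); m <- nrow(bimdf)
  raw <- readBin(bed, "raw", n = 3 + ceiling(n / 4) * m)
  if (!identical(as.integer(raw[1:3]), c(108L, 27L, 1L)))
    stop("not a SNP-major PLINK .bed file: ", bed, call. = FALSE)
  body <- raw[-(1:3)]
  bpsnp <- ceiling(n / 4)
  # 2-bit codes per individual: 00 hom A1, 01 missing, 10 het, 11 hom A2
  lut <- matrix(NA_integer_, nrow = 256, ncol = 4)
  for (b in 0:255) {
    q <- bitwAnd(bitwShiftR(b, c(0L, 2L, 4L, 6L)), 3L)
    lut[b + 1, ] <- ifelse(q == 0L, 2L, ifelse(q == 3L, 0L, NA_integer_))
  }
  codes <- matrix(NA_integer_, nrow = n, ncol = m)
  for (j in seq_len(m)) {
    bytes <- as.integer(body[((j - 1) * bpsnp + 1):(j * bpsnp)])
    vals <- t(lut[bytes + 1, , drop = FALSE])
    codes[, j] <- as.vector(vals)[seq_len(n)]
  }
  snps <- data.frame(snp_id = bimdf$snp_id, chrom = as.character(bimdf$chrom),
                     pos = as.integer(bimdf$pos), ref = bimdf$a2, alt = bimdf$a1,
                     stringsAsFactors = FALSE)
  genotype_matrix(codes, as.character(famdf[[2]]), snps)
}

#' Read a phenotype table
#'
#' Two-column CSV `(accession_id, value)`; values must be finite and
#' accessions unique.
#'
#' @param path CSV path.
#' @return data frame with columns `accession_id` (character) and `value`.
#' @export
read_phenotype <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("phenotype CSV needs two columns", call. = FALSE)
  out <- data.frame(accession_id = as.character(df[[1]]),
                    value = as.numeric(df[[2]]), stringsAsFactors = FALSE)
  if (anyDuplicated(out$accession_id))
    stop("duplicated accessions in phenotype table", call. = FALSE)
  if (any(!is.finite(out$value)))
    stop("phenotype values must be finite", call. = FALSE)
  out
}

#' Align a phenotype table to the accessions of a genotype matrix
#'
#' @param G a [genotype_matrix].
#' @param pheno data frame from [read_phenotype] (or equivalent).
#' @return list with the subsetted `G` and the phenotype vector `y` in
#'   matching accession order.
#' @export
align_phenotype <- function(G, pheno) {
  common <- intersect(rownames(G$codes), pheno$accession_id)
  if (length(common) == 0)
    stop("no accessions shared between genotypes and phenotype", call. = FALSE)
  G2 <- subset_genotypes(G, accessions = common)
  y <- pheno$value[match(common, pheno$accession_id)]
  names(y) <- common
  list(G = G2, y = y)
}
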