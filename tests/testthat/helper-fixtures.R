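# fixtures are built in code; nothing binary is stored in the repo

toy_genotypes <- function(codes, chrom = "1", pos = NULL) {
  codes <- as.matrix(codes)
  if (is.null(pos)) pos <- seq_len(ncol(codes)) * 100L
  genotype_matrix(codes, sprintf("acc%02d", seq_len(nrow(codes))),
                  data.frame(snp_id = paste0("s", seq_len(ncol(codes))),
                             chrom = chrom, pos = pos, ref = "A", alt = "T",
                             stringsAsFactors = FALSE))
}

write_tiny_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3\ts4",
    "1\t100\tsnpA\tA\tT\t.\t.\t.\tGT\t0/0\t0/0\t1/1\t1/1",
    "1\t200\tsnpB\tG\tC\t.\t.\t.\tGT\t0/0\t0/1\t1|1\t./.",
    "1\t300\tsnpC\tG\tC,A\t.\t.\t.\tGT\t1/1\t0/0\t0/0\t0/0"),
    path)
  path
}

# SNP-major PLINK triple written byte-by-byte; genotype quads are 2-bit codes
# 00 = hom A1 (alt), 01 = missing, 10 = het, 11 = hom A2 (ref)
write_tiny_plink <- function(prefix) {
  writeLines(sprintf("f%d i%d 0 0 0 -9", 1:4, 1:4), paste0(prefix, ".fam"))
  writeLines(c("1 s1 0 100 T A", "1 s2 0 200 C G"), paste0(prefix, ".bim"))
  pack <- function(q) as.raw(sum(q * c(1, 4, 16, 64)))
  writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)),
             pack(c(3, 0, 0, 1)),       # snp1: 0, 2, 2, NA
             pack(c(3, 3, 2, 0))),      # snp2: 0, 0, NA, 2
           paste0(prefix, ".bed"))
  prefix
}

# independent GLS Wald statistic for a known covariance V (whitening + exact
# variance, no sigma estimation) — oracle for the score test
gls_wald <- function(g, y, V) {
  X <- cbind(1, g)
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  vb <- solve(XtVX)
  drop(beta[2]^2 / vb[2, 2])
}

# ratio-of-averages Fst estimator over subpopulation allele frequencies
fst_estimate <- function(G) {
  ps <- sapply(split(seq_along(G$subpop), G$subpop),
               function(i) colMeans(G$codes[i, , drop = FALSE], na.rm = TRUE) / 2)
  pbar <- rowMeans(ps)
  ht <- 2 * pbar * (1 - pbar)
  hs <- rowMeans(2 * ps * (1 - ps))
  keep <- ht > 0.05
  mean(ht[keep] - hs[keep]) / mean(ht[keep])
}

# structure-confounded null-scan conditions reused by calibration tests:
# subpopulation shifts on the residual-SD scale, no variance loci
confounded_config <- function(seed, n = 500, m = 5000, K = 5, fst = 0.2) {
  shifts <- local({ set.seed(seed + 500); stats::rnorm(K) })
  sim_config(n = n, m = m, K = K, fst = fst, structure_effect = shifts,
             seed = seed)
}
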