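test_that("pairwise r2 matches the hand value and is invariant to allele relabeling", {
  g1 <- c(0, 0, 2, 2); g2 <- c(0, 2, 2, 2)
  expect_equal(pairwise_r2(g1, g2), 1 / 3, tolerance = 1e-12)
  # independent oracle: covariance formula by hand
  r_hand <- sum((g1 - mean(g1)) * (g2 - mean(g2))) /
    sqrt(sum((g1 - mean(g1))^2) * sum((g2 - mean(g2))^2))
  expect_equal(pairwise_r2(g1, g2), r_hand^2, tolerance = 1e-12)
  expect_equal(pairwise_r2(g1, g1), 1)
  expect_equal(pairwise_r2(g1, 2 - g1), 1)
  # missing pairs dropped
  expect_equal(pairwise_r2(c(g1, NA), c(g2, 0)), 1 / 3, tolerance = 1e-12)
  expect_error(pairwise_r2(g1, c(2, 2, 2, 2)), "constant")
})

test_that("candidate screen keeps in-window SNPs above the LD threshold, sorted", {
  set.seed(40)
  n <- 60
  lead <- 2L * rbinom(n, 1, 0.5)
  flip <- function(g, k) { i <- sample(n, k); g[i] <- 2 - g[i]; g }
  codes <- cbind(flip(lead, 2), lead, flip(lead, 3), flip(lead, 15),
                 flip(lead, 28), 2 - lead)
  G <- toy_genotypes(codes,
                     pos = c(90e3L, 100e3L, 120e3L, 150e3L, 180e3L, 260e3L))
  r2s <- apply(codes[, -2], 2, pairwise_r2, g2 = lead)
  expect_true(r2s[1] > 0.8 && r2s[2] > 0.8)       # 2 strong proxies in window
  expect_true(r2s[3] < 0.8 && r2s[4] < 0.8)
  hits <- candidate_screen(G, "s2", window = 1e5, r2_min = 0.8)
  expect_equal(hits$snp_id, c("s1", "s3"))        # lead itself excluded; s6 out of window
  expect_equal(hits$r2, unname(r2s[1:2]), tolerance = 1e-12)
  expect_true(all(diff(hits$pos) > 0))
  # r2_min = 0 returns every in-window SNP; results nest as r2_min decreases
  all_in <- candidate_screen(G, "s2", window = 1e5, r2_min = 0)
  expect_equal(nrow(all_in), 4L)
  expect_true(all(hits$snp_id %in% all_in$snp_id))
  # widening the window can only add hits
  wide <- candidate_screen(G, "s2", window = 2e5, r2_min = 0.8)
  expect_true(all(hits$snp_id %in% wide$snp_id))
  expect_error(candidate_screen(G, "nope"), "not found")
})

test_that("kinship LMM reduces to OLS with identity kinship, including interactions", {
  set.seed(41)
  n <- 60
  g <- 2 * rbinom(n, 1, 0.3); cv <- rnorm(n)
  y <- 1 + 0.5 * g + 0.3 * cv + rnorm(n)
  r <- suppressMessages(lmm_assoc(y, g, kinship_matrix(diag(n), "identity"),
                                  covariate = cv, interaction = TRUE))
  f <- summary(lm(y ~ g * cv))$coefficients
  expect_equal(r$effect, f["g", 1], tolerance = 1e-6)
  expect_equal(r$p, f["g", 4], tolerance = 1e-6)
  expect_equal(r$interaction_effect, f["g:cv", 1], tolerance = 1e-6)
  expect_equal(r$interaction_p, f["g:cv", 4], tolerance = 1e-6)
  expect_error(suppressMessages(
    lmm_assoc(y, g, kinship_matrix(diag(n), "identity"), covariate = g,
              interaction = FALSE)), "singular")
})

test_that("kinship LMM null p-values stay uniform under structure confounding", {
  cfg <- sim_config(n = 200, m = 600, K = 4, fst = 0.25,
                    structure_effect = c(-1.2, -0.4, 0.4, 1.2), seed = 10)
  G <- sim_genotypes(cfg)
  Gf <- maf_filter(G)
  y <- sim_phenotype(G, cfg)$value
  K <- ibs_kinship(Gf)
  set.seed(10)
  idx <- sample(ncol(Gf$codes), 80)
  p_lmm <- sapply(idx, function(j)
    suppressMessages(lmm_assoc(y, Gf$codes[, j], K))$p)
  p_ols <- sapply(idx, function(j)
    summary(lm(y ~ Gf$codes[, j]))$coefficients[2, 4])
  expect_gt(ks.test(p_lmm, "punif")$p.value, 0.01)
  expect_lt(ks.test(p_ols, "punif")$p.value, 0.01)   # inflated without correction
})

test_that("no-interaction simulations give null-uniform interaction p-values", {
  pint <- sapply(1:100, function(s) {
    set.seed(s)
    n <- 80
    g <- 2 * rbinom(n, 1, 0.3); cv <- rnorm(n)
    y <- 1 + 0.5 * g + 0.4 * cv + rnorm(n)   # parallel means across covariate
    suppressMessages(lmm_assoc(y, g, kinship_matrix(diag(n), "identity"),
                               covariate = cv, interaction = TRUE))$interaction_p
  })
  expect_gt(ks.test(pint, "punif")$p.value, 0.01)
})

test_that("phenotype batch attaches Benjamini-Hochberg FDR across phenotypes", {
  set.seed(43)
  n <- 80
  g <- setNames(2 * rbinom(n, 1, 0.3), sprintf("acc%02d", 1:n))
  K <- kinship_matrix(diag(n), "identity")
  dimnames(K) <- list(names(g), names(g))
  tab <- data.frame(accession_id = names(g),
                    t1 = rnorm(n) + 0.8 * g,      # real effect
                    t2 = rnorm(n), t3 = rnorm(n), t4 = rnorm(n))
  res <- suppressMessages(assoc_batch(tab, g, K))
  expect_equal(res$fdr, p.adjust(res$p, "BH"))
  expect_lt(res$p[res$phenotype == "t1"], 0.01)
  expect_equal(res$n, rep(n, 4))
})
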