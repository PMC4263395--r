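test_that("null REML recovers planted variance components and handles boundaries", {
  cfg <- sim_config(n = 300, m = 2000, K = 5, fst = 0.2, seed = 42)
  S <- ibs_kinship(maf_filter(sim_genotypes(cfg)))
  set.seed(7)
  ev <- eigen(as.matrix(S), symmetric = TRUE)
  u <- drop(ev$vectors %*% (sqrt(pmax(ev$values, 0)) * rnorm(300)))
  y <- 2 + u + rnorm(300)                      # sigma_g2 = sigma_e2 = 1
  nf <- fit_null(y, S)
  expect_lt(abs(nf$sigma_g2 - 1), 0.35)
  expect_lt(abs(nf$sigma_e2 - 1), 0.35)
  # iid response: genetic variance pinned at the boundary
  set.seed(8)
  nf0 <- fit_null(rnorm(300), S)
  expect_lt(nf0$sigma_g2 / (nf0$sigma_g2 + nf0$sigma_e2), 0.05)
  # S = I: flat likelihood resolved to sigma_g2 = 0 with a note
  expect_message(nfI <- fit_null(y, kinship_matrix(diag(300), "ibs")), "flat")
  expect_equal(nfI$sigma_g2, 0)
})

test_that("score test reproduces hand values under V = I", {
  nm <- null_model(kinship_matrix(diag(4), "ibs"), sigma_g2 = 0, sigma_e2 = 1)
  st <- score_test(c(0, 0, 2, 2), c(-1, -1, 1, 1), nm)
  expect_equal(st$chi2, 4, tolerance = 1e-12)
  expect_equal(st$p, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  st2 <- score_test(c(0, 0, 2, 2), c(-2, 0, 0, 2), nm)
  expect_equal(st2$effect, 1, tolerance = 1e-12)
  expect_equal(st2$se, 0.5, tolerance = 1e-12)
  # response orthogonal to the genotype
  st3 <- score_test(c(0, 0, 2, 2), c(-1, 1, -1, 1), nm)
  expect_equal(st3$chi2, 0, tolerance = 1e-12)
  expect_equal(st3$p, 1)
  expect_error(score_test(c(2, 2, 2, 2), c(-1, -1, 1, 1), nm), "constant")
})

test_that("score statistic equals the GLS Wald statistic when V is known", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(20:50, 1)
    A <- matrix(rnorm(n * n), n)
    S <- tcrossprod(A) / n
    sg2 <- runif(1, 0.2, 2); se2 <- runif(1, 0.2, 2)
    g <- 2 * rbinom(n, 1, 0.4)
    while (var(g) == 0) g <- 2 * rbinom(n, 1, 0.4)
    y <- rnorm(n)^2
    nm <- null_model(kinship_matrix(S, "sim"), sg2, se2)
    V <- sg2 * S + se2 * diag(n)
    expect_equal(score_test(g, y, nm)$chi2, gls_wald(g, y, V), tolerance = 1e-8)
  }
})

test_that("scan equals per-SNP score tests and duplicates get identical statistics", {
  set.seed(30)
  n <- 40
  codes <- matrix(2L * rbinom(n * 6, 1, 0.4), n, 6)
  codes[, 6] <- codes[, 5]                     # duplicated SNP, new position
  G <- toy_genotypes(codes)
  y <- rnorm(n)^2
  S <- ibs_kinship(G)
  sc <- suppressMessages(vgwas_scan(G, y, S, gc = FALSE))
  nf <- suppressMessages(fit_null(y, S))
  st1 <- score_test(codes[, 1], y, nf)
  expect_equal(sc$chi2[1], st1$chi2, tolerance = 1e-10)
  expect_equal(sc$effect[1], st1$effect, tolerance = 1e-10)
  expect_equal(sc$chi2[5], sc$chi2[6], tolerance = 1e-12)
  expect_equal(sc$p_raw[5], sc$p_raw[6], tolerance = 1e-12)
})

test_that("genomic control divides by the chi-square(1) median ratio", {
  gcr <- genomic_control(0.90988)
  expect_equal(gcr$lambda_gc, 2, tolerance = 1e-3)
  expect_equal(gcr$adjusted, 0.90988 / gcr$lambda_gc, tolerance = 1e-12)
  # null calibration on iid chi-square(1) draws
  set.seed(5)
  x <- rchisq(1e5, 1)
  expect_true(genomic_control(x)$lambda_gc > 0.97 &&
                genomic_control(x)$lambda_gc < 1.03)
  # exact elementwise division, no flooring by default
  g2 <- genomic_control(c(0.1, 0.2, 0.4))
  expect_equal(g2$adjusted, c(0.1, 0.2, 0.4) / g2$lambda_gc, tolerance = 1e-15)
  expect_equal(genomic_control(c(0.1, 0.2, 0.4), floor_at_1 = TRUE)$lambda_gc, 1)
  expect_error(genomic_control(numeric(0)), "empty")
})

test_that("Bonferroni threshold scales inversely with the number of tests", {
  expect_equal(bonferroni_threshold(214553), 0.05 / 214553, tolerance = 1e-12)
  expect_lt(abs(bonferroni_threshold(214553) * 1e7 - 2.3305), 5e-4)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(500), 2 * bonferroni_threshold(1000))
})

test_that("Gamma-GLM guard is calibrated under the null and detects scaled carriers", {
  set.seed(12)
  ps <- replicate(500, {
    y <- rgamma(150, 2, 2)
    g <- 2 * rbinom(150, 1, 0.3)
    if (var(g) == 0) NA_real_ else gamma_check(y, g)$p
  })
  expect_gt(ks.test(ps[!is.na(ps)], "punif")$p.value, 0.01)
  set.seed(13)
  g <- 2 * rbinom(500, 1, 0.3)
  y <- rgamma(500, 2, 2) * ifelse(g == 2, 3, 1)
  r <- gamma_check(y, g)
  expect_gt(r$coef, 0)
  expect_lt(r$p, 0.01)
  expect_error(gamma_check(rgamma(10, 2), rep(2, 10)), "constant")
})

test_that("GC-adjusted p is monotone decreasing in the raw statistic", {
  set.seed(14)
  chi2 <- sort(rchisq(300, 1))
  adj <- genomic_control(chi2)$adjusted
  p <- pchisq(adj, 1, lower.tail = FALSE)
  expect_true(all(diff(p) <= 0))
})

test_that("structure-confounded null scans: kinship correction removes the inflation", {
  lams <- sapply(1:6, function(seed) {
    cfg <- confounded_config(seed, n = 300, m = 2000, K = 5)
    G <- sim_genotypes(cfg)
    ph <- sim_phenotype(G, cfg)
    sc <- suppressWarnings(suppressMessages(
      adaptability_scan(G, ph, kinship = "hem", gamma = FALSE)))
    sc0 <- suppressWarnings(suppressMessages(
      adaptability_scan(G, ph,
                        kinship = kinship_matrix(diag(nrow(G$codes)), "identity"),
                        gamma = FALSE)))
    c(kin = attr(sc, "lambda_gc"), flat = attr(sc0, "lambda_gc"))
  })
  expect_lt(median(lams["kin", ]), median(lams["flat", ]))
  expect_gt(median(lams["flat", ]), 1.2)
})

test_that("full scan pipeline is calibrated on one structure-confounded null", {
  cfg <- confounded_config(1)                # n = 500, m = 5000
  G <- sim_genotypes(cfg)
  ph <- sim_phenotype(G, cfg)
  sc <- suppressWarnings(suppressMessages(adaptability_scan(G, ph, gamma = FALSE)))
  m <- sum(!is.na(sc$p_gc))
  frac <- mean(sc$p_gc < 0.05, na.rm = TRUE)
  envelope <- 1.96 * sqrt(0.05 * 0.95 / 5000)
  expect_lt(abs(frac - 0.05), envelope + 1e-12)
  expect_false(any(sc$significant[!is.na(sc$p_gc)] &
                     sc$p_gc > attr(sc, "threshold"), na.rm = TRUE))
})
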