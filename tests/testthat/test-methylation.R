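make_meth <- function(pos, level, chrom = "1", total = 10) {
  data.frame(chrom = chrom, pos = pos,
             strand = rep_len(c("+", "-"), length(pos)), context = "CHH",
             mc_count = as.integer(round(level * total)), total = total,
             stringsAsFactors = FALSE)
}

test_that("constant methylation field gives a flat metaprofile", {
  meth <- make_meth(seq(10, 990, 10), 0.3)
  tes <- data.frame(chrom = "1", start = 1, end = 1000)
  p <- te_profile(meth, tes)
  expect_true(all(abs(p$level[!is.na(p$level)] - 0.3) < 1e-12))
  expect_equal(p$mean_body, 0.3, tolerance = 1e-12)
})

test_that("two-level 200-bp TE resolves into border-aligned window averages", {
  # level 1.0 in TE bp 1-100, 0.0 in bp 101-200, sites every 10 bp
  meth <- make_meth(1000 + seq(10, 200, 10), rep(c(1, 0), each = 10))
  tes <- data.frame(chrom = "1", start = 1001, end = 1200)
  p <- te_profile(meth, tes, window = 100, step = 50)
  in5p <- which(p$n_sites_5p > 0)
  in3p <- which(p$n_sites_3p > 0)
  expect_true(all(p$level_5p[in5p] == 1))   # windows inside the first 100 bp
  expect_true(all(p$level_3p[in3p] == 0))   # windows inside the second 100 bp
  expect_equal(p$level[1], 0.5, tolerance = 1e-12)  # pooled borders intermediate
  # empty windows are NA, not 0
  expect_true(all(is.na(p$level[p$n_sites == 0])))
})

test_that("profiles truncate at 5 kb and at the TE midpoint", {
  meth <- make_meth(seq(50, 11950, 100), 0.4)
  tes <- data.frame(chrom = "1", start = 1, end = 12000)
  p <- te_profile(meth, tes, max_offset = 5000)
  expect_lte(max(p$offset + p$window / 2), 5000 + p$window / 2)
  expect_true(all(p$offset <= 5000))
  # a short TE contributes no offsets beyond its half-length
  p2 <- te_profile(make_meth(seq(10, 390, 10), 0.4),
                   data.frame(chrom = "1", start = 1, end = 400))
  expect_true(all(p2$n_sites[p2$offset - p2$window / 2 > 200] == 0))
})

test_that("pooled curve is the site-weighted average over TEs", {
  m1 <- make_meth(seq(10, 190, 10), 0.8)
  m2 <- make_meth(2000 + seq(10, 190, 10), 0.2)
  m3 <- make_meth(4000 + seq(10, 190, 20), 0.6)
  tes <- data.frame(chrom = "1", start = c(1, 2001, 4001),
                    end = c(200, 2200, 4200))
  pooled <- te_profile(rbind(m1, m2, m3), tes)
  singles <- lapply(list(m1, m2, m3), function(m) te_profile(m, tes))
  for (k in which(pooled$n_sites > 0)) {
    ns <- sapply(singles, function(p) p$n_sites[k])
    lv <- sapply(singles, function(p) p$level[k])
    expect_equal(pooled$level[k], sum(ns * lv, na.rm = TRUE) / sum(ns),
                 tolerance = 1e-12)
  }
})

test_that("knockout-like classification is a scale-free cohort-median rule", {
  means <- c(a = 0.2, b = 0.21, c = 0.19, d = 0.2, e = 0.02, f = 0.22)
  lab <- classify_knockout_like(means)
  expect_equal(names(which(lab)), "e")
  expect_equal(classify_knockout_like(3 * means), lab)   # ratio rule
  expect_false(any(classify_knockout_like(rep(0.2, 6)))) # identical cohort
  expect_error(classify_knockout_like(means[1:4]), "at least 5")
})

test_that("simulated methylome cohort recovers exactly the knockout-like accessions", {
  sim <- sim_methylomes(n_wt = 14, n_ko = 2, seed = 3)
  prof <- te_profile_cohort(sim$meth, sim$tes)
  lab <- classify_knockout_like(prof)
  expect_equal(sort(names(which(lab))), sort(names(which(sim$groups == "ko"))))
})

test_that("Fisher's exact test reproduces enumeration oracles and transpose symmetry", {
  # 2 of 16 vs 0 of 135: exact hypergeometric 120/11325
  tab <- matrix(c(2, 0, 14, 135), 2, 2)
  expect_equal(fisher_exact(tab), 120 / 11325, tolerance = 1e-9)
  expect_equal(fisher_exact(matrix(c(1, 1, 1, 1), 2)), 1)
  expect_equal(fisher_exact(matrix(c(3, 0, 0, 3), 2)), 0.1, tolerance = 1e-9)
  expect_equal(fisher_exact(t(tab)), fisher_exact(tab), tolerance = 1e-12)
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("Brown-Forsythe test matches the by-hand ANOVA on median deviations", {
  r <- brown_forsythe(list(c(1, 2, 3, 4), c(1, 3, 5, 7)))
  expect_equal(r$F, 2.4, tolerance = 1e-10)
  expect_equal(r$df1, 1); expect_equal(r$df2, 6)
  expect_equal(r$p, pf(2.4, 1, 6, lower.tail = FALSE), tolerance = 1e-10)
  # identical groups: F = 0; shifts within a group do not matter
  r0 <- brown_forsythe(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(r0$F, 0)
  r1 <- brown_forsythe(list(c(1, 2, 3, 4), c(1, 3, 5, 7) + 100))
  expect_equal(r1$F, 2.4, tolerance = 1e-10)
  # power sanity: 10x variance, n = 200/group
  set.seed(15)
  r2 <- brown_forsythe(list(rnorm(200), rnorm(200) * 10))
  expect_lt(r2$p, 1e-6)
  expect_error(brown_forsythe(list(1, c(1, 2))), ">= 2 values")
})

test_that("allc reader and BED conversion feed the profiler coherently", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1\t100\t+\tCHH\t3\t10", "1\t101\t-\tCHH\t0\t8",
               "1\t102\t+\tCG\t5\t5"), f)
  meth <- read_allc(f)
  expect_equal(nrow(meth), 3L)
  expect_equal(meth$mc_count[1], 3L)
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("1\t99\t200\tTE1", bed)     # 0-based half-open -> 100..200
  tes <- read_te_annotation(bed)
  expect_equal(tes$start, 100L)
  expect_equal(tes$end, 200L)
  p <- te_profile(meth, tes, window = 50, step = 25, max_offset = 50)
  expect_equal(p$mean_body, mean(c(0.3, 0)), tolerance = 1e-12)  # CG ignored
})
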