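#' Configuration for the structured-population simulator
#'
#' Describes a K-subpopulation set of inbred accessions under the
#' Balding-Nichols allele-frequency model, with optional planted
#' variance-controlling loci (the signal a variance-heterogeneity scan
#' should detect), mean-effect loci and per-subpopulation phenotype shifts
#' (the structure confounding the scan must correct for).
#'
#' @param n number of accessions.
#' @param m number of SNPs.
#' @param K number of subpopulations (round-robin accession assignment).
#' @param fst Wright's fixation index in `[0, 1)` governing subpopulation
#'   allele-frequency divergence.
#' @param variance_loci data frame with columns `index`, `sd_ratio` (>= 1),
#'   `maf`: at each such SNP the minor-allele homozygotes get their residual
#'   SD multiplied by `sd_ratio`; the SNP's allele frequency is fixed at
#'   `maf` in every subpopulation (a plastic allele spread across strata).
#' @param mean_loci data frame with columns `index`, `beta` (additive effect
#'   per 0/2 code unit).
#' @param structure_effect per-subpopulation phenotype shifts (length `K`;
#'   recycled). Default 0 (no confounding).
#' @param mu grand mean of the phenotype.
#' @param sigma baseline residual SD.
#' @param seed integer seed making every generator call deterministic.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n = 500, m = 5000, K = 5, fst = 0.2,
                       variance_loci = NULL, mean_loci = NULL,
                       structure_effect = 0, mu = 0, sigma = 1, seed = 1) {
  if (fst < 0 || fst >= 1) stop("'fst' must lie in [0, 1)", call. = FALSE)
  if (!is.null(variance_loci)) {
    stopifnot(all(c("index", "sd_ratio", "maf") %in% names(variance_loci)))
    if (any(variance_loci$index > m)) stop("variance locus index > m", call. = FALSE)
    if (any(variance_loci$sd_ratio < 1)) stop("sd_ratio must be >= 1", call. = FALSE)
  }
  if (!is.null(mean_loci)) {
    stopifnot(all(c("index", "beta") %in% names(mean_loci)))
    if (any(mean_loci$index > m)) stop("mean locus index > m", call. = FALSE)
  }
  structure(list(n = n, m = m, K = K, fst = fst,
                 variance_loci = variance_loci, mean_loci = mean_loci,
                 structure_effect = rep_len(structure_effect, K),
                 mu = mu, sigma = sigma, seed = seed),
            class = "sim_config")
}

#' Simulate structured inbred genotypes (Balding-Nichols model)
#'
#' Ancestral allele frequencies are Uniform(0.05, 0.95); each subpopulation
#' draws its frequency from Beta(p(1-F)/F, (1-p)(1-F)/F) around the
#' ancestral p (at `fst = 0` the ancestral frequency is used directly), and
#' each inbred accession's genotype is 2 x Bernoulli(subpopulation
#' frequency). Planted variance loci get their configured frequency in every
#' subpopulation.
#'
#' @param config a [sim_config].
#' @return a [genotype_matrix] with an extra element `subpop` (integer
#'   subpopulation per accession).
#' @export
sim_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n; m <- config$m; K <- config$K; F <- config$fst
    p_anc <- stats::runif(m, 0.05, 0.95)
    freq <- if (F > 0) {
      matrix(stats::rbeta(K * m, shape1 = rep(p_anc, each = K) * (1 - F) / F,
                          shape2 = rep(1 - p_anc, each = K) * (1 - F) / F),
             nrow = K, ncol = m)
    } else matrix(p_anc, nrow = K, ncol = m, byrow = TRUE)
    if (!is.null(config$variance_loci))
      freq[, config$variance_loci$index] <-
        matrix(rep(config$variance_loci$maf, each = K), nrow = K)
    subpop <- rep_len(seq_len(K), n)
    probs <- freq[subpop, , drop = FALSE]
    codes <- matrix(2L * stats::rbinom(n * m, 1L, as.vector(probs)), n, m)
    snps <- data.frame(snp_id = paste0("1:", seq_len(m) * 1000L, ":A:T"),
                       chrom = "1", pos = seq_len(m) * 1000L,
                       ref = "A", alt = "T", stringsAsFactors = FALSE)
    G <- genotype_matrix(codes, sprintf("acc_%04d", seq_len(n)), snps)
    G$subpop <- subpop
    G
  })
}

#' Simulate a phenotype with structure effects and variance loci
#'
#' \eqn{y_i = \mu + \mathrm{shift}(\mathrm{subpop}_i) + \sum_l \beta_l g_{il}
#' + \varepsilon_i} with
#' \eqn{\varepsilon_i \sim N(0, \sigma^2 \prod_l r_l^2)} where the product
#' runs over planted variance loci whose minor allele the accession carries:
#' carriers of a plastic allele sit in a wider phenotype distribution.
#'
#' @param G a [genotype_matrix] from [sim_genotypes].
#' @param config the same [sim_config] (its `seed` is offset internally so
#'   genotypes and phenotype noise are independent streams).
#' @return data frame `(accession_id, value)`.
#' @export
sim_phenotype <- function(G, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1000003, {
    n <- nrow(G$codes)
    y <- rep(config$mu, n) + config$structure_effect[G$subpop]
    if (!is.null(config$mean_loci))
      for (k in seq_len(nrow(config$mean_loci)))
        y <- y + config$mean_loci$beta[k] * G$codes[, config$mean_loci$index[k]]
    sd_i <- rep(config$sigma, n)
    if (!is.null(config$variance_loci))
      for (k in seq_len(nrow(config$variance_loci))) {
        carrier <- G$codes[, config$variance_loci$index[k]] == 2L
        carrier[is.na(carrier)] <- FALSE
        sd_i[carrier] <- sd_i[carrier] * config$variance_loci$sd_ratio[k]
      }
    y <- y + stats::rnorm(n, 0, sd_i)
    data.frame(accession_id = rownames(G$codes), value = y,
               stringsAsFactors = FALSE)
  })
}

#' Simulate TE-body methylomes for wild-type-like and knockout-like groups
#'
#' Lays `n_tes` TEs on one chromosome and, for each accession, draws per-site
#' CHH methylation around its group's TE-body level (Beta noise, binomial
#' read sampling with Poisson coverage truncated at >= 1); sites in the TE
#' flanks get a common low background level.
#'
#' @param n_wt,n_ko numbers of wild-type-like and knockout-like accessions.
#' @param n_tes number of TEs.
#' @param te_length TE length in bp.
#' @param site_spacing bp between consecutive CHH sites.
#' @param wt_level,ko_level mean TE-body CHH level per group.
#' @param background CHH level outside TE bodies.
#' @param noise_sd SD of the per-site Beta noise around the group level.
#' @param mean_coverage mean Poisson read depth per site.
#' @param flank flank width (bp) around each TE that also carries sites.
#' @param seed integer seed.
#' @return list with `meth` (named list of methylation tables, wild-type
#'   accessions first), `tes` (1-based inclusive intervals), `groups`
#'   (named character vector, `"wt"`/`"ko"`).
#' @export
sim_methylomes <- function(n_wt = 14, n_ko = 2, n_tes = 20, te_length = 2000,
                           site_spacing = 20, wt_level = 0.20,
                           ko_level = 0.02, background = 0.01,
                           noise_sd = 0.05, mean_coverage = 20, flank = 500,
                           seed = 1) {
  stopifnot(wt_level >= 0, wt_level <= 1, ko_level >= 0, ko_level <= 1)
  with_seed(seed, {
    gap <- 2 * flank + 3000
    starts <- (seq_len(n_tes) - 1L) * (te_length + gap) + flank + 1L
    tes <- data.frame(chrom = "1", start = starts,
                      end = starts + te_length - 1L, stringsAsFactors = FALSE)
    pos <- unlist(lapply(seq_len(n_tes), function(i)
      seq(starts[i] - flank, starts[i] + te_length - 1L + flank,
          by = site_spacing)))
    pos <- sort(unique(pos[pos >= 1]))
    in_body <- rep(FALSE, length(pos))
    for (i in seq_len(n_tes))
      in_body <- in_body | (pos >= tes$start[i] & pos <= tes$end[i])
    ids <- c(sprintf("wt_%02d", seq_len(n_wt)), sprintf("ko_%02d", seq_len(n_ko)))
    groups <- stats::setNames(rep(c("wt", "ko"), c(n_wt, n_ko)), ids)
    levels0 <- ifelse(groups == "wt", wt_level, ko_level)
    draw_site_p <- function(lv, k) {
      if (noise_sd <= 0 || lv <= 0 || lv >= 1) return(rep(lv, k))
      nu <- max(lv * (1 - lv) / noise_sd^2 - 1, 1)
      stats::rbeta(k, lv * nu, (1 - lv) * nu)
    }
    meth <- lapply(seq_along(ids), function(a) {
      lv <- ifelse(in_body, levels0[a], background)
      p_site <- numeric(length(pos))
      p_site[in_body] <- draw_site_p(levels0[a], sum(in_body))
      p_site[!in_body] <- draw_site_p(background, sum(!in_body))
      tot <- pmax(1L, stats::rpois(length(pos), mean_coverage))
      mc <- stats::rbinom(length(pos), tot, p_site)
      data.frame(chrom = "1", pos = pos,
                 strand = rep_len(c("+", "-"), length(pos)),
                 context = "CHH", mc_count = mc, total = tot,
                 stringsAsFactors = FALSE)
    })
    names(meth) <- ids
    list(meth = meth, tes = tes, groups = groups)
  })
}

#' Simulate replicated heat-stress survival counts
#'
#' Survivor counts are Binomial(`n_per_group`, rate) with
#' experiment-specific base rates (log-normal jitter around `base_rate`) and
#' the non-reference genotype's rate multiplied by `true_fold` (capped at 1).
#'
#' @param true_fold survival-rate ratio of the mutant vs the reference.
#' @param base_rate reference survival probability.
#' @param n_experiments number of replicate experiments.
#' @param n_per_group plants per genotype per experiment.
#' @param experiment_sd SD of the log-scale experiment effect.
#' @param seed integer seed.
#' @return a [stress_table] data frame with genotypes `"ref"` and `"mut"`.
#' @export
sim_stress <- function(true_fold = 1.6, base_rate = 0.40, n_experiments = 6,
                       n_per_group = 30, experiment_sd = 0.15, seed = 1) {
  if (base_rate <= 0 || base_rate * true_fold > 1)
    stop("need 0 < base_rate and base_rate * true_fold <= 1", call. = FALSE)
  with_seed(seed, {
    rate_e <- pmin(base_rate * exp(stats::rnorm(n_experiments, 0, experiment_sd)),
                   1 / max(true_fold, 1))
    rows <- lapply(seq_len(n_experiments), function(e) {
      data.frame(experiment = paste0("exp", e),
                 genotype = c("ref", "mut"),
                 survived = c(stats::rbinom(1, n_per_group, rate_e[e]),
                              stats::rbinom(1, n_per_group,
                                            min(1, rate_e[e] * true_fold))),
                 total = n_per_group, stringsAsFactors = FALSE)
    })
    stress_table(do.call(rbind, rows))
  })
}
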