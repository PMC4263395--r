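#' Read an allc-style per-site methylation table
#'
#' Tab-separated, one row per cytosine: chromosome, 1-based position, strand
#' (+/-), context (CG/CHG/CHH), methylated read count, total read count; an
#' optional trailing call column is ignored.
#'
#' @param path TSV path.
#' @param header whether the file has a header line (default `FALSE`, as in
#'   allc dumps).
#' @return data frame with columns `chrom`, `pos`, `strand`, `context`,
#'   `mc_count`, `total`.
#' @export
read_allc <- function(path, header = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop("allc table needs >= 6 columns", call. = FALSE)
  out <- data.frame(chrom = as.character(df[[1]]), pos = as.integer(df[[2]]),
                    strand = as.character(df[[3]]), context = as.character(df[[4]]),
                    mc_count = as.integer(df[[5]]), total = as.integer(df[[6]]),
                    stringsAsFactors = FALSE)
  if (any(out$mc_count > out$total))
    stop("methylated count exceeds total", call. = FALSE)
  if (any(!out$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  out
}

#' Read a transposable-element annotation (BED or GFF)
#'
#' BED input (0-based half-open) is converted to 1-based inclusive
#' coordinates; GFF/GFF3 is already 1-based inclusive.
#'
#' @param path annotation path; format guessed from the extension unless
#'   `format` is given.
#' @param format `"bed"` or `"gff"`.
#' @return data frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @export
read_te_annotation <- function(path, format = NULL) {
  if (is.null(format))
    format <- switch(tolower(tools::file_ext(path)),
                     bed = "bed", gff = "gff", gff3 = "gff", gtf = "gff",
                     stop("cannot guess annotation format from ", path,
                          call. = FALSE))
  gr <- rtracklayer::import(path, format = format)
  df <- as.data.frame(gr)
  data.frame(chrom = as.character(df$seqnames), start = df$start,
             end = df$end, stringsAsFactors = FALSE)
}

# assign CHH sites to TEs and compute distance to the nearer TE border;
# offsets past min(TE length / 2, max_offset) are dropped
te_site_offsets <- function(meth, tes, max_offset) {
  chh <- meth[meth$context == "CHH" & meth$total > 0, , drop = FALSE]
  if (nrow(chh) == 0) stop("no covered CHH sites in methylation table", call. = FALSE)
  res <- list()
  for (ch in unique(tes$chrom)) {
    te <- tes[tes$chrom == ch, , drop = FALSE]
    s <- chh[chh$chrom == ch, , drop = FALSE]
    if (nrow(s) == 0) next
    ov <- IRanges::findOverlaps(IRanges::IRanges(s$pos, s$pos),
                                IRanges::IRanges(te$start, te$end))
    if (length(ov) == 0) next
    i <- S4Vectors::queryHits(ov); j <- S4Vectors::subjectHits(ov)
    d5 <- s$pos[i] - te$start[j]
    d3 <- te$end[j] - s$pos[i]
    off <- pmin(d5, d3)                       # distance to the nearer border
    side <- ifelse(d5 <= d3, "5p", "3p")      # midpoint ties go to 5p
    len <- te$end[j] - te$start[j] + 1
    keep <- off <= pmin(len / 2, max_offset)
    res[[ch]] <- data.frame(offset = off[keep], side = side[keep],
                            level = s$mc_count[i][keep] / s$total[i][keep],
                            te = paste(ch, j[keep], sep = ":"),
                            stringsAsFactors = FALSE)
  }
  skipped <- setdiff(unique(tes$chrom), unique(chh$chrom))
  if (length(skipped))
    message("TEs on chromosome(s) without methylation data skipped: ",
            paste(skipped, collapse = ", "))
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0)
    stop("no CHH sites fall inside any TE", call. = FALSE)
  out
}

#' TE-border-aligned CHH methylation metaprofile
#'
#' Per-site CHH methylation levels (methylated / total reads) are binned by
#' distance from the nearer TE border, pooled over both DNA strands and all
#' TEs, and averaged in sliding windows (default 100 bp wide, 50 bp step),
#' truncated `max_offset` bp (default 5 kb) from the border. Offsets past
#' the TE midpoint are excluded, so each site is counted once, toward its
#' nearer border. Curves are reported separately for the genomic-left (5p)
#' and genomic-right (3p) borders — the two halves of the mirror-style
#' metaplot in which the TE edges are aligned — together with the pooled
#' (site-weighted) curve.
#'
#' @param meth methylation table (see [read_allc]).
#' @param tes TE intervals with 1-based inclusive `chrom`, `start`, `end`
#'   (see [read_te_annotation]).
#' @param window sliding-window width in bp (default 100).
#' @param step window step in bp (default 50).
#' @param max_offset truncation distance from the TE border in bp (default
#'   5000).
#' @param accession_id optional label stored on the profile.
#' @return object of class `te_profile`: list with `offset` (window centers,
#'   bp from the border), pooled `level` and `n_sites`, per-border
#'   `level_5p`/`level_3p` and `n_sites_5p`/`n_sites_3p` (windows without
#'   sites are `NA`, not 0), plus `mean_body` (mean level over all in-body
#'   CHH sites) and the window parameters.
#' @export
te_profile <- function(meth, tes, window = 100, step = 50, max_offset = 5000,
                       accession_id = NA_character_) {
  sites <- te_site_offsets(meth, tes, max_offset)
  starts <- seq(0, max(0, max_offset - window), by = step)
  winmean <- function(sub) {
    lv <- ns <- numeric(length(starts))
    for (k in seq_along(starts)) {
      inwin <- sub$offset >= starts[k] & sub$offset < starts[k] + window
      ns[k] <- sum(inwin)
      lv[k] <- if (ns[k] > 0) mean(sub$level[inwin]) else NA_real_
    }
    list(level = lv, n = ns)
  }
  all <- winmean(sites)
  s5 <- winmean(sites[sites$side == "5p", , drop = FALSE])
  s3 <- winmean(sites[sites$side == "3p", , drop = FALSE])
  structure(list(accession_id = accession_id,
                 offset = starts + window / 2,
                 level = all$level, n_sites = all$n,
                 level_5p = s5$level, n_sites_5p = s5$n,
                 level_3p = s3$level, n_sites_3p = s3$n,
                 window = window, step = step, max_offset = max_offset,
                 mean_body = mean(sites$level), n_total_sites = nrow(sites)),
            class = "te_profile")
}

#' @export
print.te_profile <- function(x, ...) {
  cat(sprintf("te_profile%s: %d windows (width %d, step %d), mean TE-body CHH = %.3f\n",
              if (is.na(x$accession_id)) "" else paste0(" [", x$accession_id, "]"),
              length(x$offset), x$window, x$step, x$mean_body))
  invisible(x)
}

#' TE metaprofiles for a cohort of accessions
#'
#' @param meth_list named list of methylation tables, one per accession.
#' @param tes TE intervals.
#' @param ... passed to [te_profile].
#' @return named list of `te_profile` objects.
#' @export
te_profile_cohort <- function(meth_list, tes, ...) {
  out <- lapply(names(meth_list), function(id)
    te_profile(meth_list[[id]], tes, accession_id = id, ...))
  names(out) <- names(meth_list)
  out
}

#' Flag accessions with a knockout-like TE-body CHH pattern
#'
#' An accession is called knockout-like when its mean TE-body CHH level falls
#' below `frac` (default 0.5) of the cohort median — a deterministic stand-in
#' for the visual pattern match of metaplot curves against null-mutant
#' profiles.
#'
#' @param profiles list of `te_profile` objects (>= 5 accessions), or a named
#'   numeric vector of mean TE-body levels.
#' @param frac fraction of the cohort median used as threshold.
#' @return named logical vector.
#' @export
classify_knockout_like <- function(profiles, frac = 0.5) {
  means <- if (is.numeric(profiles)) profiles
           else vapply(profiles, function(p) p$mean_body, 0)
  if (length(means) < 5)
    stop("need a cohort of at least 5 accessions", call. = FALSE)
  means < frac * stats::median(means)
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Exact hypergeometric test; the two-sided p-value sums the probabilities of
#' all tables at most as probable as the observed one.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return the p-value.
#' @export
fisher_exact <- function(table, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("table cells must be non-negative integers", call. = FALSE)
  if (sum(table) == 0) stop("empty table", call. = FALSE)
  stats::fisher.test(table, alternative = alternative)$p.value
}

#' Brown-Forsythe heterogeneity-of-variance test
#'
#' One-way ANOVA F-test on the absolute deviations from the group medians,
#' with (k - 1, N - k) degrees of freedom; robust to non-normality of the
#' raw values.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
brown_forsythe <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need >= 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2))
    stop("each group needs >= 2 values", call. = FALSE)
  d <- unlist(lapply(groups, function(x) abs(x - stats::median(x))))
  grp <- factor(rep(seq_along(groups), lengths(groups)))
  ft <- stats::oneway.test(d ~ grp, var.equal = TRUE)
  list(F = unname(ft$statistic), df1 = unname(ft$parameter[1]),
       df2 = unname(ft$parameter[2]), p = ft$p.value)
}
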