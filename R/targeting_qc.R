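#' Observed uniquely-mapped bases per targeted locus
#'
#' Counts primary, non-duplicate records with `mapq >= uniqueness_mapq`
#' ("uniquely mapped" for targeting assessment; default 1, i.e. any confident
#' primary). A record's bases are apportioned by overlap to each locus's
#' target interval; bases shared by overlapping targets go to the
#' earlier-listed locus (the same ownership rule as [expected_fractions()]),
#' so conservation holds exactly: sum of locus bases plus `off_target` equals
#' the total span length of the filtered records.
#'
#' @param records alignment records from one run (any filtering state).
#' @param panel a `target_panel`.
#' @param uniqueness_mapq MAPQ threshold defining "uniquely mapped", default 1.
#' @return list with `per_locus` (named numeric, bp) and `off_target` (bp).
#' @export
observed_bases <- function(records, panel, uniqueness_mapq = 1) {
  stopifnot(inherits(panel, "target_panel"))
  recs <- filter_primary(records, min_mapq = uniqueness_mapq)
  total <- sum(recs$end - recs$start)
  per_locus <- stats::setNames(numeric(nrow(panel$loci)), panel$loci$name)
  if (nrow(recs) > 0 && nrow(panel$loci) > 0) {
    own <- panel_ownership(panel)
    gr_reads <- gi_to_gr(recs[, c("chrom", "start", "end")])
    gr_own <- gi_to_gr(own)
    hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_reads, gr_own))
    if (length(hits)) {
      w <- GenomicRanges::width(suppressWarnings(IRanges::pintersect(
        gr_reads[S4Vectors::queryHits(hits)], gr_own[S4Vectors::subjectHits(hits)])))
      agg <- tapply(w, own$name[S4Vectors::subjectHits(hits)], sum)
      per_locus[names(agg)] <- as.numeric(agg)
    }
  }
  list(per_locus = per_locus, off_target = total - sum(per_locus))
}

#' Build the per-locus targeting assessment table
#'
#' One row per locus with expected fraction, observed uniquely-mapped bases,
#' observed fraction of all observed bases (so locus fractions plus the
#' off-target remainder sum to 1), and their log10 transforms. Loci with zero
#' observed bases carry `-Inf` logs; they are excluded from the regression and
#' always flagged.
#'
#' @inheritParams observed_bases
#' @return `data.frame` of class `targeting_assessment` with columns `name`,
#'   `expected_fraction`, `observed_bases`, `observed_fraction`,
#'   `log_expected`, `log_observed`, `residual` (NA until a fit is applied),
#'   `flagged`; attribute `off_target` holds the off-target remainder (bp).
#' @export
targeting_assessment <- function(records, panel, uniqueness_mapq = 1) {
  obs <- observed_bases(records, panel, uniqueness_mapq)
  ef <- expected_fractions(panel)
  total_obs <- sum(obs$per_locus) + obs$off_target
  of <- if (total_obs > 0) obs$per_locus / total_obs else obs$per_locus * 0
  out <- data.frame(
    name = panel$loci$name,
    expected_fraction = as.numeric(ef[panel$loci$name]),
    observed_bases = as.numeric(obs$per_locus[panel$loci$name]),
    observed_fraction = as.numeric(of[panel$loci$name]),
    stringsAsFactors = FALSE)
  out$log_expected <- log10(out$expected_fraction)
  out$log_observed <- ifelse(out$observed_bases > 0, log10(out$observed_fraction), -Inf)
  out$residual <- NA_real_
  out$flagged <- FALSE
  attr(out, "off_target") <- obs$off_target
  attr(out, "uniqueness_mapq") <- uniqueness_mapq
  class(out) <- c("targeting_assessment", "data.frame")
  out
}

#' Fit the targeting regression in log space
#'
#' Ordinary least squares of log10(observed fraction) on log10(expected
#' fraction) over loci with observed bases > 0. Under perfect targeting every
#' locus attracts bases in proportion to its expected share, so the fit has
#' slope 1 and zero residuals; loci falling below the line are candidates for
#' reference-assembly problems.
#'
#' @param assessment a `targeting_assessment`.
#' @return list of class `targeting_fit`: `slope`, `intercept`, `r_squared`,
#'   `residual_sd` (sqrt(RSS/(n-2))), `n_used`, and `residuals` named by locus
#'   (NA for loci excluded from the fit).
#' @export
fit_targeting_regression <- function(assessment) {
  stopifnot(inherits(assessment, "targeting_assessment"))
  use <- assessment$observed_bases > 0
  if (sum(use) < 3)
    stop("need >= 3 loci with observed bases to fit the targeting regression, have ",
         sum(use))
  m <- stats::lm(log_observed ~ log_expected, data = assessment[use, ])
  r <- stats::residuals(m)
  n <- sum(use)
  res_sd <- if (n > 2) sqrt(sum(r^2) / (n - 2)) else 0
  y <- assessment$log_observed[use]
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(r^2) / tss else 1
  residuals <- stats::setNames(rep(NA_real_, nrow(assessment)), assessment$name)
  residuals[assessment$name[use]] <- as.numeric(r)
  structure(list(
    slope = unname(stats::coef(m)[2]), intercept = unname(stats::coef(m)[1]),
    r_squared = r2, residual_sd = res_sd,
    n_used = n, residuals = residuals), class = "targeting_fit")
}

#' @export
print.targeting_fit <- function(x, ...) {
  cat(sprintf("targeting_fit: slope %.4f, intercept %.4f, r^2 %.4f, residual sd %.4f (n=%d)\n",
              x$slope, x$intercept, x$r_squared, x$residual_sd, x$n_used))
  invisible(x)
}

#' Flag under-targeted loci
#'
#' One-sided rule: a locus is flagged iff its regression residual is at or
#' below `-z_threshold * residual_sd` (a deficit; surpluses never flag), or it
#' had zero observed bases. With `residual_sd` exactly 0 only zero-observed
#' loci flag.
#'
#' @param assessment a `targeting_assessment`.
#' @param fit the [fit_targeting_regression()] result for that assessment.
#' @param z_threshold studentised-residual cutoff, default 2.
#' @return the assessment with `residual` and `flagged` columns filled.
#' @export
flag_undertargeted <- function(assessment, fit, z_threshold = 2.0) {
  stopifnot(inherits(assessment, "targeting_assessment"),
            inherits(fit, "targeting_fit"))
  r <- fit$residuals[assessment$name]
  assessment$residual <- as.numeric(r)
  deficit <- !is.na(r) & fit$residual_sd > 0 & r <= -z_threshold * fit$residual_sd
  assessment$flagged <- deficit | assessment$observed_bases == 0
  attr(assessment, "z_threshold") <- z_threshold
  attr(assessment, "fit") <- fit
  assessment
}

#' Diagnose reference-duplication artifacts at a flagged locus
#'
#' When a panel locus has a near-identical copy elsewhere in the assembly,
#' reads from the locus align primary to the copy and only supplementary to
#' the locus, starving it of uniquely-mapped bases. This inspects the
#' pre-filter record stream over the flagged locus's target: if supplementary
#' or secondary records carry at least `min_supp_fraction` of the overlapping
#' aligned bases, the primary alignments of those same reads are clustered
#' (gaps <= `merge_gap` merged, clusters with fewer than `min_reads`
#' supporting reads dropped) and clusters not contained in the panel are
#' returned as mask candidates.
#'
#' @param records the full record stream including secondary/supplementary.
#' @param locus one row of `panel$loci` (or a name present in the panel).
#' @param panel the `target_panel`.
#' @param min_supp_fraction evidence threshold on the supplementary share of
#'   aligned bases over the locus target, default 0.5.
#' @param merge_gap cluster merge gap in bp, default 10 kb.
#' @param min_reads minimum supporting reads per cluster, default 3.
#' @return list with `candidates` (interval table of off-panel mask
#'   candidates, with `n_reads` support column), `in_panel` (the supplementary
#'   footprint inside the locus target, used by the mask-in-panel policy) and
#'   `evidence` (list: `supp_fraction`, `note`).
#' @export
diagnose_duplicates <- function(records, locus, panel, min_supp_fraction = 0.5,
                                merge_gap = 10000, min_reads = 3) {
  stopifnot(inherits(panel, "target_panel"))
  if (is.character(locus)) {
    stopifnot(locus %in% panel$loci$name)
    locus <- panel$loci[panel$loci$name == locus, ]
  }
  target <- gintervals(locus$chrom, locus$target_start, locus$target_end, locus$name)
  empty <- list(candidates = cbind(empty_gintervals(), n_reads = integer(0)),
                in_panel = empty_gintervals(),
                evidence = list(supp_fraction = NA_real_, note = "no coverage"))
  mapped <- records[!records$unmapped & !records$duplicate, ]
  ov <- overlap_bases(mapped, target)
  if (!any(ov > 0)) return(empty)
  is_supp <- mapped$secondary | mapped$supplementary
  supp_bases <- sum(ov[is_supp])
  frac <- supp_bases / sum(ov)
  if (frac < min_supp_fraction) {
    return(list(candidates = cbind(empty_gintervals(), n_reads = integer(0)),
                in_panel = empty_gintervals(),
                evidence = list(supp_fraction = frac,
                                note = "supplementary fraction below threshold")))
  }
  ids <- unique(mapped$read_id[is_supp & ov > 0])
  prim <- mapped[!mapped$secondary & !mapped$supplementary &
                   mapped$read_id %in% ids, ]
  in_panel <- gi_reduce(gr_to_gi(suppressWarnings(GenomicRanges::intersect(
    gi_to_gr(mapped[is_supp & ov > 0, c("chrom", "start", "end")]),
    gi_to_gr(target)))))
  if (nrow(prim) == 0) {
    return(list(candidates = cbind(empty_gintervals(), n_reads = integer(0)),
                in_panel = in_panel,
                evidence = list(supp_fraction = frac,
                                note = "no primary alignments for supplementary reads")))
  }
  clusters <- gi_reduce(prim[, c("chrom", "start", "end")], merge_gap = merge_gap)
  gr_cl <- gi_to_gr(clusters)
  gr_pr <- gi_to_gr(prim[, c("chrom", "start", "end")])
  hits <- GenomicRanges::findOverlaps(gr_pr, gr_cl)
  tab <- table(factor(S4Vectors::subjectHits(hits), levels = seq_len(nrow(clusters))))
  n_reads <- as.integer(tab)
  # consolidate breakpoints: trim each cluster to its well-supported pileup
  # (depth >= trim_frac of the cluster maximum), so a handful of reads
  # running off the duplicate copy into unique flank do not stretch the call
  trim_frac <- 0.25
  for (ci in seq_len(nrow(clusters))) {
    sub <- prim[S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == ci], ]
    prof <- depth_profile(sub, clusters[ci, , drop = FALSE])
    good <- which(prof$depth >= trim_frac * max(prof$depth))
    clusters$end[ci] <- clusters$start[ci] + good[length(good)]
    clusters$start[ci] <- clusters$start[ci] + good[1] - 1
  }
  clusters$name <- paste0(clusters$chrom, ":", format_bp(clusters$start),
                          "-", format_bp(clusters$end))
  keep <- n_reads >= min_reads
  clusters <- clusters[keep, , drop = FALSE]
  n_reads <- n_reads[keep]
  # drop clusters fully contained in the panel: they cannot be the foreign copy
  if (nrow(clusters)) {
    inside <- gi_overlap_width(clusters, panel$merged) == gi_width(clusters)
    clusters <- clusters[!inside, , drop = FALSE]
    n_reads <- n_reads[!inside]
  }
  rownames(clusters) <- NULL
  list(candidates = cbind(clusters, n_reads = n_reads),
       in_panel = in_panel,
       evidence = list(supp_fraction = frac, note = "duplicate signature"))
}

#' Combine per-locus mask candidates into a mask set
#'
#' Under the default `"mask-duplicate-copy"` policy the off-panel copy is
#' masked; any candidate portion overlapping a panel target is truncated to
#' its off-panel part and a warning is recorded in the provenance. Under
#' `"mask-in-panel"` the supplementary footprint inside each flagged locus is
#' masked instead.
#'
#' @param diagnoses named list (flagged locus name -> [diagnose_duplicates()]
#'   result).
#' @param panel the `target_panel`.
#' @param policy `"mask-duplicate-copy"` (default) or `"mask-in-panel"`.
#' @return list of class `mask_set`: `intervals` (merged, sorted interval
#'   table) and `provenance` (`data.frame`: interval coordinates, contributing
#'   loci, supporting reads, warnings).
#' @export
emit_mask_set <- function(diagnoses, panel,
                          policy = c("mask-duplicate-copy", "mask-in-panel")) {
  policy <- match.arg(policy)
  stopifnot(inherits(panel, "target_panel"))
  pieces <- list()
  for (locus in names(diagnoses)) {
    d <- diagnoses[[locus]]
    cand <- if (policy == "mask-duplicate-copy") d$candidates else d$in_panel
    if (is.null(cand) || nrow(cand) == 0) next
    cand <- cand[, c("chrom", "start", "end")]
    warning_txt <- rep("", nrow(cand))
    if (policy == "mask-duplicate-copy") {
      ovl <- gi_overlap_width(cand, panel$merged)
      if (any(ovl > 0)) {
        trimmed <- gi_setdiff(cand[ovl > 0, , drop = FALSE], panel$merged)
        keep <- list()
        if (any(ovl == 0))
          keep[[1]] <- cbind(cand[ovl == 0, , drop = FALSE],
                             locus = locus, warning = "")
        if (nrow(trimmed) > 0)
          keep[[length(keep) + 1]] <- cbind(trimmed[, c("chrom", "start", "end")],
                                            locus = locus,
                                            warning = "truncated to off-panel portion")
        if (length(keep))
          pieces[[length(pieces) + 1]] <- do.call(rbind, keep)
        next
      }
    }
    pieces[[length(pieces) + 1]] <- cbind(cand, locus = locus, warning = warning_txt)
  }
  if (!length(pieces)) {
    ms <- list(intervals = empty_gintervals(),
               provenance = data.frame(chrom = character(), start = numeric(),
                                       end = numeric(), loci = character(),
                                       warning = character()))
    class(ms) <- "mask_set"
    return(ms)
  }
  raw <- do.call(rbind, pieces)
  merged <- gi_reduce(raw[, c("chrom", "start", "end")])
  prov <- merged[, c("chrom", "start", "end")]
  gr_m <- gi_to_gr(merged)
  gr_r <- gi_to_gr(raw[, c("chrom", "start", "end")])
  hits <- GenomicRanges::findOverlaps(gr_r, gr_m)
  loci <- character(nrow(merged)); warns <- character(nrow(merged))
  for (i in seq_len(nrow(merged))) {
    src <- S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == i]
    loci[i] <- paste(sort(unique(raw$locus[src])), collapse = ",")
    w <- unique(raw$warning[src]); w <- w[nzchar(w)]
    warns[i] <- paste(w, collapse = ";")
  }
  prov$loci <- loci
  prov$warning <- warns
  ms <- list(intervals = merged, provenance = prov)
  class(ms) <- "mask_set"
  ms
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("mask_set: %d interval(s), %s bp\n", nrow(x$intervals),
              format_bp(sum(gi_width(x$intervals)))))
  invisible(x)
}

#' Write a mask set as BED with a provenance name column
#' @param mask a `mask_set`.
#' @param path output path.
#' @export
write_mask_bed <- function(mask, path) {
  stopifnot(inherits(mask, "mask_set"))
  p <- mask$provenance
  nm <- ifelse(nzchar(p$warning), paste0(p$loci, "|", p$warning), p$loci)
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(p))
    writeLines(paste(p$chrom, format_bp(p$start), format_bp(p$end), nm, sep = "\t"), con)
  invisible(path)
}

#' Read a mask set from BED
#' @param path BED3/BED4 file; the name column (before any `|`) is taken as
#'   the provenance locus list.
#' @return a `mask_set`.
#' @export
read_mask_bed <- function(path) {
  x <- load_gene_intervals(path)
  merged <- gi_reduce(x)
  prov <- merged[, c("chrom", "start", "end")]
  prov$loci <- if (nrow(merged)) vapply(seq_len(nrow(merged)), function(i) {
    src <- gi_overlap_width(x, merged[i, , drop = FALSE]) > 0
    paste(sort(unique(sub("\\|.*$", "", x$name[src]))), collapse = ",")
  }, character(1)) else character(0)
  prov$warning <- rep("", nrow(merged))
  ms <- list(intervals = merged, provenance = prov)
  class(ms) <- "mask_set"
  ms
}
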