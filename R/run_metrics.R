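#' Define an adaptive / nonadaptive channel partition
#'
#' On a split flow cell, a subset of pore channels runs adaptive sampling
#' (real-time rejection of off-target molecules) while the rest sequence
#' non-selectively; the nonadaptive channels provide the genome-wide
#' background against which enrichment is measured.
#'
#' @param adaptive,nonadaptive integer vectors of channel ids; must be
#'   disjoint.
#' @return list of class `channel_partition`.
#' @export
channel_partition <- function(adaptive, nonadaptive) {
  adaptive <- as.integer(adaptive); nonadaptive <- as.integer(nonadaptive)
  if (length(intersect(adaptive, nonadaptive)))
    stop("adaptive and nonadaptive channel sets must be disjoint")
  structure(list(adaptive = adaptive, nonadaptive = nonadaptive),
            class = "channel_partition")
}

#' Route records by channel
#'
#' @param records alignment records.
#' @param partition a [channel_partition()].
#' @return list: `adaptive`, `nonadaptive` (record subsets) and `unassigned`
#'   (count of records with no channel or a channel in neither set; excluded
#'   from both outputs).
#' @export
partition_channels <- function(records, partition) {
  stopifnot(inherits(partition, "channel_partition"))
  ad <- !is.na(records$channel) & records$channel %in% partition$adaptive
  na <- !is.na(records$channel) & records$channel %in% partition$nonadaptive
  list(adaptive = records[ad, ], nonadaptive = records[na, ],
       unassigned = sum(!ad & !na))
}

#' Mean per-base coverage over targeted loci
#'
#' Per-locus coverage is total aligned base pairs over the locus target
#' divided by the target size; the run-level value is the unweighted mean
#' across loci (each locus counts equally regardless of size).
#'
#' @param records pre-filtered records (see [filter_primary()]).
#' @param panel a `target_panel`.
#' @return list: `mean` (fold) and `per_locus` (named numeric).
#' @export
mean_target_coverage <- function(records, panel) {
  stopifnot(inherits(panel, "target_panel"))
  if (nrow(panel$loci) == 0) stop("empty panel")
  targets <- panel_targets(panel)
  per_locus <- vapply(seq_len(nrow(targets)), function(i) {
    sum(overlap_bases(records, targets[i, , drop = FALSE])) / gi_width(targets[i, ])
  }, numeric(1))
  names(per_locus) <- targets$name
  list(mean = mean(per_locus), per_locus = per_locus)
}

#' Genome-wide background coverage outside the panel
#'
#' Tiles every chromosome with non-overlapping windows of `window` bp
#' (trailing partial windows dropped), wholly excludes windows overlapping any
#' merged panel target, and averages per-window depth (aligned bp / window
#' size) over the remainder.
#'
#' @param records nonadaptive-channel, pre-filtered records.
#' @param chrom_lengths named numeric vector.
#' @param panel a `target_panel` (its merged targets are excluded).
#' @param window tile size in bp, default 10 kb.
#' @return list: `mean` (fold) and `n_windows`.
#' @export
background_coverage <- function(records, chrom_lengths, panel, window = 10000) {
  stopifnot(inherits(panel, "target_panel"), window > 0)
  tiles <- list()
  for (chrom in names(chrom_lengths)) {
    n <- floor(chrom_lengths[[chrom]] / window)
    if (n < 1) next
    s <- (seq_len(n) - 1) * window
    tiles[[chrom]] <- gintervals(rep(chrom, n), s, s + window)
  }
  if (!length(tiles)) stop("no background windows: chromosomes shorter than window")
  tiles <- do.call(rbind, tiles)
  keep <- gi_overlap_width(tiles, panel$merged) == 0
  tiles <- tiles[keep, , drop = FALSE]
  if (nrow(tiles) == 0) stop("no eligible background windows outside the panel")
  bp <- if (nrow(records)) gi_overlap_width_reads(records, tiles) else numeric(nrow(tiles))
  list(mean = mean(bp / window), n_windows = nrow(tiles))
}

## total aligned bp per window over all records (vectorised)
gi_overlap_width_reads <- function(records, windows) {
  recs <- records[!records$unmapped, ]
  out <- numeric(nrow(windows))
  if (nrow(recs) == 0) return(out)
  gr_w <- gi_to_gr(windows)
  gr_r <- gi_to_gr(recs[, c("chrom", "start", "end")])
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_w, gr_r))
  if (!length(hits)) return(out)
  w <- GenomicRanges::width(suppressWarnings(IRanges::pintersect(
    gr_w[S4Vectors::queryHits(hits)], gr_r[S4Vectors::subjectHits(hits)])))
  agg <- tapply(w, S4Vectors::queryHits(hits), sum)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' On-target enrichment factor
#'
#' Mean target coverage divided by genome-wide background coverage. A zero
#' background makes the ratio undefined (reported as such, not an error),
#' with both inputs echoed.
#'
#' @param target mean target coverage (fold).
#' @param background background coverage (fold).
#' @return list of class `enrichment_result`: `enrichment` (ratio, `NA` if
#'   undefined), `defined`, `target`, `background`.
#' @export
enrichment <- function(target, background) {
  stopifnot(target >= 0, background >= 0)
  structure(list(
    enrichment = if (background > 0) target / background else NA_real_,
    defined = background > 0,
    target = target, background = background), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  if (x$defined)
    cat(sprintf("enrichment: %.2fx (target %.2fx / background %.2fx)\n",
                x$enrichment, x$target, x$background))
  else
    cat(sprintf("enrichment: undefined (target %.2fx, background 0x)\n", x$target))
  invisible(x)
}

#' Phase breadth over strict gene bodies
#'
#' The fraction of each gene's strict coding-span interval covered by phase
#' blocks; flanks used for capture are deliberately excluded. Overlapping
#' blocks count each base once.
#'
#' @param blocks interval table of phase blocks with a `phase_set` column
#'   (e.g. from [blocks_from_phased_vcf()]).
#' @param cores interval table of gene cores (one row per gene, named).
#' @return `data.frame` per gene: `name`, `core_bp`, `phased_bp`, `breadth`,
#'   `fully_phased` (breadth exactly 1); attribute `"summary"` holds mean,
#'   median, quartiles of breadth and the fraction of genes fully phased.
#' @export
phase_breadth <- function(blocks, cores) {
  validate_gintervals(cores, "core")
  if (any(gi_width(cores) <= 0)) stop("gene with zero-length core")
  phased <- vapply(seq_len(nrow(cores)), function(i) {
    if (nrow(blocks) == 0) return(0)
    gi_overlap_width(cores[i, , drop = FALSE], blocks)
  }, numeric(1))
  out <- data.frame(name = cores$name, core_bp = gi_width(cores),
                    phased_bp = phased, breadth = phased / gi_width(cores),
                    stringsAsFactors = FALSE)
  out$fully_phased <- out$breadth == 1
  q <- stats::quantile(out$breadth, c(0.25, 0.5, 0.75), names = FALSE)
  attr(out, "summary") <- list(mean = mean(out$breadth), q1 = q[1],
                               median = q[2], q3 = q[3],
                               fraction_fully_phased = mean(out$fully_phased))
  out
}

#' Phase blocks from a phased VCF
#'
#' One block per (chromosome, phase set): the interval from the first member
#' variant's position to the end of the last member variant's reference
#' allele, 0-based half-open. Unphased genotypes are ignored; a phased
#' genotype lacking a PS value raises a warning and is treated as unphased.
#'
#' @param path VCF file with `GT` (using `|` for phased calls) and `PS`.
#' @return interval table with a `phase_set` column.
#' @export
blocks_from_phased_vcf <- function(path) {
  v <- read_phased_variants(path)
  ph <- v[v$phased & !is.na(v$phase_set), , drop = FALSE]
  n_missing_ps <- sum(v$phased & is.na(v$phase_set))
  if (n_missing_ps > 0)
    warning(n_missing_ps, " phased genotype(s) lack a phase set; treated as unphased")
  if (nrow(ph) == 0) {
    out <- empty_gintervals()
    out$phase_set <- integer(0)
    return(out)
  }
  key <- paste(ph$chrom, ph$phase_set, sep = "\r")
  pieces <- lapply(split(ph, key), function(g) {
    data.frame(chrom = g$chrom[1], start = min(g$pos) - 1,
               end = max(g$pos - 1 + nchar(g$ref)),
               name = paste0("PS", g$phase_set[1]),
               phase_set = g$phase_set[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  gi_sort(out)
}

#' Earliest time at which a variant set is phased
#'
#' Post hoc analysis of a run: scans haplotagged records in `start_time`
#' order and returns the earliest time at which (a) every variant position is
#' covered by at least `min_support` haplotagged records and (b) all variant
#' positions fall in one connected component of phase sets, where a record
#' connects its phase set to every variant it covers and records sharing a
#' read id connect their phase sets.
#'
#' @param records alignment records carrying `start_time`, `haplotype` and
#'   `phase_set`; records without a timestamp are excluded (their count is
#'   reported in attribute `"n_no_timestamp"`).
#' @param variants `data.frame` with columns `chrom` and `pos` (0-based
#'   positions of the variants to phase); at least 2 rows.
#' @param min_support minimum haplotagged records covering each variant.
#' @return the time in seconds (numeric), or `NA` if the condition is never
#'   met.
#' @export
time_to_phase <- function(records, variants, min_support = 1) {
  stopifnot(is.data.frame(variants), nrow(variants) >= 2,
            all(c("chrom", "pos") %in% names(variants)))
  usable <- !records$unmapped & !is.na(records$haplotype) &
    !is.na(records$phase_set)
  n_no_ts <- sum(usable & is.na(records$start_time))
  recs <- records[usable & !is.na(records$start_time), ]
  recs <- recs[order(recs$start_time), ]
  nv <- nrow(variants)
  # union-find over nodes: variants 1..nv, phase sets nv+1..
  ps_ids <- integer(0)
  parent <- seq_len(nv)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  support <- integer(nv)
  ans <- NA_real_
  read_node <- new.env(parent = emptyenv())  # read_id -> first ps node seen
  for (k in seq_len(nrow(recs))) {
    ps <- recs$phase_set[k]
    node_ps <- match(ps, ps_ids)
    if (is.na(node_ps)) {
      ps_ids <- c(ps_ids, ps)
      parent <- c(parent, nv + length(ps_ids))
      node_ps <- length(ps_ids)
    }
    node_ps <- nv + node_ps
    # connect phase sets sharing this read id
    rid <- recs$read_id[k]
    prev <- get0(rid, envir = read_node)
    if (!is.null(prev)) {
      ra <- find(prev); rb <- find(node_ps)
      if (ra != rb) parent[ra] <- rb
    }
    assign(rid, node_ps, envir = read_node)
    covered <- which(variants$chrom == recs$chrom[k] &
                       variants$pos >= recs$start[k] & variants$pos < recs$end[k])
    if (length(covered)) {
      support[covered] <- support[covered] + 1L
      for (vix in covered) {
        ra <- find(vix); rb <- find(node_ps)
        if (ra != rb) parent[ra] <- rb
      }
    }
    if (all(support >= min_support)) {
      roots <- vapply(seq_len(nv), find, integer(1))
      if (length(unique(roots)) == 1) { ans <- recs$start_time[k]; break }
    }
  }
  attr(ans, "n_no_timestamp") <- n_no_ts
  ans
}
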