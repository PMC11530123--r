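#' Read per-site 5mC calls from a bedMethyl-style TSV
#'
#' Expects at least five tab-separated columns: chrom, start, end, coverage,
#' percent modified (0-100). A `fraction` column in [0,1] is derived.
#'
#' @param path TSV path (no header).
#' @return `data.frame`: `chrom`, `pos` (0-based CpG position), `coverage`,
#'   `fraction`.
#' @export
read_bedmethyl <- function(path) {
  x <- data.table::fread(path, sep = "\t", header = FALSE,
                         colClasses = list(character = 1))
  if (ncol(x) < 5) stop("bedMethyl file needs >= 5 columns, found ", ncol(x))
  out <- data.frame(chrom = x[[1]], pos = as.numeric(x[[2]]),
                    coverage = as.integer(x[[4]]),
                    fraction = as.numeric(x[[5]]) / 100,
                    stringsAsFactors = FALSE)
  if (any(out$fraction < 0 | out$fraction > 1, na.rm = TRUE))
    stop("percent-modified column outside [0, 100]")
  out
}

#' Aggregate per-read modification calls into per-site fractions
#'
#' A read's call at a site counts as modified when its modification
#' probability is at or above `prob_threshold`. Sites covered by fewer than
#' `min_coverage` calls are dropped.
#'
#' @param calls `data.frame` with columns `chrom`, `pos` (0-based site
#'   position) and `prob` (per-read modification probability).
#' @param min_coverage minimum calls per retained site, default 5.
#' @param prob_threshold probability at/above which a call is modified,
#'   default 0.5.
#' @return `data.frame`: `chrom`, `pos`, `coverage`, `fraction`, sorted by
#'   chrom then position.
#' @export
aggregate_sites <- function(calls, min_coverage = 5, prob_threshold = 0.5) {
  stopifnot(all(c("chrom", "pos", "prob") %in% names(calls)))
  dt <- data.table::as.data.table(calls)
  agg <- dt[, list(coverage = .N,
                   fraction = mean(prob >= prob_threshold)),
            by = c("chrom", "pos")]
  agg <- agg[agg$coverage >= min_coverage, ]
  out <- as.data.frame(agg[order(agg$chrom, agg$pos), ])
  rownames(out) <- NULL
  out
}

#' Detect focal hypomethylated clusters
#'
#' Scans sites in position order per chromosome for maximal runs of
#' consecutive sites whose modified fraction is at or below `frac_threshold`,
#' allowing gaps up to `max_gap` bp between neighbouring low sites; runs with
#' at least `min_sites` sites are reported. A promoter-scale focal
#' hypomethylation (the signature of an active regulatory element in 5mC
#' data) shows up as one such run against a highly methylated baseline.
#'
#' @param sites per-site table (`chrom`, `pos`, `fraction`), sorted by
#'   position within each chromosome (unsorted input is an error).
#' @param frac_threshold maximum modified fraction of a "low" site, default
#'   0.25.
#' @param min_sites minimum sites per reported cluster, default 3.
#' @param max_gap maximum bp between neighbouring low sites in one cluster,
#'   default 500.
#' @return interval table; each cluster spans its first to last site
#'   (half-open, so `end` is last site + 1) with an `n_sites` column.
#' @export
hypomethylated_clusters <- function(sites, frac_threshold = 0.25, min_sites = 3,
                                    max_gap = 500) {
  stopifnot(all(c("chrom", "pos", "fraction") %in% names(sites)))
  out <- list()
  for (chrom in unique(sites$chrom)) {
    s <- sites[sites$chrom == chrom, , drop = FALSE]
    if (is.unsorted(s$pos)) stop("sites not sorted by position on ", chrom)
    low <- which(s$fraction <= frac_threshold)
    if (!length(low)) next
    brk <- c(0, which(diff(s$pos[low]) > max_gap), length(low))
    for (b in seq_len(length(brk) - 1)) {
      run <- low[(brk[b] + 1):brk[b + 1]]
      if (length(run) < min_sites) next
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = s$pos[run[1]], end = s$pos[run[length(run)]] + 1,
        name = sprintf("hypo_%s_%s", chrom, format_bp(s$pos[run[1]])),
        n_sites = length(run), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    x <- empty_gintervals(); x$n_sites <- integer(0); return(x)
  }
  do.call(rbind, out)
}

#' Mean methylation per region
#'
#' @param sites per-site table (`chrom`, `pos`, `fraction`).
#' @param regions interval table (half-open: a site at `end` is excluded).
#' @return `data.frame` per region: `name`, `chrom`, `start`, `end`,
#'   `n_sites`, `mean_fraction` (`NA`, i.e. missing, for regions with no
#'   sites — not 0).
#' @export
region_methylation_summary <- function(sites, regions) {
  validate_gintervals(regions, "region")
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    hit <- sites$chrom == r$chrom & sites$pos >= r$start & sites$pos < r$end
    data.frame(name = r$name, chrom = r$chrom, start = r$start, end = r$end,
               n_sites = sum(hit),
               mean_fraction = if (any(hit)) mean(sites$fraction[hit]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
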