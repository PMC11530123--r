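#' Load gene intervals from a BED file
#'
#' Parses BED3/BED4 into the package interval table. Coordinates are taken as
#' 0-based half-open per the BED standard; when the name column is absent the
#' interval is labelled `"chrom:start-end"`. `track`, `browser` and `#` lines
#' are skipped.
#'
#' @param path BED file path.
#' @return interval `data.frame` (see [gintervals()]), in file order.
#' @export
load_gene_intervals <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) &
    !grepl("^(track|browser|#)", lines)
  rows <- vector("list", sum(keep))
  j <- 0L
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("BED parse error at line %d: fewer than 3 tab-separated fields", i))
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end) || start != floor(start) || end != floor(end))
      stop(sprintf("BED parse error at line %d: non-integer coordinates '%s', '%s'",
                   i, f[2], f[3]))
    if (start < 0 || start >= end)
      stop(sprintf("BED parse error at line %d: need 0 <= start < end, got %s >= %s",
                   i, f[2], f[3]))
    nm <- if (length(f) >= 4 && nzchar(f[4])) f[4] else
      paste0(f[1], ":", format_bp(start), "-", format_bp(end))
    j <- j + 1L
    rows[[j]] <- data.frame(chrom = f[1], start = start, end = end, name = nm,
                            stringsAsFactors = FALSE)
  }
  if (j == 0L) return(empty_gintervals())
  do.call(rbind, rows[seq_len(j)])
}

#' Build a flanked target panel from gene intervals
#'
#' Each gene body (the "core") is extended by `flank` bp on each side and
#' clipped to its chromosome to form the adaptive-sampling target. Overlapping
#' targets are merged for the panel's total base count so shared bases are
#' never double counted.
#'
#' @param genes interval table of gene bodies (e.g. from
#'   [load_gene_intervals()]); names must be unique.
#' @param flank bp added on each side of the core (default 50 kb, the buffer
#'   used for panel capture so reads starting outside a gene still cover it).
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param cores optional interval table giving strict coding-span intervals
#'   (matched to `genes` by name) used for phase breadth; defaults to the gene
#'   intervals themselves.
#' @return a `target_panel`: list with `loci` (per-locus core and target
#'   coordinates), `merged` (disjoint sorted union of targets), `total_bases`
#'   (sum of merged widths) and `summed_bases` (sum of per-locus target widths,
#'   counting overlaps twice).
#' @export
build_targets <- function(genes, flank = 50000, chrom_lengths, cores = NULL) {
  validate_gintervals(genes, "gene")
  stopifnot(flank >= 0, is.numeric(chrom_lengths), !is.null(names(chrom_lengths)))
  if (anyDuplicated(genes$name))
    stop("duplicate gene names: ", paste(unique(genes$name[duplicated(genes$name)]), collapse = ", "))
  unknown <- setdiff(genes$chrom, names(chrom_lengths))
  if (length(unknown))
    stop("unknown chromosome for gene(s) ",
         paste(genes$name[genes$chrom %in% unknown], collapse = ", "),
         ": ", paste(unknown, collapse = ", "))
  too_big <- genes$end > chrom_lengths[genes$chrom]
  if (any(too_big))
    stop("gene extends beyond its chromosome: ",
         paste(genes$name[too_big], collapse = ", "))
  loci <- data.frame(
    name = genes$name, chrom = genes$chrom,
    core_start = genes$start, core_end = genes$end,
    target_start = pmax(0, genes$start - flank),
    target_end = pmin(as.numeric(chrom_lengths[genes$chrom]), genes$end + flank),
    stringsAsFactors = FALSE)
  if (!is.null(cores)) {
    validate_gintervals(cores, "core")
    m <- match(loci$name, cores$name)
    hit <- !is.na(m)
    loci$core_start[hit] <- cores$start[m[hit]]
    loci$core_end[hit] <- cores$end[m[hit]]
  }
  targets <- gintervals(loci$chrom, loci$target_start, loci$target_end, loci$name)
  merged <- gi_reduce(targets)
  panel <- list(loci = loci, merged = merged,
                total_bases = sum(gi_width(merged)),
                summed_bases = sum(gi_width(targets)),
                flank = flank, chrom_lengths = chrom_lengths)
  class(panel) <- "target_panel"
  panel
}

#' @export
print.target_panel <- function(x, ...) {
  cat(sprintf("target_panel: %d loci, flank %s bp\n", nrow(x$loci), format_bp(x$flank)))
  cat(sprintf("  merged target span: %s bp (%d intervals)\n",
              format_bp(x$total_bases), nrow(x$merged)))
  if (x$summed_bases != x$total_bases)
    cat(sprintf("  summed per-locus span (overlaps counted twice): %s bp\n",
                format_bp(x$summed_bases)))
  invisible(x)
}

#' Per-locus target intervals of a panel
#' @param panel a `target_panel`.
#' @return interval table, one row per locus (flanked target coordinates).
#' @export
panel_targets <- function(panel) {
  gintervals(panel$loci$chrom, panel$loci$target_start, panel$loci$target_end,
             panel$loci$name)
}

#' Per-locus strict core (gene-body) intervals of a panel
#' @param panel a `target_panel`.
#' @return interval table, one row per locus (core coordinates).
#' @export
panel_cores <- function(panel) {
  gintervals(panel$loci$chrom, panel$loci$core_start, panel$loci$core_end,
             panel$loci$name)
}

## Disjoint per-locus ownership of target bases: a base shared by overlapping
## targets belongs to the earlier-listed locus. Used by expected_fractions and
## observed_bases so both sides of the regression apportion bases identically.
panel_ownership <- function(panel) {
  targets <- panel_targets(panel)
  owned <- vector("list", nrow(targets))
  seen <- empty_gintervals()
  for (i in seq_len(nrow(targets))) {
    piece <- gi_setdiff(targets[i, ], seen)
    if (nrow(piece)) piece$name <- targets$name[i]
    owned[[i]] <- piece
    seen <- gi_reduce(rbind(seen, targets[i, ])[, c("chrom", "start", "end", "name")])
  }
  out <- do.call(rbind, owned)
  rownames(out) <- NULL
  out
}

#' Expected fraction of targeted bases per locus
#'
#' The share of all targeted bases each locus is expected to attract, used as
#' the x-axis of the targeting regression. Bases shared by overlapping flanked
#' loci are assigned to the earlier-listed locus so fractions sum to exactly 1.
#'
#' @param panel a `target_panel`.
#' @return named numeric vector of fractions summing to 1.
#' @export
expected_fractions <- function(panel) {
  stopifnot(inherits(panel, "target_panel"))
  if (nrow(panel$loci) == 0 || panel$total_bases <= 0)
    stop("empty panel: no targeted bases")
  own <- panel_ownership(panel)
  bp <- tapply(gi_width(own), factor(own$name, levels = panel$loci$name), sum,
               default = 0)
  stats::setNames(as.numeric(bp) / panel$total_bases, panel$loci$name)
}

#' Write panel targets as BED4
#'
#' One line per locus (target coordinates, name column = gene label), sorted by
#' chromosome then start. Round-trips through [load_gene_intervals()].
#'
#' @param panel a `target_panel`.
#' @param path output path.
#' @export
write_targets_bed <- function(panel, path) {
  stopifnot(inherits(panel, "target_panel"))
  x <- gi_sort(panel_targets(panel))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(x$chrom, format_bp(x$start), format_bp(x$end), x$name,
                   sep = "\t"), con)
  invisible(path)
}

#' Write gene cores as BED4 (strict gene-body intervals)
#' @inheritParams write_targets_bed
#' @export
write_cores_bed <- function(panel, path) {
  stopifnot(inherits(panel, "target_panel"))
  x <- gi_sort(panel_cores(panel))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(x$chrom, format_bp(x$start), format_bp(x$end), x$name,
                   sep = "\t"), con)
  invisible(path)
}
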