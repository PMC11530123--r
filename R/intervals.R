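#' Construct a table of genomic intervals
#'
#' The package-wide interval container is a plain `data.frame` with columns
#' `chrom`, `start`, `end` and `name`, using 0-based half-open coordinates
#' (BED native). VCF positions are converted at the ingestion boundary only.
#'
#' @param chrom character vector of sequence names.
#' @param start,end numeric vectors, 0-based half-open (`start < end`).
#' @param name optional labels; defaults to `"chrom:start-end"`.
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `name`.
#' @export
gintervals <- function(chrom, start, end, name = NULL) {
  n <- length(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (is.null(name)) name <- paste0(chrom, ":", format_bp(start), "-", format_bp(end))
  x <- data.frame(chrom = as.character(chrom), start = start, end = end,
                  name = as.character(name), stringsAsFactors = FALSE)
  validate_gintervals(x)
  x
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

validate_gintervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (any(is.na(x$chrom) | !nzchar(x$chrom)))
    stop(what, ": chrom must be nonempty")
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad))
    stop(sprintf("%s %d: need 0 <= start < end, got [%s, %s)",
                 what, bad[1], format_bp(x$start[bad[1]]), format_bp(x$end[bad[1]])))
  invisible(x)
}

empty_gintervals <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             name = character(), stringsAsFactors = FALSE)
}

gi_width <- function(x) x$end - x$start

## Bridge to GenomicRanges (1-based closed) for interval arithmetic.
gi_to_gr <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1, x$end))
}

gr_to_gi <- function(gr, name = NULL) {
  if (length(gr) == 0) return(empty_gintervals())
  x <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr) - 1,
                  end = GenomicRanges::end(gr),
                  stringsAsFactors = FALSE)
  x$name <- if (is.null(name)) paste0(x$chrom, ":", format_bp(x$start), "-", format_bp(x$end)) else name
  x
}

## Union of intervals, sorted by chrom then start; gaps <= merge_gap are bridged.
gi_reduce <- function(x, merge_gap = 0) {
  if (nrow(x) == 0) return(empty_gintervals())
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gi_to_gr(x)),
                              min.gapwidth = merge_gap + 1)
  gr_to_gi(gr)
}

## Per-row intersection width of a with the union of b (vectorised over a).
gi_overlap_width <- function(a, b) {
  if (nrow(a) == 0) return(numeric(0))
  if (nrow(b) == 0) return(numeric(nrow(a)))
  ga <- gi_to_gr(a)
  gb <- GenomicRanges::reduce(gi_to_gr(b))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(ga, gb))
  w <- GenomicRanges::width(suppressWarnings(IRanges::pintersect(
    ga[S4Vectors::queryHits(hits)], gb[S4Vectors::subjectHits(hits)])))
  out <- numeric(nrow(a))
  agg <- tapply(w, S4Vectors::queryHits(hits), sum)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

## a \ union(b), returned as an interval table.
gi_setdiff <- function(a, b) {
  if (nrow(a) == 0) return(empty_gintervals())
  if (nrow(b) == 0) return(gi_reduce(a))
  gr <- suppressWarnings(
    GenomicRanges::setdiff(GenomicRanges::reduce(gi_to_gr(a)),
                           GenomicRanges::reduce(gi_to_gr(b))))
  gr_to_gi(GenomicRanges::sort(gr))
}

## Sort by chrom (lexicographic) then start.
gi_sort <- function(x) x[order(x$chrom, x$start, x$end), , drop = FALSE]

## Read a 2-column TSV of (sequence name, length), e.g. cut -f1,2 ref.fa.fai.
#' Read chromosome lengths from a FASTA-index style TSV
#'
#' @param path two-or-more-column tab-separated file; column 1 is the sequence
#'   name, column 2 its length in bp (the layout of a `.fai` index).
#' @return named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  x <- data.table::fread(path, sep = "\t", header = FALSE, select = 1:2,
                         colClasses = list(character = 1))
  stats::setNames(as.numeric(x[[2]]), x[[1]])
}
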