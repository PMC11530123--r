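#' Construct a table of alignment records
#'
#' The canonical alignment container is a `data.table` with one row per
#' aligned segment. `start`/`end` give the reference bases consumed by the
#' alignment (0-based half-open): reference-advancing CIGAR length, so
#' soft-clips never count. Optional run annotations are `channel` (pore id),
#' `start_time` (seconds since run start), `haplotype` (HP tag, 1/2) and
#' `phase_set` (PS tag); all may be `NA`.
#'
#' @param read_id,chrom,start,end,mapq core fields; `start`/`end` are `NA` for
#'   unmapped records.
#' @param secondary,supplementary,duplicate,unmapped SAM flag booleans.
#' @param channel,start_time,haplotype,phase_set optional annotations.
#' @return a `data.table` of class `alignment_records`.
#' @export
alignment_records <- function(read_id, chrom, start, end, mapq,
                              secondary = FALSE, supplementary = FALSE,
                              duplicate = FALSE, unmapped = FALSE,
                              channel = NA_integer_, start_time = NA_real_,
                              haplotype = NA_integer_, phase_set = NA_integer_) {
  x <- data.table::data.table(
    read_id = as.character(read_id), chrom = as.character(chrom),
    start = as.numeric(start), end = as.numeric(end), mapq = as.integer(mapq),
    secondary = as.logical(secondary), supplementary = as.logical(supplementary),
    duplicate = as.logical(duplicate), unmapped = as.logical(unmapped),
    channel = as.integer(channel), start_time = as.numeric(start_time),
    haplotype = as.integer(haplotype), phase_set = as.integer(phase_set))
  validate_alignment_records(x)
  x
}

validate_alignment_records <- function(x) {
  mapped <- !x$unmapped
  if (any(mapped & (is.na(x$start) | is.na(x$end) | x$start < 0 | x$start >= x$end)))
    stop("mapped records must carry a valid span (0 <= start < end)")
  if (any(!is.na(x$mapq) & x$mapq < 0)) stop("mapq must be >= 0")
  data.table::setattr(x, "class", unique(c("alignment_records", class(x))))
  invisible(x)
}

#' Read alignments from SAM or BAM
#'
#' SAM input is converted through [Rsamtools::asBam()] under a temporary
#' prefix. Channel is taken from the `ch` tag, falling back to a `_ch<N>`
#' read-id suffix; start time from the `st` tag (seconds, run-relative);
#' haplotype and phase set from `HP`/`PS`. All tags are tolerated as absent.
#'
#' @param path SAM or BAM file.
#' @return an `alignment_records` table (see [alignment_records()]).
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    tag = c("ch", "st", "HP", "PS"))
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- res$flag
  mapped <- !bitwAnd(flag, 4L)
  refw <- rep(NA_integer_, length(flag))
  refw[mapped] <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar[mapped])
  ch <- res$tag$ch
  if (is.null(ch)) ch <- rep(NA_integer_, length(flag))
  noch <- is.na(ch) & grepl("_ch[0-9]+$", res$qname)
  ch[noch] <- as.integer(sub(".*_ch([0-9]+)$", "\\1", res$qname[noch]))
  tagor <- function(tag, cast, na) {
    v <- res$tag[[tag]]
    if (is.null(v)) rep(na, length(flag)) else cast(v)
  }
  alignment_records(
    read_id = res$qname, chrom = as.character(res$rname),
    start = ifelse(mapped, res$pos - 1, NA_real_),
    end = ifelse(mapped, res$pos - 1 + refw, NA_real_),
    mapq = res$mapq,
    secondary = bitwAnd(flag, 256L) > 0, supplementary = bitwAnd(flag, 2048L) > 0,
    duplicate = bitwAnd(flag, 1024L) > 0, unmapped = !mapped,
    channel = as.integer(ch),
    start_time = tagor("st", as.numeric, NA_real_),
    haplotype = tagor("HP", as.integer, NA_integer_),
    phase_set = tagor("PS", as.integer, NA_integer_))
}

#' Keep primary, confidently mapped records
#'
#' The read filter applied before variant-calling-grade metrics: mapped,
#' non-secondary, non-supplementary, non-duplicate records with
#' `mapq >= min_mapq`. Order is preserved and the operation is idempotent.
#'
#' @param records an `alignment_records` table.
#' @param min_mapq minimum mapping quality, default 50.
#' @return the filtered records.
#' @export
filter_primary <- function(records, min_mapq = 50) {
  keep <- !records$unmapped & !records$secondary & !records$supplementary &
    !records$duplicate & !is.na(records$mapq) & records$mapq >= min_mapq
  records[keep, ]
}

#' Reference bases a record shares with an interval
#'
#' @param records an `alignment_records` table (unmapped rows contribute 0).
#' @param interval a single-row interval table.
#' @return numeric vector, one overlap width (bp) per record; cross-chromosome
#'   records give 0.
#' @export
overlap_bases <- function(records, interval) {
  stopifnot(nrow(interval) == 1)
  out <- numeric(nrow(records))
  idx <- which(!records$unmapped & records$chrom == interval$chrom)
  if (length(idx))
    out[idx] <- pmax(0, pmin(records$end[idx], interval$end) -
                          pmax(records$start[idx], interval$start))
  out
}

#' Per-base depth over an interval
#'
#' @param records alignment records, pre-filtered as the caller wishes.
#' @param interval a single-row interval table.
#' @return list with `interval` and `depth`, an integer vector with one value
#'   per base of the interval; `mean(depth)` equals
#'   `sum(overlap_bases(records, interval)) / width`.
#' @export
depth_profile <- function(records, interval) {
  stopifnot(nrow(interval) == 1)
  w <- interval$end - interval$start
  idx <- which(!records$unmapped & records$chrom == interval$chrom &
                 records$end > interval$start & records$start < interval$end)
  if (!length(idx)) return(list(interval = interval, depth = integer(w)))
  ir <- IRanges::IRanges(pmax(records$start[idx], interval$start) + 1,
                         pmin(records$end[idx], interval$end))
  cov <- IRanges::coverage(ir, width = interval$end)
  list(interval = interval,
       depth = as.integer(S4Vectors::window(cov, interval$start + 1, interval$end)))
}
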