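#' Hard-mask a reference FASTA
#'
#' Replaces every base inside the mask intervals with uppercase 'N' (hard
#' masking: aligners cannot place reads there), leaving sequence names, order
#' and lengths untouched. Output is wrapped at 60 columns with headers copied
#' verbatim, so masking is byte-deterministic and idempotent.
#'
#' @param reference FASTA path or a [Biostrings::DNAStringSet]. Sequences are
#'   matched to mask chromosomes by the first whitespace-delimited token of
#'   the header.
#' @param mask a `mask_set`, or any interval table.
#' @param out output FASTA path, or `NULL` to return the masked sequences.
#' @return (invisibly) a report `data.frame` with per-sequence masked base
#'   counts; the masked `DNAStringSet` is attached as attribute `"sequences"`.
#' @export
mask_fasta <- function(reference, mask, out = NULL) {
  seqs <- if (inherits(reference, "DNAStringSet")) reference
          else Biostrings::readDNAStringSet(reference)
  ivs <- if (inherits(mask, "mask_set")) mask$intervals else mask
  if (nrow(ivs)) validate_gintervals(ivs, "mask interval")
  keys <- sub("\\s.*$", "", names(seqs))
  unknown <- setdiff(unique(ivs$chrom), keys)
  if (length(unknown))
    stop("mask names unknown sequence(s): ", paste(unknown, collapse = ", "))
  lens <- stats::setNames(Biostrings::width(seqs), keys)
  beyond <- ivs$end > lens[ivs$chrom]
  if (any(beyond))
    stop(sprintf("mask interval beyond sequence end: %s:[%s,%s) (length %s)",
                 ivs$chrom[which(beyond)[1]], format_bp(ivs$start[which(beyond)[1]]),
                 format_bp(ivs$end[which(beyond)[1]]),
                 format_bp(lens[ivs$chrom[which(beyond)[1]]])))
  masked_bp <- stats::setNames(numeric(length(seqs)), keys)
  if (nrow(ivs)) {
    merged <- gi_reduce(ivs)
    for (chrom in unique(merged$chrom)) {
      i <- match(chrom, keys)
      sub <- merged[merged$chrom == chrom, , drop = FALSE]
      at <- IRanges::IRanges(sub$start + 1, sub$end)
      seqs[[i]] <- Biostrings::replaceAt(seqs[[i]], at,
                                         as.character(strrep("N", gi_width(sub))))
      masked_bp[i] <- sum(gi_width(sub))
    }
  }
  if (!is.null(out))
    Biostrings::writeXStringSet(seqs, out, width = 60)
  report <- data.frame(sequence = keys, length = as.numeric(lens),
                       masked_bases = as.numeric(masked_bp),
                       stringsAsFactors = FALSE)
  attr(report, "sequences") <- seqs
  invisible(report)
}

#' Verify a hard-masked reference against the original
#'
#' @param original,masked FASTA paths or `DNAStringSet`s.
#' @param mask a `mask_set` or interval table.
#' @return list: `ok` (TRUE iff lengths match, all masked positions are 'N'
#'   and all unmasked positions are unchanged) and `discrepancy` (message
#'   describing the first problem, or `NA`). A pre-existing 'N' inside the
#'   mask is allowed.
#' @export
verify_mask <- function(original, masked, mask) {
  a <- if (inherits(original, "DNAStringSet")) original
       else Biostrings::readDNAStringSet(original)
  b <- if (inherits(masked, "DNAStringSet")) masked
       else Biostrings::readDNAStringSet(masked)
  ivs <- if (inherits(mask, "mask_set")) mask$intervals else mask
  keys_a <- sub("\\s.*$", "", names(a))
  keys_b <- sub("\\s.*$", "", names(b))
  if (!identical(keys_a, keys_b))
    return(list(ok = FALSE, discrepancy = "sequence names differ"))
  if (!identical(Biostrings::width(a), Biostrings::width(b)))
    return(list(ok = FALSE, discrepancy = "sequence lengths differ"))
  for (i in seq_along(a)) {
    chrom <- keys_a[i]
    sa <- as.character(a[[i]])
    sb <- as.character(b[[i]])
    in_mask <- rep(FALSE, nchar(sa))
    sub <- ivs[ivs$chrom == chrom, , drop = FALSE]
    for (j in seq_len(nrow(sub)))
      in_mask[(sub$start[j] + 1):sub$end[j]] <- TRUE
    ca <- strsplit(sa, "")[[1]]
    cb <- strsplit(sb, "")[[1]]
    bad_mask <- in_mask & cb != "N"
    if (any(bad_mask))
      return(list(ok = FALSE, discrepancy = sprintf(
        "%s position %d inside mask is '%s', not 'N'",
        chrom, which(bad_mask)[1], cb[which(bad_mask)[1]])))
    bad_out <- !in_mask & ca != cb
    if (any(bad_out))
      return(list(ok = FALSE, discrepancy = sprintf(
        "%s position %d outside mask changed '%s' -> '%s'",
        chrom, which(bad_out)[1], ca[which(bad_out)[1]], cb[which(bad_out)[1]])))
  }
  list(ok = TRUE, discrepancy = NA_character_)
}
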