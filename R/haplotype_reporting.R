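#' Read phased variants from a VCF
#'
#' Loads the first sample's genotypes into a flat table. Multi-allelic sites
#' are split into bi-allelic rows on ingest (the genotype is recoded per alt:
#' matching allele index becomes 1, others 0). Positions stay 1-based here;
#' conversion to the internal 0-based convention happens where intervals are
#' derived.
#'
#' @param path VCF 4.2+ file with `GT` (phased calls use `|`) and optionally
#'   `PS`; symbolic SVs carry `SVTYPE` and `END` in INFO.
#' @return `data.frame`: `id`, `chrom`, `pos` (1-based), `ref`, `alt`, `gt1`,
#'   `gt2` (allele indices on haplotype 1/2), `phased`, `phase_set`,
#'   `svtype`, `sv_end`.
#' @export
read_phased_variants <- function(path) {
  v <- suppressWarnings(VariantAnnotation::readVcf(path))
  n <- length(v)
  rr <- SummarizedExperiment::rowRanges(v)
  gt <- as.character(VariantAnnotation::geno(v)$GT[, 1])
  ps <- if ("PS" %in% names(VariantAnnotation::geno(v)))
    VariantAnnotation::geno(v)$PS[, 1] else rep(NA_integer_, n)
  info <- VariantAnnotation::info(v)
  svtype <- if ("SVTYPE" %in% names(info)) as.character(info$SVTYPE) else rep(NA_character_, n)
  sv_end <- if ("END" %in% names(info)) suppressWarnings(as.numeric(info$END)) else rep(NA_real_, n)
  alts <- VariantAnnotation::alt(v)
  ids <- names(rr)
  rows <- list()
  for (i in seq_len(n)) {
    phased <- grepl("|", gt[i], fixed = TRUE)
    idx <- suppressWarnings(as.integer(strsplit(gt[i], "[/|]")[[1]]))
    if (length(idx) != 2 || anyNA(idx)) next
    a <- as.character(alts[[i]])
    for (j in seq_along(a)) {
      rows[[length(rows) + 1]] <- data.frame(
        id = if (length(a) > 1) paste0(ids[i], "_alt", j) else ids[i],
        chrom = as.character(GenomicRanges::seqnames(rr)[i]),
        pos = GenomicRanges::start(rr)[i],
        ref = as.character(VariantAnnotation::ref(v)[[i]]),
        alt = a[j],
        gt1 = as.integer(idx[1] == j), gt2 = as.integer(idx[2] == j),
        phased = phased,
        phase_set = suppressWarnings(as.integer(ps[i])),
        svtype = svtype[i], sv_end = sv_end[i],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(id = character(), chrom = character(), pos = numeric(),
                      ref = character(), alt = character(), gt1 = integer(),
                      gt2 = integer(), phased = logical(), phase_set = integer(),
                      svtype = character(), sv_end = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

is_het <- function(v) v$gt1 != v$gt2

#' Classify a heterozygous variant pair as cis, trans or unphased
#'
#' Two variants are in cis when their alternate alleles sit on the same
#' haplotype of one phase set, trans when on opposite haplotypes. Variants in
#' different (or missing) phase sets carry no relative phase information.
#'
#' @param v1,v2 single-row variant records (rows of
#'   [read_phased_variants()] output). Both must be heterozygous.
#' @return `"cis"`, `"trans"` or `"unphased"`.
#' @export
classify_pair <- function(v1, v2) {
  if (!is_het(v1) || !is_het(v2))
    stop("classify_pair requires heterozygous variants; phase of a homozygous pair is undefined")
  if (!isTRUE(v1$phased) || !isTRUE(v2$phased)) return("unphased")
  if (is.na(v1$phase_set) || is.na(v2$phase_set) ||
      v1$phase_set != v2$phase_set) return("unphased")
  h1 <- if (v1$gt1 == 1) 1L else 2L  # haplotype carrying v1's alt
  h2 <- if (v2$gt1 == 1) 1L else 2L
  if (h1 == h2) "cis" else "trans"
}

#' Genomic distance between two variants
#'
#' @param v1,v2 single-row variant records on the same chromosome.
#' @return absolute position difference in bp.
#' @export
variant_distance <- function(v1, v2) {
  if (v1$chrom != v2$chrom)
    stop("variant_distance undefined across chromosomes (", v1$chrom, " vs ", v2$chrom, ")")
  abs(v2$pos - v1$pos)
}

#' Breakpoints and length of a structural variant record
#'
#' @param v a single-row variant record with `svtype` in DEL/DUP/INV and an
#'   `sv_end` coordinate.
#' @return list: `start` (the record position), `end`, `length`
#'   (`end - start` under the half-open convention).
#' @export
sv_span <- function(v) {
  if (is.na(v$svtype) || !v$svtype %in% c("DEL", "DUP", "INV"))
    stop("sv_span requires an SV record (SVTYPE DEL/DUP/INV)")
  if (is.na(v$sv_end)) stop("SV record lacks an END coordinate")
  if (v$sv_end <= v$pos) stop("empty SV span: END <= POS")
  list(start = v$pos, end = v$sv_end, length = v$sv_end - v$pos)
}

#' Per-case allelic-architecture report
#'
#' For each requested variant pair: cis/trans/unphased classification,
#' genomic distance (NA across chromosomes) and the phase sets involved; plus
#' a per-variant haplotype assignment table. Ordering is deterministic
#' (pairs in input order).
#'
#' @param variants output of [read_phased_variants()].
#' @param pairs `data.frame` with columns `id1`, `id2` naming variant ids.
#' @return list of class `architecture_report`: `pairs` table and `variants`
#'   table.
#' @export
architecture_report <- function(variants, pairs) {
  stopifnot(all(c("id1", "id2") %in% names(pairs)))
  unknown <- setdiff(c(pairs$id1, pairs$id2), variants$id)
  if (length(unknown))
    stop("unknown variant id(s) in pairs: ", paste(unknown, collapse = ", "))
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    v1 <- variants[variants$id == pairs$id1[k], ][1, ]
    v2 <- variants[variants$id == pairs$id2[k], ][1, ]
    data.frame(
      id1 = v1$id, id2 = v2$id,
      classification = classify_pair(v1, v2),
      distance_bp = if (v1$chrom == v2$chrom) abs(v2$pos - v1$pos) else NA_real_,
      phase_set1 = v1$phase_set, phase_set2 = v2$phase_set,
      stringsAsFactors = FALSE)
  })
  ptab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id1 = character(), id2 = character(), classification = character(),
               distance_bp = numeric(), phase_set1 = integer(),
               phase_set2 = integer(), stringsAsFactors = FALSE)
  vtab <- variants[, c("id", "chrom", "pos", "ref", "alt", "phased", "phase_set")]
  vtab$alt_haplotype <- ifelse(variants$phased & is_het(variants),
                               ifelse(variants$gt1 == 1, 1L, 2L), NA_integer_)
  structure(list(pairs = ptab, variants = vtab), class = "architecture_report")
}

#' @export
print.architecture_report <- function(x, ...) {
  cat("allelic architecture report\n")
  if (nrow(x$pairs) == 0) {
    cat("  (no pairs requested)\n")
  } else {
    for (k in seq_len(nrow(x$pairs))) {
      p <- x$pairs[k, ]
      extra <- if (p$classification == "unphased" &&
                   !is.na(p$phase_set1) && !is.na(p$phase_set2))
        sprintf(" [PS %s vs %s]", p$phase_set1, p$phase_set2) else ""
      cat(sprintf("  %s / %s: %s%s%s\n", p$id1, p$id2, p$classification,
                  if (!is.na(p$distance_bp))
                    sprintf(", %s bp apart", format_bp(p$distance_bp)) else "",
                  extra))
    }
  }
  invisible(x)
}
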