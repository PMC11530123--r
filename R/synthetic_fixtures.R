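#' Build a toy reference with planted segmental duplications
#'
#' Generates random-base chromosomes, then copies each requested source
#' segment to its copy location, mutating copied bases independently at rate
#' `1 - identity`. The returned truth records both intervals of every
#' duplication pair; downstream, reads originating in either copy of an
#' active duplication acquire the supplementary-alignment signature that the
#' targeting QC diagnoses.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param duplications list of lists with fields `src_chrom`, `src_start`,
#'   `src_end`, `copy_chrom`, `copy_start`, `identity` (fraction in (0,1]).
#' @param seed integer seed; the output is fully determined by
#'   (`chrom_lengths`, `duplications`, `seed`).
#' @return list of class `sim_reference`: `seqs`
#'   ([Biostrings::DNAStringSet]), `chrom_lengths`, `truth` (list with a
#'   `duplications` table and the seed).
#' @export
make_reference <- function(chrom_lengths, duplications = list(), seed = 1) {
  stopifnot(is.numeric(chrom_lengths), !is.null(names(chrom_lengths)))
  set.seed(seed)
  seqs <- Biostrings::DNAStringSet(vapply(chrom_lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1)))
  names(seqs) <- names(chrom_lengths)
  dup_tab <- data.frame(src_chrom = character(), src_start = numeric(),
                        src_end = numeric(), copy_chrom = character(),
                        copy_start = numeric(), copy_end = numeric(),
                        identity = numeric(), stringsAsFactors = FALSE)
  if (length(duplications)) {
    dup_tab <- do.call(rbind, lapply(duplications, function(d) {
      data.frame(src_chrom = d$src_chrom, src_start = d$src_start,
                 src_end = d$src_end, copy_chrom = d$copy_chrom,
                 copy_start = d$copy_start,
                 copy_end = d$copy_start + (d$src_end - d$src_start),
                 identity = if (is.null(d$identity)) 1.0 else d$identity,
                 stringsAsFactors = FALSE)
    }))
    planted <- rbind(
      gintervals(dup_tab$src_chrom, dup_tab$src_start, dup_tab$src_end),
      gintervals(dup_tab$copy_chrom, dup_tab$copy_start, dup_tab$copy_end))
    if (sum(gi_width(gi_reduce(planted))) < sum(gi_width(planted)))
      stop("planted duplication intervals overlap")
    if (any(dup_tab$copy_end > chrom_lengths[dup_tab$copy_chrom]) ||
        any(dup_tab$src_end > chrom_lengths[dup_tab$src_chrom]))
      stop("planted duplication outside reference bounds")
    for (i in seq_len(nrow(dup_tab))) {
      d <- dup_tab[i, ]
      seg <- strsplit(as.character(Biostrings::subseq(
        seqs[[d$src_chrom]], d$src_start + 1, d$src_end)), "")[[1]]
      mut <- stats::runif(length(seg)) < (1 - d$identity)
      if (any(mut))
        seg[mut] <- vapply(seg[mut], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }, character(1))
      seqs[[d$copy_chrom]] <- Biostrings::replaceAt(
        seqs[[d$copy_chrom]], IRanges::IRanges(d$copy_start + 1, d$copy_end),
        paste(seg, collapse = ""))
    }
  }
  structure(list(seqs = seqs, chrom_lengths = chrom_lengths,
                 truth = list(duplications = dup_tab, seed = seed)),
            class = "sim_reference")
}

#' Default run-simulation parameters
#'
#' Depths follow the adaptive/nonadaptive contrast a split MinION flow cell
#' produces (target ~25x from adaptive channels over ~1.5x non-selective
#' background); read lengths are log-normal with mean 7 kb, echoing typical
#' ligation-library nanopore runs; rejected molecules are truncated at the
#' 500 bp decision length.
#'
#' @param target_depth,background_depth planted mean coverages (fold).
#' @param read_length_mean,read_length_sd log-normal read length moments (bp).
#' @param min_read_length floor on sampled lengths (bp).
#' @param decision_length bases sequenced before an adaptive reject (bp).
#' @param adaptive_channels,nonadaptive_channels pore-channel id sets.
#' @param run_hours run duration; read start times are uniform over it.
#' @return parameter list for [simulate_run()].
#' @export
run_params <- function(target_depth = 25, background_depth = 1.5,
                       read_length_mean = 7000, read_length_sd = 2500,
                       min_read_length = 200, decision_length = 500,
                       adaptive_channels = 1:256,
                       nonadaptive_channels = 257:512, run_hours = 24) {
  stopifnot(target_depth >= 0, background_depth >= 0,
            decision_length < read_length_mean)
  as.list(environment())
}

rlen <- function(n, p) {
  cv <- p$read_length_sd / p$read_length_mean
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(p$read_length_mean) - sdlog^2 / 2
  pmax(p$min_read_length, round(stats::rlnorm(n, meanlog, sdlog)))
}

## draw reads overlapping [s,e) on `chrom` until their overlap bases reach
## `budget`; with start_inside, starts are confined to [s,e) (the adaptive
## accept rule judges a molecule by where it begins)
draw_budget_reads <- function(chrom, s, e, chrom_len, budget, p,
                              start_inside = FALSE) {
  starts <- numeric(0); ends <- numeric(0)
  got <- 0
  while (got < budget) {
    n <- max(10, ceiling((budget - got) / p$read_length_mean * 1.3))
    len <- rlen(n, p)
    x0 <- floor(stats::runif(n, if (start_inside) s else s - len + 1, e))
    a <- pmax(0, x0); b <- pmin(chrom_len, x0 + len)
    ov <- pmin(b, e) - pmax(a, s)
    keep <- ov > 0 & b > a
    a <- a[keep]; b <- b[keep]; ov <- ov[keep]
    if (!length(a)) next
    cum <- got + cumsum(ov)
    take <- which(cum - ov < budget)  # stop once budget reached
    starts <- c(starts, a[take]); ends <- c(ends, b[take])
    got <- if (length(take)) cum[take[length(take)]] else got
  }
  data.frame(chrom = chrom, start = starts, end = ends)
}

#' Simulate an adaptive-sampling sequencing run
#'
#' Reads are sampled along the genome with start times uniform over the run.
#' On adaptive channels, on-target molecules are drawn until each merged
#' target interval reaches `target_depth` in aligned bases; molecules
#' starting outside the merged targets are rejected, i.e. truncated to
#' `decision_length` (the charge-reversal model, with zero rejection
#' latency). Nonadaptive channels sequence the whole genome at
#' `background_depth`. Reads originating in either interval of an active
#' planted duplication are emitted as a primary record at the duplicate copy
#' plus a supplementary record at the in-panel source — the mapping signature
#' a real aligner produces over assembly duplication artifacts. A duplication
#' is inactive when at least half of its copy interval is hard-masked ('N')
#' in the reference, which is how masking repairs targeting. Fixed seed and
#' parameters give identical output.
#'
#' @param ref a `sim_reference` from [make_reference()].
#' @param panel a `target_panel` on the same chromosomes.
#' @param params a [run_params()] list.
#' @param seed integer seed.
#' @return list: `records` (an `alignment_records` table; adaptive on-target
#'   primaries carry HP/PS haplotags, every record carries channel and start
#'   time) and `truth` (params, seed, active duplications).
#' @export
simulate_run <- function(ref, panel, params = run_params(), seed = 1) {
  stopifnot(inherits(ref, "sim_reference"), inherits(panel, "target_panel"))
  if (nrow(panel$merged) == 0 && params$target_depth > 0)
    stop("empty panel with target_depth > 0")
  set.seed(seed)
  p <- params
  lens <- ref$chrom_lengths
  genome <- sum(lens)
  total_target <- sum(gi_width(panel$merged))

  pieces <- list()
  # adaptive channels: per merged target interval, fill the base budget
  n_on <- 0
  if (p$target_depth > 0) for (i in seq_len(nrow(panel$merged))) {
    m <- panel$merged[i, ]
    d <- draw_budget_reads(m$chrom, m$start, m$end, lens[[m$chrom]],
                           p$target_depth * (m$end - m$start), p,
                           start_inside = TRUE)
    if (nrow(d)) {
      d$channel_set <- "adaptive"
      d$rejected <- FALSE
      d$phase_set <- i
      pieces[[length(pieces) + 1]] <- d
      n_on <- n_on + nrow(d)
    }
  }
  # adaptive channels: rejected off-target molecules, truncated
  if (n_on > 0 && total_target < genome) {
    n_rej <- round(n_on * (genome - total_target) / total_target)
    if (n_rej > 0) {
      chrom <- sample(names(lens), n_rej, replace = TRUE, prob = lens / genome)
      x0 <- floor(stats::runif(n_rej, 0, lens[chrom]))
      on_tgt <- rep(FALSE, n_rej)
      probe <- gintervals(chrom, x0, x0 + 1)
      on_tgt <- gi_overlap_width(probe, panel$merged) > 0
      chrom <- chrom[!on_tgt]; x0 <- x0[!on_tgt]
      if (length(x0)) {
        d <- data.frame(chrom = chrom, start = x0,
                        end = pmin(lens[chrom], x0 + p$decision_length))
        d <- d[d$end > d$start, ]
        d$channel_set <- "adaptive"; d$rejected <- TRUE; d$phase_set <- NA_integer_
        pieces[[length(pieces) + 1]] <- d
      }
    }
  }
  # nonadaptive channels: whole-genome background
  if (p$background_depth > 0) for (chrom in names(lens)) {
    d <- draw_budget_reads(chrom, 0, lens[[chrom]], lens[[chrom]],
                           p$background_depth * lens[[chrom]], p)
    if (nrow(d)) {
      d$channel_set <- "nonadaptive"; d$rejected <- FALSE; d$phase_set <- NA_integer_
      pieces[[length(pieces) + 1]] <- d
    }
  }
  if (!length(pieces)) {
    rec <- alignment_records(character(0), character(0), numeric(0), numeric(0),
                             integer(0))
    return(list(records = rec, truth = list(params = p, seed = seed,
                                            active_duplications = ref$truth$duplications[0, ])))
  }
  reads <- do.call(rbind, pieces)
  n <- nrow(reads)
  reads$read_id <- sprintf("r%06d", seq_len(n))
  reads$channel <- ifelse(reads$channel_set == "adaptive",
                          sample(p$adaptive_channels, n, replace = TRUE),
                          sample(p$nonadaptive_channels, n, replace = TRUE))
  reads$start_time <- round(stats::runif(n, 0, p$run_hours * 3600), 1)
  reads$haplotype <- ifelse(!is.na(reads$phase_set),
                            sample(1:2, n, replace = TRUE), NA_integer_)

  # duplication signature: primary at the copy, supplementary at the source
  dup <- ref$truth$duplications
  active <- logical(nrow(dup))
  for (i in seq_len(nrow(dup))) {
    d <- dup[i, ]
    copy_seq <- Biostrings::subseq(ref$seqs[[d$copy_chrom]], d$copy_start + 1, d$copy_end)
    n_frac <- Biostrings::letterFrequency(copy_seq, "N") / (d$copy_end - d$copy_start)
    active[i] <- n_frac < 0.5
  }
  origin <- reads  # untouched molecule origins; masks computed against these
  prim <- reads
  supp_pieces <- list()
  for (i in which(active)) {
    d <- dup[i, ]
    shift <- d$copy_start - d$src_start
    # molecules originating in the source segment: primary relocated to the copy
    in_src <- origin$chrom == d$src_chrom & origin$start >= d$src_start &
      origin$start < d$src_end
    if (any(in_src)) {
      os <- origin$start[in_src]; oe <- pmin(origin$end[in_src], d$src_end)
      supp_pieces[[length(supp_pieces) + 1]] <- data.frame(
        chrom = d$src_chrom, start = os, end = oe,
        read_id = origin$read_id[in_src], channel = origin$channel[in_src],
        start_time = origin$start_time[in_src])
      prim$chrom[in_src] <- d$copy_chrom
      prim$start[in_src] <- os + shift
      prim$end[in_src] <- oe + shift
      prim$haplotype[in_src] <- NA_integer_
      prim$phase_set[in_src] <- NA_integer_
    }
    # molecules originating in the copy: primary stays, supplementary at source
    in_copy <- origin$chrom == d$copy_chrom & origin$start >= d$copy_start &
      origin$start < d$copy_end
    if (any(in_copy)) {
      os <- origin$start[in_copy]; oe <- pmin(origin$end[in_copy], d$copy_end)
      supp_pieces[[length(supp_pieces) + 1]] <- data.frame(
        chrom = d$src_chrom, start = os - shift, end = oe - shift,
        read_id = origin$read_id[in_copy], channel = origin$channel[in_copy],
        start_time = origin$start_time[in_copy])
    }
  }
  rec <- alignment_records(
    read_id = prim$read_id, chrom = prim$chrom, start = prim$start,
    end = prim$end, mapq = 60L, channel = prim$channel,
    start_time = prim$start_time, haplotype = prim$haplotype,
    phase_set = prim$phase_set)
  if (length(supp_pieces)) {
    sp <- do.call(rbind, supp_pieces)
    rec <- rbind(rec, alignment_records(
      read_id = sp$read_id, chrom = sp$chrom, start = sp$start, end = sp$end,
      mapq = 60L, supplementary = TRUE, channel = sp$channel,
      start_time = sp$start_time))
    validate_alignment_records(rec)
  }
  list(records = rec,
       truth = list(params = p, seed = seed,
                    active_duplications = dup[active, , drop = FALSE]))
}

#' Simulate phased variants realizing requested phase breadths and cis/trans pairs
#'
#' Per gene, one phase block covering the requested fraction of the core
#' (anchored by heterozygous SNVs at both block ends so the block is exactly
#' recoverable from the VCF), plus optional variant pairs placed inside the
#' block with genotypes realizing their cis/trans labels.
#'
#' @param panel a `target_panel`.
#' @param breadths named numeric vector in [0,1], one per gene (default: 1
#'   for every locus).
#' @param pairs list of lists with fields `gene` and `label`
#'   (`"cis"`/`"trans"`).
#' @param seed integer seed.
#' @return list: `variants` (table in [read_phased_variants()] layout),
#'   `blocks` (planted block intervals with `phase_set`), `truth` (pair
#'   labels and requested breadths).
#' @export
simulate_phased_variants <- function(panel, breadths = NULL, pairs = list(),
                                     seed = 1) {
  stopifnot(inherits(panel, "target_panel"))
  set.seed(seed)
  cores <- panel_cores(panel)
  if (is.null(breadths))
    breadths <- stats::setNames(rep(1, nrow(cores)), cores$name)
  stopifnot(all(breadths >= 0 & breadths <= 1),
            all(names(breadths) %in% cores$name))
  vrows <- list(); brows <- list(); prows <- list()
  for (g in names(breadths)) {
    core <- cores[cores$name == g, ]
    L <- core$end - core$start
    plen <- round(breadths[[g]] * L)
    ps <- 1000L + match(g, cores$name)
    gene_pairs <- Filter(function(x) identical(x$gene, g), pairs)
    if (plen < 1) {
      if (length(gene_pairs))
        stop("pair requested in gene ", g, " but breadth ", breadths[[g]],
             " leaves no phased positions")
      next
    }
    brows[[g]] <- data.frame(chrom = core$chrom, start = core$start,
                             end = core$start + plen, name = paste0("PS", ps),
                             phase_set = ps, stringsAsFactors = FALSE)
    anchor_pos <- unique(c(core$start, core$start + plen - 1))  # 0-based
    for (k in seq_along(anchor_pos)) {
      vrows[[length(vrows) + 1]] <- data.frame(
        id = sprintf("%s_anchor%d", g, k), chrom = core$chrom,
        pos = anchor_pos[k] + 1, ref = "A", alt = "C",
        gt1 = 1L, gt2 = 0L, phased = TRUE, phase_set = ps,
        svtype = NA_character_, sv_end = NA_real_, stringsAsFactors = FALSE)
    }
    if (length(gene_pairs)) {
      if (plen < 2 + 2 * length(gene_pairs))
        stop("pair requested in gene ", g, " but breadth ", breadths[[g]],
             " excludes a variant position")
      # interior positions, distinct from anchors and each other
      avail <- setdiff(seq(core$start + 1, core$start + plen - 2),
                       anchor_pos)
      for (pi in seq_along(gene_pairs)) {
        lab <- match.arg(gene_pairs[[pi]]$label, c("cis", "trans"))
        pos2 <- sort(sample(avail, 2))
        avail <- setdiff(avail, pos2)
        ids <- sprintf("%s_pair%d_%s", g, pi, c("a", "b"))
        gt <- if (lab == "cis") list(c(1L, 0L), c(1L, 0L)) else
          list(c(1L, 0L), c(0L, 1L))
        for (k in 1:2) {
          vrows[[length(vrows) + 1]] <- data.frame(
            id = ids[k], chrom = core$chrom, pos = pos2[k] + 1,
            ref = "A", alt = "G", gt1 = gt[[k]][1], gt2 = gt[[k]][2],
            phased = TRUE, phase_set = ps, svtype = NA_character_,
            sv_end = NA_real_, stringsAsFactors = FALSE)
        }
        prows[[length(prows) + 1]] <- data.frame(
          gene = g, id1 = ids[1], id2 = ids[2], label = lab,
          stringsAsFactors = FALSE)
      }
    }
  }
  variants <- if (length(vrows)) do.call(rbind, vrows) else
    read_phased_variants_empty()
  variants <- variants[order(variants$chrom, variants$pos), ]
  rownames(variants) <- NULL
  blocks <- if (length(brows)) do.call(rbind, c(brows, make.row.names = FALSE)) else {
    x <- empty_gintervals(); x$phase_set <- integer(0); x
  }
  truth_pairs <- if (length(prows)) do.call(rbind, prows) else
    data.frame(gene = character(), id1 = character(), id2 = character(),
               label = character(), stringsAsFactors = FALSE)
  list(variants = variants, blocks = blocks,
       truth = list(breadths = breadths, pairs = truth_pairs, seed = seed))
}

read_phased_variants_empty <- function() {
  data.frame(id = character(), chrom = character(), pos = numeric(),
             ref = character(), alt = character(), gt1 = integer(),
             gt2 = integer(), phased = logical(), phase_set = integer(),
             svtype = character(), sv_end = numeric(), stringsAsFactors = FALSE)
}

#' Simulate a methylome with planted hypomethylated intervals
#'
#' Emits one site per CG dinucleotide of the reference. Modified fractions
#' are drawn from `Beta(baseline_shape1, baseline_shape2)` (default mean 0.9,
#' the heavily methylated genomic baseline) except inside planted intervals,
#' where `Beta(hypo_shape1, hypo_shape2)` (default mean 0.1) emulates an
#' unmethylated regulatory element. Coverages are Poisson; zero-coverage
#' sites are dropped (their fraction is undefined).
#'
#' @param ref a `sim_reference`.
#' @param hypo_intervals interval table of planted hypomethylated regions.
#' @param baseline_shape1,baseline_shape2,hypo_shape1,hypo_shape2 Beta shapes.
#' @param coverage_mean Poisson mean of per-site coverage.
#' @param seed integer seed.
#' @return list: `sites` (`chrom`, `pos`, `coverage`, `fraction`) and `truth`.
#' @export
simulate_methylome <- function(ref, hypo_intervals,
                               baseline_shape1 = 9, baseline_shape2 = 1,
                               hypo_shape1 = 1, hypo_shape2 = 9,
                               coverage_mean = 20, seed = 1) {
  stopifnot(inherits(ref, "sim_reference"), coverage_mean > 0)
  set.seed(seed)
  if (nrow(hypo_intervals)) validate_gintervals(hypo_intervals, "hypo interval")
  rows <- list()
  for (chrom in names(ref$seqs)) {
    hits <- Biostrings::matchPattern("CG", ref$seqs[[chrom]])
    pos <- BiocGenerics::start(hits) - 1  # 0-based C of each CpG
    if (!length(pos)) next
    hy <- hypo_intervals[hypo_intervals$chrom == chrom, , drop = FALSE]
    in_hypo <- rep(FALSE, length(pos))
    for (j in seq_len(nrow(hy)))
      in_hypo <- in_hypo | (pos >= hy$start[j] & pos < hy$end[j])
    frac <- numeric(length(pos))
    frac[!in_hypo] <- stats::rbeta(sum(!in_hypo), baseline_shape1, baseline_shape2)
    frac[in_hypo] <- stats::rbeta(sum(in_hypo), hypo_shape1, hypo_shape2)
    cov <- stats::rpois(length(pos), coverage_mean)
    keep <- cov > 0
    rows[[chrom]] <- data.frame(chrom = chrom, pos = pos[keep],
                                coverage = cov[keep], fraction = frac[keep],
                                stringsAsFactors = FALSE)
  }
  sites <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else NULL
  list(sites = sites,
       truth = list(hypo_intervals = hypo_intervals, seed = seed))
}

#' Write alignment records as SAM
#'
#' Standards-conformant SAM 1.6 with `ch`/`st`/`HP`/`PS` tags and SA tags on
#' split alignments; round-trips through [read_alignments()].
#'
#' @param records an `alignment_records` table.
#' @param chrom_lengths named numeric vector for the `@SQ` header lines.
#' @param path output path.
#' @export
write_sam <- function(records, chrom_lengths, path) {
  mapped <- !records$unmapped
  if (any(mapped & (records$end > chrom_lengths[records$chrom])))
    stop("record beyond reference bounds")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                     as.integer(chrom_lengths)), con)
  if (nrow(records) == 0) return(invisible(path))
  flag <- ifelse(records$unmapped, 4L, 0L) +
    ifelse(records$secondary, 256L, 0L) +
    ifelse(records$duplicate, 1024L, 0L) +
    ifelse(records$supplementary, 2048L, 0L)
  w <- ifelse(mapped, records$end - records$start, 0)
  cigar <- ifelse(mapped, paste0(format_bp(w), "M"), "*")
  # SA tag on split reads so supplementary records are self-consistent
  split_ids <- unique(records$read_id[records$supplementary])
  sa <- rep("", nrow(records))
  if (length(split_ids)) {
    idx <- which(records$read_id %in% split_ids & mapped)
    for (i in idx) {
      mates <- setdiff(which(records$read_id == records$read_id[i] & mapped), i)
      if (length(mates))
        sa[i] <- paste0("\tSA:Z:", paste0(
          records$chrom[mates], ",", format_bp(records$start[mates] + 1),
          ",+,", cigar[mates], ",", records$mapq[mates], ",0;", collapse = ""))
    }
  }
  opt <- paste0(
    ifelse(is.na(records$channel), "", sprintf("\tch:i:%d", records$channel)),
    ifelse(is.na(records$start_time), "",
           sprintf("\tst:f:%s", format_bp(records$start_time))),
    ifelse(is.na(records$haplotype), "", sprintf("\tHP:i:%d", records$haplotype)),
    ifelse(is.na(records$phase_set), "", sprintf("\tPS:i:%d", records$phase_set)),
    sa)
  mapq <- ifelse(is.na(records$mapq), 0L, records$mapq)
  lines <- paste0(records$read_id, "\t", flag, "\t",
                  ifelse(mapped, records$chrom, "*"), "\t",
                  ifelse(mapped, format_bp(records$start + 1), "0"), "\t",
                  mapq, "\t", cigar, "\t*\t0\t0\t*\t*", opt)
  writeLines(lines, con)
  invisible(path)
}

#' Write variants as a phased VCF 4.2
#'
#' `GT` uses `|` for phased genotypes (with `PS`) and `/` otherwise; symbolic
#' SV rows carry `SVTYPE`/`END` INFO. Round-trips through
#' [read_phased_variants()].
#'
#' @param variants table in the [read_phased_variants()] layout.
#' @param path output path.
#' @param chrom_lengths optional named vector for `##contig` header lines.
#' @param sample sample name, default `"SAMPLE"`.
#' @export
write_vcf <- function(variants, path, chrom_lengths = NULL, sample = "SAMPLE") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">"), con)
  if (!is.null(chrom_lengths))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
                       as.integer(chrom_lengths)), con)
  writeLines(paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                    sample), con)
  v <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  if (nrow(v)) {
    info <- ifelse(!is.na(v$svtype),
                   paste0("SVTYPE=", v$svtype, ";END=", format_bp(v$sv_end)), ".")
    alt <- ifelse(!is.na(v$svtype), paste0("<", v$svtype, ">"), v$alt)
    sep <- ifelse(v$phased, "|", "/")
    gt <- paste0(v$gt1, sep, v$gt2)
    fmt <- ifelse(v$phased & !is.na(v$phase_set), "GT:PS", "GT")
    smp <- ifelse(v$phased & !is.na(v$phase_set),
                  paste0(gt, ":", v$phase_set), gt)
    writeLines(paste(v$chrom, format_bp(v$pos), v$id, v$ref, alt, ".", "PASS",
                     info, fmt, smp, sep = "\t"), con)
  }
  invisible(path)
}

#' Write per-site 5mC calls as a bedMethyl-style TSV
#'
#' Five columns: chrom, start, end (start + 1), coverage, percent modified.
#' Round-trips through [read_bedmethyl()].
#'
#' @param sites table with `chrom`, `pos`, `coverage`, `fraction`.
#' @param path output path.
#' @export
write_bedmethyl <- function(sites, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(sites))
    writeLines(paste(sites$chrom, format_bp(sites$pos), format_bp(sites$pos + 1),
                     sites$coverage, sprintf("%.4f", sites$fraction * 100),
                     sep = "\t"), con)
  invisible(path)
}

#' The default seeded end-to-end scenario
#'
#' Two 1.5-Mb chromosomes carrying 12 target loci with 20-40 kb cores and
#' 10-kb flanks, one planted segmental duplication covering most of locus
#' `L04`'s target (its copy placed off-panel on chr2), one planted
#' hypomethylated interval, and phased-variant configurations spanning the
#' breadth grid and cis/trans labels.
#'
#' @param seed integer seed (default 17).
#' @return list: `ref` (`sim_reference`), `panel` (`target_panel`), `params`
#'   ([run_params()]), `dup_locus` (name of the duplication-affected locus),
#'   `hypo_intervals`, `seed`.
#' @export
default_scenario <- function(seed = 17) {
  lens <- c(chr1 = 1500000, chr2 = 1500000)
  cores <- gintervals(
    chrom = rep(c("chr1", "chr2"), each = 6),
    start = c(60000, 160000, 260000, 380000, 520000, 700000,
              80000, 200000, 320000, 500000, 660000, 850000),
    end = c(90000, 180000, 300000, 404000, 556000, 728000,
            112000, 220000, 360000, 524000, 696000, 878000),
    name = sprintf("L%02d", 1:12))
  dup <- list(src_chrom = "chr1", src_start = 375000, src_end = 409000,
              copy_chrom = "chr2", copy_start = 1100000, identity = 0.98)
  ref <- make_reference(lens, duplications = list(dup), seed = seed)
  panel <- build_targets(cores, flank = 10000, chrom_lengths = lens)
  list(ref = ref, panel = panel, params = run_params(),
       dup_locus = "L04",
       dup_copy = gintervals("chr2", 1100000, 1134000, "dup_copy"),
       hypo_intervals = gintervals("chr2", 1250000, 1252000, "hypo1"),
       seed = seed)
}
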