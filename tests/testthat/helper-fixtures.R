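# Shared fixture builders. Everything is generated in code; no binary files.

toy_lens <- c(chr1 = 1e6, chr2 = 1e6)

# three disjoint loci on chr1, flank 0 unless asked
toy_panel <- function(flank = 0, lens = toy_lens) {
  genes <- gintervals(c("chr1", "chr1", "chr2"),
                      c(100000, 400000, 200000),
                      c(130000, 470000, 220000),
                      c("GA", "GB", "GC"))
  build_targets(genes, flank = flank, chrom_lengths = lens)
}

# shorthand primary record
rec <- function(chrom, start, end, mapq = 60, id = NULL, ...) {
  if (is.null(id)) id <- sprintf("r%s_%s", chrom, start)
  alignment_records(read_id = id, chrom = chrom, start = start, end = end,
                    mapq = mapq, ...)
}

# n stacked full-span records over an interval (coverage exactly n)
stack_recs <- function(chrom, start, end, n, prefix = "s", ...) {
  alignment_records(read_id = sprintf("%s%03d", prefix, seq_len(n)),
                    chrom = chrom, start = start, end = end, mapq = 60, ...)
}

# forge a targeting_assessment table from raw fractions (for regression tests)
forge_assessment <- function(expected, observed_bases) {
  total <- sum(observed_bases)
  out <- data.frame(
    name = sprintf("T%02d", seq_along(expected)),
    expected_fraction = expected,
    observed_bases = observed_bases,
    observed_fraction = observed_bases / total,
    stringsAsFactors = FALSE)
  out$log_expected <- log10(out$expected_fraction)
  out$log_observed <- ifelse(out$observed_bases > 0,
                             log10(out$observed_fraction), -Inf)
  out$residual <- NA_real_
  out$flagged <- FALSE
  attr(out, "off_target") <- 0
  class(out) <- c("targeting_assessment", "data.frame")
  out
}

# independent OLS oracle: explicit normal equations
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  r <- y - X %*% beta
  list(intercept = beta[1], slope = beta[2], residuals = as.numeric(r),
       residual_sd = sqrt(sum(r^2) / (length(y) - 2)),
       r_squared = 1 - sum(r^2) / sum((y - mean(y))^2))
}

reciprocal_overlap <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  ov <- max(0, min(a$end, b$end) - max(a$start, b$start))
  min(ov / (a$end - a$start), ov / (b$end - b$start))
}
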