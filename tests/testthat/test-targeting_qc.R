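test_that("observed_bases apportions, filters and conserves", {
  p <- toy_panel()  # GA chr1:[1e5,1.3e5) GB chr1:[4e5,4.7e5) GC chr2:[2e5,2.2e5)
  inside <- rec("chr1", 101000, 102000, id = "in")
  o <- observed_bases(inside, p)
  expect_equal(unname(o$per_locus["GA"]), 1000)
  expect_equal(o$off_target, 0)

  half <- rec("chr1", 129500, 130500, id = "half")
  o2 <- observed_bases(half, p)
  expect_equal(unname(o2$per_locus["GA"]), 500)
  expect_equal(o2$off_target, 500)

  low <- rec("chr1", 101000, 102000, mapq = 0, id = "low")
  o3 <- observed_bases(low, p, uniqueness_mapq = 1)
  expect_equal(sum(o3$per_locus) + o3$off_target, 0)

  # conservation on a random record set
  set.seed(3)
  s <- sample(0:9e5, 60, replace = TRUE)
  recs <- alignment_records(sprintf("r%d", 1:60),
                            sample(c("chr1", "chr2"), 60, replace = TRUE),
                            s, s + sample(100:20000, 60, replace = TRUE), 60)
  o4 <- observed_bases(recs, p)
  expect_equal(sum(o4$per_locus) + o4$off_target, sum(recs$end - recs$start))
})

test_that("exact proportionality gives slope 1, zero residuals, r^2 = 1", {
  ef <- c(0.05, 0.1, 0.15, 0.2, 0.22, 0.28)
  a <- forge_assessment(ef, observed_bases = ef * 4e6)
  fit <- fit_targeting_regression(a)
  expect_equal(fit$slope, 1, tolerance = 1e-10)
  expect_equal(unname(fit$residuals), rep(0, 6), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  a <- flag_undertargeted(a, fit)
  expect_false(any(a$flagged))
})

test_that("a planted 10x deficit matches the closed-form OLS oracle", {
  set.seed(5)
  ef <- runif(10, 0.02, 0.2); ef <- ef / sum(ef)
  ob <- ef * 5e6
  ob[4] <- ob[4] / 10                     # one locus observes a tenth of expectation
  a <- forge_assessment(ef, ob)
  fit <- fit_targeting_regression(a)
  orc <- ols_oracle(a$log_expected, a$log_observed)
  expect_equal(fit$slope, orc$slope, tolerance = 1e-9)
  expect_equal(fit$intercept, orc$intercept, tolerance = 1e-9)
  expect_equal(unname(fit$residuals), orc$residuals, tolerance = 1e-9)
  expect_equal(fit$residual_sd, orc$residual_sd, tolerance = 1e-9)
  expect_lt(fit$residuals[["T04"]], -0.8)  # ~ -1 log10 unit, shrunk by the fit
})

test_that("zero-observed loci are excluded from the fit and auto-flagged", {
  ef <- rep(0.1, 10)
  ob <- rep(1e5, 10); ob[7] <- 0
  a <- forge_assessment(ef, ob)
  fit <- fit_targeting_regression(a)
  expect_equal(fit$n_used, 9)
  expect_true(is.na(fit$residuals[["T07"]]))
  a <- flag_undertargeted(a, fit)
  expect_equal(a$name[a$flagged], "T07")
  # fewer than 3 usable loci is an error
  expect_error(fit_targeting_regression(forge_assessment(c(.5, .3, .2), c(1e5, 2e5, 0))),
               ">= 3 loci")
})

test_that("flagging is one-sided: a deficit flags, a surplus never does", {
  set.seed(9)
  ef <- runif(20, 0.01, 0.1); ef <- ef / sum(ef)
  ob <- ef * 1e7 * exp(rnorm(20, 0, 0.005))
  ob[13] <- ob[13] / 10                   # planted deficit
  ob[2] <- ob[2] * 2                      # clear surplus, same |log| order
  a <- forge_assessment(ef, ob)
  fit <- fit_targeting_regression(a)
  a <- flag_undertargeted(a, fit, z_threshold = 2)
  expect_true(a$flagged[13])
  expect_false(a$flagged[2])
  expect_equal(sum(a$flagged), 1)
})

test_that("diagnose_duplicates reads the supplementary signature", {
  lens <- c(chr1 = 1e6, chr2 = 1e6)
  p <- build_targets(gintervals(c("chr1", "chr1", "chr1"),
                                c(1e5, 3e5, 5e5), c(1.4e5, 3.4e5, 5.4e5),
                                c("A", "B", "C")),
                     flank = 0, chrom_lengths = lens)
  flagged <- p$loci[p$loci$name == "A", ]

  # all-primary coverage: no duplicate signature
  prim_only <- stack_recs("chr1", 100000, 140000, 5)
  d0 <- diagnose_duplicates(prim_only, flagged, p)
  expect_equal(nrow(d0$candidates), 0)
  expect_lt(d0$evidence$supp_fraction, 0.5)

  # no coverage at all
  d1 <- diagnose_duplicates(stack_recs("chr2", 0, 1000, 2), flagged, p)
  expect_equal(d1$evidence$note, "no coverage")

  # supplementary at the locus, primaries clustered at an off-panel copy
  mk_pair <- function(ids, copy_start) rbind(
    alignment_records(ids, "chr2", copy_start, copy_start + 30000, 60),
    alignment_records(ids, "chr1", 105000, 135000, 60, supplementary = TRUE))
  recs <- rbind(mk_pair(sprintf("d%d", 1:4), 700000),
                stack_recs("chr1", 100000, 105000, 2, prefix = "p"))
  d2 <- diagnose_duplicates(recs, flagged, p)
  expect_equal(nrow(d2$candidates), 1)
  expect_equal(d2$candidates$start, 700000)
  expect_equal(d2$candidates$end, 730000)
  expect_equal(d2$candidates$n_reads, 4)

  # two planted copies -> two clusters with split support
  recs3 <- rbind(mk_pair(sprintf("x%d", 1:3), 650000),
                 mk_pair(sprintf("y%d", 1:5), 850000))
  d3 <- diagnose_duplicates(recs3, flagged, p)
  expect_equal(nrow(d3$candidates), 2)
  expect_equal(sort(d3$candidates$n_reads), c(3, 5))

  # clusters below the read-support floor are dropped
  d4 <- diagnose_duplicates(mk_pair(sprintf("z%d", 1:2), 650000), flagged, p)
  expect_equal(nrow(d4$candidates), 0)
})

test_that("emit_mask_set merges, records provenance and truncates at panel edges", {
  lens <- c(chr1 = 1e6)
  p <- build_targets(gintervals("chr1", 1e5, 2e5, "A"), flank = 0,
                     chrom_lengths = lens)
  cand <- function(s, e, n = 5) cbind(gintervals("chr1", s, e), n_reads = n)
  d <- function(cd) list(candidates = cd, in_panel = empty_gintervals(),
                         evidence = list(supp_fraction = 0.9, note = ""))

  one <- emit_mask_set(list(A = d(cand(5e5, 5.2e5))), p)
  expect_equal(nrow(one$intervals), 1)
  expect_equal(one$provenance$loci, "A")

  both <- emit_mask_set(list(A = d(cand(5e5, 5.2e5)), B = d(cand(5.1e5, 5.3e5))), p)
  expect_equal(nrow(both$intervals), 1)
  expect_equal(both$intervals$start, 5e5)
  expect_equal(both$intervals$end, 5.3e5)
  expect_equal(both$provenance$loci, "A,B")

  # interval-clip oracle: candidate [190000,260000) minus target [1e5,2e5)
  straddle <- emit_mask_set(list(A = d(cand(190000, 260000))), p)
  expect_equal(straddle$intervals$start, 200000)
  expect_equal(straddle$intervals$end, 260000)
  expect_match(straddle$provenance$warning, "truncated")

  # mask-in-panel policy masks the in-panel footprint instead
  din <- list(A = list(candidates = cand(5e5, 5.2e5),
                       in_panel = gintervals("chr1", 1.2e5, 1.5e5),
                       evidence = list(supp_fraction = 0.9, note = "")))
  inp <- emit_mask_set(din, p, policy = "mask-in-panel")
  expect_equal(inp$intervals$start, 1.2e5)
  expect_equal(inp$intervals$end, 1.5e5)
})

test_that("mask BED round-trips with provenance", {
  p <- build_targets(gintervals("chr1", 1e5, 2e5, "A"), flank = 0,
                     chrom_lengths = c(chr1 = 1e6))
  d <- list(A = list(candidates = cbind(gintervals("chr1", 5e5, 5.2e5), n_reads = 5),
                     in_panel = empty_gintervals(),
                     evidence = list(supp_fraction = 0.9, note = "")))
  ms <- emit_mask_set(d, p)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_mask_bed(ms, bed)
  back <- read_mask_bed(bed)
  expect_equal(back$intervals[, c("chrom", "start", "end")],
               ms$intervals[, c("chrom", "start", "end")])
  expect_equal(back$provenance$loci, "A")
})
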