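test_that("partition_channels routes by channel id", {
  part <- channel_partition(1:256, 257:512)
  recs <- rbind(rec("chr1", 0, 100, id = "a", channel = 10),
                rec("chr1", 0, 100, id = "b", channel = 300),
                rec("chr1", 0, 100, id = "c"))
  out <- partition_channels(recs, part)
  expect_equal(out$adaptive$read_id, "a")
  expect_equal(out$nonadaptive$read_id, "b")
  expect_equal(out$unassigned, 1)
  none <- partition_channels(recs, channel_partition(integer(0), integer(0)))
  expect_equal(none$unassigned, 3)
  expect_error(channel_partition(1:10, 5:20), "disjoint")
})

test_that("mean_target_coverage divides bases by target size, unweighted mean", {
  p1 <- build_targets(gintervals("chr1", 0, 100000, "X"), 0, c(chr1 = 1e6))
  recs <- stack_recs("chr1", 0, 100000, 25)
  expect_equal(mean_target_coverage(recs, p1)$mean, 25)

  p2 <- build_targets(gintervals(c("chr1", "chr1"), c(0, 200000),
                                 c(100000, 300000), c("X", "Y")),
                      0, c(chr1 = 1e6))
  recs2 <- rbind(stack_recs("chr1", 0, 100000, 10, prefix = "x"),
                 stack_recs("chr1", 200000, 300000, 30, prefix = "y"))
  mt <- mean_target_coverage(recs2, p2)
  expect_equal(unname(mt$per_locus), c(10, 30))
  expect_equal(mt$mean, 20)
  expect_equal(mean_target_coverage(recs2[0, ], p2)$mean, 0)
  expect_error(mean_target_coverage(recs2, build_targets(empty_gintervals(), 0,
                                                         c(chr1 = 1e6))))
})

test_that("mean_target_coverage is linear in read count", {
  p <- toy_panel()
  set.seed(15)
  s <- sample(0:9e5, 50, replace = TRUE)
  recs <- alignment_records(sprintf("r%d", 1:50), "chr1", s,
                            s + sample(100:10000, 50, TRUE), 60)
  doubled <- rbind(recs, alignment_records(sprintf("q%d", 1:50), "chr1",
                                           recs$start, recs$end, 60))
  expect_equal(mean_target_coverage(doubled, p)$per_locus,
               2 * mean_target_coverage(recs, p)$per_locus)
})

test_that("background_coverage tiles, excludes target windows, averages", {
  lens <- c(chr1 = 100000)
  p <- build_targets(gintervals("chr1", 20000, 40000, "T"), 0, lens)
  recs <- stack_recs("chr1", 0, 100000, 2)
  bg <- background_coverage(recs, lens, p, window = 10000)
  expect_equal(bg$n_windows, 8)
  expect_equal(bg$mean, 2.0)
  expect_equal(background_coverage(recs[0, ], lens, p, window = 10000)$mean, 0)
  expect_error(background_coverage(recs, c(chr1 = 5000), p, window = 10000),
               "windows")
})

test_that("background estimate recovers a planted Poisson-like depth", {
  # lambda = 1.5 planted as uniform random 1-kb reads; 3-SE tolerance
  set.seed(99)
  lens <- c(bg = 200000, far = 50000)
  p <- build_targets(gintervals("far", 0, 50000, "T"), 0, lens)
  lambda <- 1.5; rl <- 1000
  n <- round(lambda * lens[["bg"]] / rl)
  s <- floor(runif(n, -rl + 1, lens[["bg"]] - 1))
  recs <- alignment_records(sprintf("r%d", 1:n), "bg", pmax(0, s),
                            pmin(lens[["bg"]], s + rl), 60)
  est <- background_coverage(recs, lens, p, window = 10000)$mean
  se <- lambda / sqrt(n)
  expect_lt(abs(est - lambda), 3 * se + 0.05)
})

test_that("enrichment is the coverage ratio, undefined on zero background", {
  expect_equal(enrichment(25, 1.5625)$enrichment, 16)
  expect_equal(enrichment(3, 3)$enrichment, 1)
  z <- enrichment(10, 0)
  expect_false(z$defined)
  expect_true(is.na(z$enrichment))
  expect_equal(z$target, 10)
})

test_that("phase_breadth unions blocks over strict cores", {
  cores <- gintervals("chr1", 1000, 11000, "G")
  blocks <- data.frame(chrom = "chr1", start = c(0, 7000), end = c(6000, 20000),
                       name = c("PS1", "PS2"), phase_set = c(1, 2))
  pb <- phase_breadth(blocks, cores)
  expect_equal(pb$phased_bp, 9000)
  expect_equal(pb$breadth, 0.9)
  expect_false(pb$fully_phased)

  full <- phase_breadth(data.frame(chrom = "chr1", start = 0, end = 20000,
                                   name = "PS1", phase_set = 1), cores)
  expect_equal(full$breadth, 1)
  expect_true(full$fully_phased)
  zero_core <- data.frame(chrom = "chr1", start = 5, end = 5, name = "z")
  expect_error(phase_breadth(blocks, zero_core))
})

test_that("overlapping blocks count core bases once (boolean oracle)", {
  set.seed(31)
  core <- gintervals("chr1", 2000, 12000, "G")
  for (i in 1:10) {
    n <- sample(1:6, 1)
    s <- sample(0:14000, n, replace = TRUE)
    blocks <- data.frame(chrom = "chr1", start = s,
                         end = s + sample(500:6000, n, replace = TRUE),
                         name = "b", phase_set = seq_len(n))
    covered <- rep(FALSE, 10000)
    for (k in seq_len(n)) {
      lo <- max(blocks$start[k], 2000); hi <- min(blocks$end[k], 12000)
      if (hi > lo) covered[(lo - 1999):(hi - 2000)] <- TRUE
    }
    expect_equal(phase_breadth(blocks, core)$phased_bp, sum(covered))
  }
})

test_that("phase breadth is invariant to splitting a block", {
  core <- gintervals("chr1", 1000, 11000, "G")
  whole <- data.frame(chrom = "chr1", start = 0, end = 8000, name = "a",
                      phase_set = 1)
  split2 <- data.frame(chrom = "chr1", start = c(0, 4000), end = c(4000, 8000),
                       name = c("a", "b"), phase_set = c(1, 2))
  expect_equal(phase_breadth(split2, core)$breadth,
               phase_breadth(whole, core)$breadth)
})

test_that("blocks_from_phased_vcf derives blocks from PS groups", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  v <- data.frame(id = c("a", "b", "c", "d"), chrom = "chr1",
                  pos = c(101, 500, 900, 950), ref = c("A", "AT", "G", "C"),
                  alt = "T", gt1 = c(1L, 0L, 0L, 1L), gt2 = c(0L, 1L, 1L, 0L),
                  phased = c(TRUE, TRUE, FALSE, TRUE),
                  phase_set = c(77L, 77L, NA, 12L),
                  svtype = NA_character_, sv_end = NA_real_)
  write_vcf(v, vcf, chrom_lengths = c(chr1 = 10000))
  blocks <- blocks_from_phased_vcf(vcf)
  b77 <- blocks[blocks$phase_set == 77, ]
  expect_equal(b77$start, 100)
  expect_equal(b77$end, 501)          # last variant's 2-bp ref allele included
  b12 <- blocks[blocks$phase_set == 12, ]
  expect_equal(c(b12$start, b12$end), c(949, 950))  # single-variant block

  v$phased <- FALSE; v$phase_set <- NA_integer_
  write_vcf(v, vcf, chrom_lengths = c(chr1 = 10000))
  expect_equal(nrow(blocks_from_phased_vcf(vcf)), 0)

  v$phased <- TRUE                     # phased but no PS -> warning, ignored
  write_vcf(v, vcf, chrom_lengths = c(chr1 = 10000))
  expect_warning(b <- blocks_from_phased_vcf(vcf), "phase set")
  expect_equal(nrow(b), 0)
})

test_that("time_to_phase finds the earliest joint phasing time", {
  vars <- data.frame(chrom = "chr1", pos = c(1000, 9000))
  covering <- function(id, s, e, t, ps, hp = 1)
    alignment_records(id, "chr1", s, e, 60, channel = 1, start_time = t,
                      haplotype = hp, phase_set = ps)
  # both variants covered by reads of one phase set; second arrives at 3600
  recs <- rbind(covering("a", 500, 1500, 1200, 5),
                covering("b", 8500, 9500, 3600, 5),
                covering("late", 0, 10000, 7200, 5))
  expect_equal(as.numeric(time_to_phase(recs, vars)), 3600)

  # phase sets never linked -> undefined
  recs2 <- rbind(covering("a", 500, 1500, 1200, 5),
                 covering("b", 8500, 9500, 3600, 6))
  expect_true(is.na(time_to_phase(recs2, vars)))

  # linked through a shared read id spanning both phase sets
  recs3 <- rbind(recs2, covering("a", 8000, 8400, 4000, 6))
  expect_equal(as.numeric(time_to_phase(recs3, vars)), 4000)

  # support rule: one covering read per variant is not enough at min_support 2
  single <- rbind(covering("a", 500, 1500, 1200, 5),
                  covering("b", 8500, 9500, 3600, 5))
  expect_true(is.na(time_to_phase(single, vars, min_support = 2)))

  # untimed records are excluded and counted
  recs4 <- rbind(recs, covering("nt", 0, 10000, NA, 5))
  out <- time_to_phase(recs4, vars)
  expect_equal(attr(out, "n_no_timestamp"), 1)
  expect_equal(as.numeric(out), 3600)
})

test_that("time_to_phase is monotone under added records", {
  set.seed(44)
  vars <- data.frame(chrom = "chr1", pos = c(2000, 50000))
  s <- sample(0:59000, 40, TRUE)
  base <- alignment_records(sprintf("m%d", 1:40), "chr1", s,
                            s + 1500, 60, channel = 1,
                            start_time = runif(40, 0, 86400),
                            haplotype = sample(1:2, 40, TRUE),
                            phase_set = sample(c(1L, 1L, 2L), 40, TRUE))
  t1 <- as.numeric(time_to_phase(base, vars))
  extra <- alignment_records("bridge", "chr1", 0, 60000, 60, channel = 1,
                             start_time = 10, haplotype = 1, phase_set = 1)
  t2 <- as.numeric(time_to_phase(rbind(base, extra), vars))
  if (!is.na(t1)) expect_lte(t2, t1) else succeed()
})
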