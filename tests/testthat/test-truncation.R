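test_that("pool membership follows the length boundaries and dedups", {
  s <- make_sample(data.frame(
    chrom = "chr1",
    start = c(100L, 200L, 300L, 300L), end = c(126L, 227L, 329L, 329L),
    strand = "+"))
  pools <- build_pools(s)   # single-sample mode: both pools from one input
  expect_equal(width(pools$short), 27L)           # 27 nt -> short only
  expect_equal(sort(width(pools$long)), c(28L, 30L))
  ## the two byte-identical 30-mers collapse to one long-pool entry
  expect_equal(sum(width(pools$long) == 30L), 1L)
  expect_error(build_pools(s, spec = binning_spec(long_pool = c(33, 35),
                                                  short_pool = c(23, 27))),
               "long pool")
})

test_that("end deltas follow the sign and strand conventions", {
  ## plus strand: L=[101,130], S=[101,127] -> delta5 = 0, delta3 = -3
  s <- make_sample(data.frame(
    chrom = "chr1", start = c(101L, 101L), end = c(130L, 127L),
    strand = "+"))
  prof <- assign_and_profile(build_pools(s))
  expect_equal(prof$pairs$delta5, 0L)
  expect_equal(prof$pairs$delta3, -3L)
  ## minus strand: L=[101,130], S=[104,130] -> delta5 = 0, delta3 = -3
  sm <- make_sample(data.frame(
    chrom = "chr1", start = c(101L, 104L), end = c(130L, 130L),
    strand = "-"))
  profm <- assign_and_profile(build_pools(sm))
  expect_equal(profm$pairs$delta5, 0L)
  expect_equal(profm$pairs$delta3, -3L)
  ## a short alignment sticking out of the long one is unassigned when
  ## containment is required ...
  out <- make_sample(data.frame(
    chrom = "chr1", start = c(101L, 96L), end = c(130L, 120L), strand = "+"))
  p3 <- assign_and_profile(build_pools(out))
  expect_equal(p3$n_unassigned, 1L)
  expect_equal(nrow(p3$pairs), 0L)
  ## ... but pairs with a positive 5' delta in overlap mode
  p4 <- assign_and_profile(build_pools(out), contain = FALSE)
  expect_equal(p4$pairs$delta5, 5L)
  expect_equal(p4$pairs$delta3, -10L)
  expect_error(assign_and_profile(build_pools(out), contain = FALSE,
                                  all_containing = TRUE), "contained mode")
})

test_that("assignment matches exhaustive containment search", {
  set.seed(99)
  for (trial in 1:5) {
    longs <- random_alignments(120, seqlen = 3000L, width_range = c(28L, 32L))
    shorts <- random_alignments(150, seqlen = 3000L, width_range = c(23L, 27L))
    ls <- make_sample(longs); ss <- make_sample(shorts)
    pools <- build_pools(ls, ss)
    prof <- assign_and_profile(pools)
    want <- assign_bruteforce(pools$short, pools$long)
    got <- prof$pairs[order(prof$pairs$short_idx), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got[c("short_idx", "delta5", "delta3")],
                 want[c("short_idx", "delta5", "delta3")])
    ## containment mode never lengthens and tallies add up
    expect_true(all(prof$pairs$delta5 <= 0 & prof$pairs$delta3 <= 0))
    expect_equal(prof$n_assigned + prof$n_unassigned, prof$n_short)
  }
})

test_that("histograms are invariant under a genome strand flip", {
  sim <- shared_wt()
  mcfg <- small_config("mutant", seed = 45, n_reads = 2000L,
                       length_mixture = data.frame(mode = 30, weight = 1,
                                                   spread = 0),
                       trunc3_dist = c(`2` = 0.5, `4` = 0.5),
                       tail_A_rate = 0, tail_U_rate = 0,
                       pingpong_pair_frac = 0)
  mut <- simulate_reads(mcfg, sim$genome, sim$annotations)$sample
  pools <- build_pools(sim$sample, mut)
  prof <- assign_and_profile(pools)
  flip <- function(s) {
    L <- GenomeInfoDb::seqlengths(s)[as.character(seqnames(s))]
    gr <- GRanges(seqnames(s), IRanges(L - end(s) + 1L, L - start(s) + 1L),
                  strand = ifelse(as.character(strand(s)) == "+", "-", "+"),
                  seqinfo = GenomeInfoDb::seqinfo(s))
    mcols(gr) <- mcols(s)
    sample_set(gr)
  }
  proff <- assign_and_profile(build_pools(flip(sim$sample), flip(mut)))
  expect_equal(proff$hist3, prof$hist3)
  expect_equal(proff$hist5, prof$hist5)
})

test_that("the Welch routine matches the reference implementation", {
  ## worked example: equal variances and sizes
  a <- c(3, 3, 3, 4, 4); b <- c(1, 1, 2, 2, 2)
  w <- pirnakit:::welch_test(a, b)
  expect_equal(w$t, 5.196152, tolerance = 1e-6)
  expect_equal(w$df, 8)
  ## random vectors against stats::t.test at 1e-9 relative tolerance
  set.seed(123)
  for (trial in 1:10) {
    x <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    w <- pirnakit:::welch_test(x, y)
    tt <- stats::t.test(x, y)
    expect_equal(w$t, unname(tt$statistic), tolerance = 1e-9)
    expect_equal(w$df, unname(tt$parameter), tolerance = 1e-9)
    expect_equal(w$p, tt$p.value, tolerance = 1e-9)
    expect_equal(w$ci, as.numeric(tt$conf.int), tolerance = 1e-9)
  }
  ## degenerate cases t.test refuses: defined behaviour here
  z <- pirnakit:::welch_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(z$t, 0); expect_equal(z$p, 1)
  z2 <- pirnakit:::welch_test(c(3, 3, 3), c(2, 2, 2))
  expect_equal(z2$t, Inf); expect_equal(z2$p, 0)
})

test_that("identical end distributions give t = 0, p = 1", {
  ## 26-nt shorts shortened by 2 at both ends relative to their 30-nt partner
  s <- make_sample(data.frame(
    chrom = "chr1", start = c(101L, 103L, 201L, 203L),
    end = c(130L, 128L, 230L, 228L), strand = "+"))
  prof <- assign_and_profile(build_pools(s))
  expect_equal(prof$pairs$delta5, c(-2L, -2L))
  expect_equal(prof$pairs$delta3, c(-2L, -2L))
  ce <- compare_ends(prof)
  expect_equal(ce$t, 0); expect_equal(ce$p, 1)
})

test_that("pure 3' truncation is recovered and detected by the Welch test", {
  wtc <- small_config(seed = 46, n_reads = 2500L, abundance_sd = 0,
                      length_mixture = data.frame(mode = 30, weight = 1, spread = 0),
                      tail_A_rate = 0, tail_U_rate = 0, pingpong_pair_frac = 0)
  mtc <- small_config("mutant", seed = 47, n_reads = 1200L, abundance_sd = 0,
                      length_mixture = data.frame(mode = 30, weight = 1, spread = 0),
                      trunc3_dist = c(`1` = 0.1, `2` = 0.2, `3` = 0.3,
                                      `4` = 0.25, `5` = 0.15),
                      tail_A_rate = 0, tail_U_rate = 0, pingpong_pair_frac = 0)
  g <- simulate_genome(wtc)
  wt <- simulate_reads(wtc, g$genome, g$annotations)
  mt <- simulate_reads(mtc, g$genome, g$annotations)
  spec <- binning_spec(long_pool = c(30L, 32L), short_pool = c(25L, 29L))
  prof <- assign_and_profile(build_pools(wt$sample, mt$sample, spec))
  ## every short read is assigned and its delta3 equals the planted truncation
  expect_equal(prof$n_unassigned, 0L)
  want <- table(-mt$truth$trunc3)
  got <- prof$hist3
  expect_equal(got$count, as.integer(want[as.character(got$delta)]))
  expect_true(all(prof$hist5$delta == 0))
  ce <- compare_ends(prof)
  expect_lt(ce$p, 0.01)
  expect_gt(ce$ci[1], 0)
})

test_that("genotype comparison recovers deeper truncation in the mutant", {
  base <- small_config(seed = 48, n_reads = 2000L,
                       length_mixture = data.frame(mode = 30, weight = 1, spread = 0),
                       tail_A_rate = 0, tail_U_rate = 0, pingpong_pair_frac = 0)
  g <- simulate_genome(base)
  long <- simulate_reads(base, g$genome, g$annotations)
  shallow <- small_config("mutant", seed = 49, n_reads = 1000L,
                          length_mixture = data.frame(mode = 30, weight = 1, spread = 0),
                          trunc3_dist = c(`3` = 0.8, `4` = 0.2),
                          tail_A_rate = 0, tail_U_rate = 0, pingpong_pair_frac = 0)
  deep <- small_config("mutant", seed = 50, n_reads = 1000L,
                       length_mixture = data.frame(mode = 30, weight = 1, spread = 0),
                       trunc3_dist = c(`4` = 0.3, `5` = 0.7),
                       tail_A_rate = 0, tail_U_rate = 0, pingpong_pair_frac = 0)
  spec <- binning_spec(long_pool = c(30L, 32L), short_pool = c(23L, 27L))
  pa <- assign_and_profile(build_pools(long$sample,
                                       simulate_reads(shallow, g$genome, g$annotations)$sample,
                                       spec))
  pb <- assign_and_profile(build_pools(long$sample,
                                       simulate_reads(deep, g$genome, g$annotations)$sample,
                                       spec))
  self <- compare_genotypes(pa, pa)
  expect_equal(self$end3$t, 0)
  expect_true(all(self$proportion_diff$diff == 0))
  cmp <- compare_genotypes(pa, pb)
  expect_gt(cmp$end3$ci[1], 0)  # mutant B truncates deeper at the 3' end
})
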