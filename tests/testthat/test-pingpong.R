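test_that("5' overlap arithmetic matches the coordinate definition", {
  ## P = [101,130] on +, M = [86,110] on -: 5' ends at 101 and 110 -> o = 10
  s <- make_sample(data.frame(chrom = "chr1", start = c(101L, 86L),
                              end = c(130L, 110L), strand = c("+", "-")))
  h <- five_prime_overlaps(s)
  expect_equal(h$count[h$overlap == 10], 1)
  expect_equal(sum(h$count), 1)
  ## disjoint opposite-strand reads are not counted
  far <- make_sample(data.frame(chrom = "chr1", start = c(101L, 151L),
                                end = c(130L, 180L), strand = c("+", "-")))
  expect_equal(sum(five_prime_overlaps(far)$count), 0)
  ## a sample with one strand only has no pairs
  mono <- make_sample(data.frame(chrom = "chr1", start = c(101L, 111L),
                                 end = c(130L, 140L), strand = "+"))
  expect_equal(sum(five_prime_overlaps(mono)$count), 0)
  ## the overlap region must lie inside both reads
  uncovered <- make_sample(data.frame(chrom = "chr1", start = c(101L, 96L),
                                      end = c(130L, 126L), strand = c("+", "-")))
  expect_equal(sum(five_prime_overlaps(uncovered)$count), 0)
})

test_that("overlap histograms equal brute-force pair enumeration", {
  set.seed(111)
  for (trial in 1:3) {
    s <- make_sample(random_alignments(200, seqlen = 3000L,
                                       width_range = c(23L, 32L)))
    got <- five_prime_overlaps(s)
    want <- overlaps_bruteforce(s)
    expect_equal(got$count, want$count)
  }
})

test_that("the Z score standardises the focal count against the background", {
  h <- structure(data.frame(overlap = 1:20,
                            count = c(rep(8, 9), 60, rep(12, 10))),
                 class = c("OverlapHistogram", "data.frame"))
  z <- pingpong_z(h)
  ## background: nine 8s and ten 12s; frozen from the hand computation
  expect_equal(z$background_mean, 192 / 19, tolerance = 1e-12)
  expect_equal(z$z, 24.31617, tolerance = 1e-4)
  ## a focal count at the background mean scores ~0
  h2 <- h; h2$count[10] <- mean(h$count[-10])
  expect_equal(pingpong_z(h2)$z, 0, tolerance = 1e-12)
  ## z is monotone in the focal count with the background fixed
  zs <- sapply(c(20, 40, 80, 160), function(fc) {
    hh <- h; hh$count[10] <- fc; pingpong_z(hh)$z
  })
  expect_true(all(diff(zs) > 0))
  ## degenerate flat background errors instead of returning infinity
  flat <- h; flat$count <- rep(5, 20)
  expect_error(pingpong_z(flat), "degenerate")
  expect_error(pingpong_z(h, focal = 25), "window")
  expect_error(pingpong_z(h, window = 9:11), "background")
})

test_that("planting ping-pong pairs raises z monotonically", {
  set.seed(222)
  base <- make_sample(random_alignments(400, seqlen = 10000L,
                                        width_range = c(23L, 32L)))
  plant <- function(k) {
    if (k == 0) return(base)
    st <- sample.int(9000L, k)
    planted <- make_sample(data.frame(
      chrom = "chr1",
      start = c(st, st - 20L), end = c(st + 29L, st + 9L),
      strand = rep(c("+", "-"), each = k)))
    suppressWarnings(sample_set(c(granges_with_mcols(base),
                                  granges_with_mcols(planted))))
  }
  granges_with_mcols <- function(s) { S4Vectors::metadata(s) <- list(); s }
  zs <- sapply(c(0, 30, 90, 200), function(k) {
    h <- five_prime_overlaps(plant(k))
    pingpong_z(h)$z
  })
  expect_true(all(diff(zs) > 0))
})

test_that("stringent pairs demand the full orientation and base criteria", {
  si <- GenomeInfoDb::Seqinfo("chr1", 1e6)
  ann <- list(
    clusters = GRanges(seqinfo = si),
    repeats = GRanges("chr1", IRanges(c(1000, 3000), c(1200, 3200)),
                      strand = c("+", "+"), seqinfo = si),
    genes = {
      g <- GRanges("chr1", IRanges(c(5000, 5000), c(5400, 5400)),
                   strand = "+", seqinfo = si)
      g$type <- c("gene", "exon"); g$ID <- NA; g$Parent <- NA
      g$gene_id <- "g1"; g$transcript_type <- "coding"
      g
    })
  pri_seq <- paste0("T", strrep("C", 29))            # 1U, 30 nt
  sec_seq <- paste0("G", strrep("C", 8), "A", strrep("C", 16))  # 10A, 26 nt
  ## valid pair on the plus-strand repeat: sense 1U primary at 1050,
  ## antisense 10A secondary with 5' end at 1059
  valid <- data.frame(chrom = "chr1", start = c(1050L, 1034L),
                      end = c(1079L, 1059L), strand = c("+", "-"),
                      seq = c(pri_seq, sec_seq))
  got <- stringent_pairs(make_sample(valid), ann)
  expect_equal(got$n_pairs, 1L)
  expect_equal(got$pairs$primary_feature, "repeat")
  expect_equal(got$proportion_in_pairs, 1)
  ## same geometry on a minus-strand repeat: the 1U read is now antisense
  ## to the feature, so no role assignment satisfies criterion 4
  ann_minus <- ann
  strand(ann_minus$repeats) <- "-"
  none <- stringent_pairs(make_sample(valid), ann_minus)
  expect_equal(none$n_pairs, 0L)
  ## an 11-nt overlap fails the exact-overlap criterion
  off <- valid; off$start[2] <- 1035L; off$end[2] <- 1060L
  expect_equal(stringent_pairs(make_sample(off), ann)$n_pairs, 0L)
  ## base criteria: G-starting primary is rejected under the "and" rule but
  ## admitted under the literal "or" reading when the secondary still has 10A
  g_pri <- valid; g_pri$seq[1] <- paste0("G", strrep("C", 29))
  expect_equal(stringent_pairs(make_sample(g_pri), ann)$n_pairs, 0L)
  expect_equal(stringent_pairs(make_sample(g_pri), ann,
                               stringent_criteria(base_rule = "or"))$n_pairs, 1L)
})

test_that("planted stringent pairs are recovered from the generator", {
  cfg <- small_config(seed = 70, n_reads = 2000L, pingpong_pair_frac = 0.2,
                      frac_primary_1U = 1)
  g <- simulate_genome(cfg)
  sim <- simulate_reads(cfg, g$genome, g$annotations)
  sp <- stringent_pairs(sim$sample, g$annotations)
  truth <- sim$truth
  len <- nchar(sim$sample$seq)
  plen <- len[match(truth$partner_id, truth$read_id)]
  ## planted reads whose recorded partner is also piRNA-sized must all be
  ## recovered: pair loci are sense-primary on repeats and forcing 1U at the
  ## primary makes the 10-nt overlap arithmetic give the secondary its 10A
  want <- truth$read_id[!is.na(truth$partner_id) & len >= 23 & len <= 32 &
                          plen >= 23 & plen <= 32]
  got <- unique(c(sp$pairs$primary_id, sp$pairs$secondary_id))
  expect_true(all(want %in% got))
  ## every accepted planted read is itself piRNA-sized (reads sharing a pair
  ## locus may pair across emitted pairs, but never outside the size range)
  planted_got <- intersect(got, truth$read_id[!is.na(truth$partner_id)])
  expect_true(all(len[match(planted_got, truth$read_id)] >= 23 &
                    len[match(planted_got, truth$read_id)] <= 32))
  expect_equal(sp$proportion_in_pairs, length(got) / sp$n_pirna,
               tolerance = 1e-12)
})
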