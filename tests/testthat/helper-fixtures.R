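## Shared builders and independent brute-force oracles.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

## Build a SampleSet from a plain data.frame of alignments. Unless given,
## sequences are poly-T of the interval width (so every read is 1U and
## passes the piRNA length filter when its width is in range) and reference
## bases equal the sequence.
make_sample <- function(df, seqlen = 1e6L, sample_id = "test",
                        condition = NA_character_) {
  n <- nrow(df)
  if (is.null(df$seq)) df$seq <- strrep("T", df$end - df$start + 1L)
  if (is.null(df$ref)) df$ref <- df$seq
  if (is.null(df$mapq)) df$mapq <- 60L
  if (is.null(df$n_hits)) df$n_hits <- 1L
  chroms <- unique(df$chrom)
  gr <- GRanges(seqnames = df$chrom, ranges = IRanges(df$start, df$end),
                strand = df$strand,
                seqinfo = GenomeInfoDb::Seqinfo(chroms, rep(seqlen, length(chroms))))
  mcols(gr) <- S4Vectors::DataFrame(
    read_id = sprintf("t%04d", seq_len(n)), seq = df$seq,
    mapq = as.integer(df$mapq), n_hits = as.integer(df$n_hits),
    ref_bases = df$ref)
  sample_set(gr, sample_id = sample_id, condition = condition)
}

## A small, fast synthetic configuration.
small_config <- function(condition = "wild_type", seed = 1, ...) {
  args <- list(condition = condition, seed = seed, n_chroms = 2L,
               chrom_length = 2e5, n_clusters = 2L, cluster_length = 10000L,
               n_repeats = 20L, n_genes_coding = 8L, n_genes_noncoding = 4L,
               n_reads = 3000L, n_loci = 150L)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_config, args)
}

## compare interval sets without relying on S4 sort dispatch
ranges_key <- function(start, end) sort(paste(start, end))

## Cache one genome + wild-type simulation for reuse across tests.
.fixture_env <- new.env(parent = emptyenv())
shared_wt <- function() {
  if (is.null(.fixture_env$wt)) {
    cfg <- small_config(seed = 42)
    g <- simulate_genome(cfg)
    sim <- simulate_reads(cfg, g$genome, g$annotations)
    .fixture_env$wt <- list(config = cfg, genome = g$genome,
                            annotations = g$annotations,
                            sample = sim$sample, truth = sim$truth)
  }
  .fixture_env$wt
}

## O(n^2) containment scan: survivors of denesting among (start, end) pairs.
denest_bruteforce <- function(start, end) {
  dup <- duplicated(paste(start, end))
  idx <- which(!dup)
  keep <- vapply(idx, function(i) {
    contained <- start[idx] <= start[i] & end[idx] >= end[i] &
      !(start[idx] == start[i] & end[idx] == end[i])
    !any(contained)
  }, logical(1))
  sort(idx[keep])
}

## Brute-force all-pairs 5'-overlap histogram.
overlaps_bruteforce <- function(sample, o_max = 20L) {
  str <- as.character(strand(sample))
  plus <- which(str == "+"); minus <- which(str == "-")
  counts <- rep(0, o_max)
  for (i in plus) for (j in minus) {
    if (as.character(seqnames(sample))[i] != as.character(seqnames(sample))[j])
      next
    o <- end(sample)[j] - start(sample)[i] + 1L
    if (o < 1L || o > o_max) next
    if (start(sample)[j] <= start(sample)[i] && end(sample)[j] <= end(sample)[i])
      counts[o] <- counts[o] + 1
  }
  data.frame(overlap = seq_len(o_max), count = counts)
}

## Exhaustive priority-ordered annotation scan against plain interval lists.
## `tracks` is an ordered named list of data.frames (chrom, start, end).
annotate_bruteforce <- function(sample, tracks) {
  n <- length(sample)
  chrom <- as.character(seqnames(sample))
  s <- start(sample); e <- end(sample)
  out <- character(n)
  for (i in seq_len(n)) {
    cat <- "intergenic"
    for (nm in names(tracks)) {
      t <- tracks[[nm]]
      if (is.null(t) || !nrow(t)) next
      hit <- any(t$chrom == chrom[i] & t$start <= e[i] & t$end >= s[i])
      if (hit) { cat <- nm; break }
    }
    out[i] <- cat
  }
  out
}

## Brute-force assignment of short alignments to the longest containing long
## alignment (ties: smallest start, then input order).
assign_bruteforce <- function(short, long) {
  sc <- as.character(seqnames(short)); lc <- as.character(seqnames(long))
  ss <- as.character(strand(short)); ls <- as.character(strand(long))
  res <- data.frame(short_idx = integer(), long_idx = integer(),
                    delta5 = integer(), delta3 = integer())
  for (i in seq_along(short)) {
    cand <- which(lc == sc[i] & ls == ss[i] &
                    start(long) <= start(short)[i] &
                    end(long) >= end(short)[i] &
                    width(long) > width(short)[i])
    if (!length(cand)) next
    o <- order(-width(long)[cand], start(long)[cand], cand)
    j <- cand[o][1]
    if (ss[i] == "+") {
      d5 <- start(long)[j] - start(short)[i]
      d3 <- end(short)[i] - end(long)[j]
    } else {
      d5 <- end(short)[i] - end(long)[j]
      d3 <- start(long)[j] - start(short)[i]
    }
    res <- rbind(res, data.frame(short_idx = i, long_idx = j,
                                 delta5 = d5, delta3 = d3))
  }
  res
}

## Random alignments for oracle tests.
random_alignments <- function(n, seqlen = 5000L, width_range = c(20L, 35L),
                              chroms = "chr1", stranded = TRUE) {
  w <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  s <- sample.int(seqlen - max(w) - 1L, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = s, end = s + w - 1L,
             strand = if (stranded) sample(c("+", "-"), n, TRUE) else "+")
}
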