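test_that("piRNA calling applies the length window and 1U/10A features", {
  seqs <- c(
    u30 = paste0("T", strrep("C", 29)),            # 30 nt, 1U only
    short22 = paste0("T", strrep("C", 8), "A", strrep("C", 12)),  # 22 nt
    sec26 = paste0("G", strrep("C", 8), "A", strrep("C", 16)),    # 10A only
    both30 = paste0("T", strrep("C", 8), "A", strrep("C", 20))    # 1U and 10A
  )
  cls <- classify_pirna(seqs)
  expect_equal(cls$is_pirna, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(cls$is_primary, c(TRUE, NA, FALSE, TRUE))
  expect_equal(cls$is_secondary, c(FALSE, NA, TRUE, TRUE))
  ## exclusive typing resolves dual reads primary-first by default
  excl <- classify_pirna(seqs, exclusive = TRUE)
  expect_equal(excl$type, c("primary", NA, "secondary", "primary"))
  excl2 <- classify_pirna(seqs, exclusive = TRUE, precedence = "secondary")
  expect_equal(excl2$type[4], "secondary")
})

test_that("piRNA calling is a pure function of sequence and policy", {
  seq <- paste0("T", strrep("G", 25))
  s <- make_sample(data.frame(chrom = c("chr1", "chr2"),
                              start = c(100L, 9000L), end = c(125L, 9025L),
                              strand = c("+", "-"), seq = seq, ref = seq))
  cls <- classify_pirna(s)
  expect_equal(cls$is_pirna[1], cls$is_pirna[2])
  expect_equal(cls$is_primary[1], cls$is_primary[2])
  expect_equal(cls$is_secondary[1], cls$is_secondary[2])
})

## Hand-laid annotation: cluster 1000-2000, repeat 1500-1600 (inside the
## cluster) and 3000-3100 (+), coding gene 5000-6400 (+) with exons
## 5000-5199 and 6200-6399, noncoding gene 8000-8400 (-) with one exon.
toy_annotations <- function() {
  si <- GenomeInfoDb::Seqinfo("chr1", 1e6)
  clusters <- GRanges("chr1", IRanges(1000, 2000), strand = "*", seqinfo = si)
  repeats <- GRanges("chr1", IRanges(c(1500, 3000), c(1600, 3100)),
                     strand = c("+", "+"), seqinfo = si)
  mk <- function(start, end, strand, type, gid, ttype)
    GRanges("chr1", IRanges(start, end), strand = strand, type = type,
            ID = NA_character_, Parent = NA_character_, gene_id = gid,
            transcript_type = ttype, seqinfo = si)
  genes <- c(
    mk(5000, 6399, "+", "gene", "g1", "coding"),
    mk(5000, 5199, "+", "exon", "g1", "coding"),
    mk(6200, 6399, "+", "exon", "g1", "coding"),
    mk(5000, 5099, "+", "five_prime_UTR", "g1", "coding"),
    mk(5100, 5199, "+", "CDS", "g1", "coding"),
    mk(6200, 6299, "+", "CDS", "g1", "coding"),
    mk(6300, 6399, "+", "three_prime_UTR", "g1", "coding"),
    mk(8000, 8400, "-", "gene", "g2", "noncoding"),
    mk(8000, 8199, "-", "exon", "g2", "noncoding")
  )
  list(clusters = clusters, repeats = repeats, genes = genes)
}

test_that("annotation follows the exclusive priority hierarchy", {
  ann <- toy_annotations()
  s <- make_sample(data.frame(
    chrom = "chr1",
    start = c(1520L, 500L, 5150L, 2971L, 5500L, 8100L, 8250L),
    end   = c(1549L, 529L, 5179L, 3000L, 5529L, 8129L, 8279L),
    strand = c("+", "+", "-", "+", "+", "-", "+")))
  res <- annotate_reads(s, ann)
  ## cluster beats the repeat nested inside it
  expect_equal(res$category[1], "piRNA_cluster")
  ## ... but the secondary annotation of that candidate piRNA is the repeat
  expect_equal(res$secondary_category[1], "repeat")
  ## no feature at all
  expect_equal(res$category[2], "intergenic")
  ## minus read in a plus coding exon: exon_coding, antisense
  expect_equal(res$category[3], "exon_coding")
  expect_true(res$antisense[3])
  expect_equal(res$mrna_subtype[3], "CDS")
  ## 1-bp overlap with the repeat edge counts
  expect_equal(res$category[4], "repeat")
  ## intron of the coding gene
  expect_equal(res$category[5], "intron")
  ## sense read in the noncoding exon
  expect_equal(res$category[6], "exon_noncoding")
  expect_false(res$antisense[6])
  ## intron of the noncoding gene, antisense to the minus-strand gene
  expect_equal(res$category[7], "intron")
  expect_true(res$antisense[7])
})

test_that("annotation matches an exhaustive priority-ordered scan", {
  set.seed(31)
  for (trial in 1:5) {
    ## random small feature sets (about 40-200 features)
    n_cl <- sample(2:5, 1); n_rp <- sample(10:40, 1); n_gene <- sample(3:8, 1)
    si <- GenomeInfoDb::Seqinfo("chr1", 1e5)
    rint <- function(n, w) {
      s <- sample.int(9e4, n)
      GRanges("chr1", IRanges(s, s + w - 1L),
              strand = sample(c("+", "-"), n, TRUE), seqinfo = si)
    }
    clusters <- rint(n_cl, 3000L); strand(clusters) <- "*"
    repeats <- rint(n_rp, 200L)
    glist <- list()
    for (i in seq_len(n_gene)) {
      gs <- sample.int(8e4, 1); glen <- 2000L
      ttype <- sample(c("coding", "noncoding"), 1)
      strand <- sample(c("+", "-"), 1)
      gid <- paste0("g", i)
      ex1 <- IRanges(gs, gs + 299L); ex2 <- IRanges(gs + 1500L, gs + 1999L)
      mk <- function(r, type) GRanges("chr1", r, strand = strand, type = type,
                                      ID = NA_character_, Parent = NA_character_,
                                      gene_id = gid, transcript_type = ttype,
                                      seqinfo = si)
      glist[[length(glist) + 1]] <- c(mk(IRanges(gs, gs + glen - 1L), "gene"),
                                      mk(ex1, "exon"), mk(ex2, "exon"))
    }
    genes <- do.call(c, glist)
    ann <- list(clusters = clusters, repeats = repeats, genes = genes)

    reads <- make_sample(random_alignments(300, seqlen = 1e5), seqlen = 1e5)
    got <- annotate_reads(reads, ann)

    ## oracle: plain data.frame scan with independently derived introns
    to_df <- function(gr) data.frame(chrom = as.character(seqnames(gr)),
                                     start = start(gr), end = end(gr))
    intr <- lapply(unique(genes$gene_id), function(gid) {
      sub <- genes[genes$gene_id == gid]
      BiocGenerics::setdiff(ranges(sub[sub$type == "gene"]),
                            ranges(sub[sub$type == "exon"]))
    })
    intr <- do.call(c, intr)
    ex <- genes[genes$type == "exon"]
    tracks <- list(
      piRNA_cluster = to_df(clusters),
      `repeat` = to_df(repeats),
      exon_coding = to_df(ex[ex$transcript_type == "coding"]),
      exon_noncoding = to_df(ex[ex$transcript_type == "noncoding"]),
      intron = data.frame(chrom = "chr1", start = start(intr), end = end(intr))
    )
    want <- annotate_bruteforce(reads, tracks)
    expect_equal(got$category, want)
    ## exclusivity: exactly one category each, percentages sum to 100
    expect_true(all(got$category %in% c(names(tracks), "intergenic")))
    summ <- summarize_categories(reads, ann)
    expect_equal(sum(summ$categories$percent), 100, tolerance = 1e-9)
    expect_equal(sum(summ$secondary_categories$percent), 100, tolerance = 1e-9)
  }
})

test_that("interval partitioning reports fractions of size-selected reads", {
  s <- make_sample(data.frame(chrom = "chr1", start = (1:10) * 1000L,
                              end = (1:10) * 1000L + 29L, strand = "+"))
  hits <- GRanges("chr1", IRanges(c(1000, 2000), c(1029, 2029)))
  p <- partition_by_intervals(s, hits)
  expect_equal(p$n_overlap, 2L)
  expect_equal(p$percent, 20)
  everything <- GRanges("chr1", IRanges(1, 1e6))
  expect_equal(partition_by_intervals(s, everything)$percent, 100)
  expect_equal(partition_by_intervals(s, GRanges())$percent, 0)
  ## partition feeds downstream analyses: the subset's length profile equals
  ## direct filtering
  sub <- p$reads
  ld <- length_distribution(sub)
  expect_equal(sum(ld$count), 2L)
  expect_equal(ld$count[ld$length == 30], 2L)
})

test_that("category summaries agree with generator ground truth", {
  sim <- shared_wt()
  summ <- summarize_categories(sim$sample, sim$annotations)
  truth_cat <- ifelse(sim$truth$category == "cluster", "piRNA_cluster",
                      sim$truth$category)
  want <- table(factor(truth_cat, levels = summ$categories$category))
  expect_equal(summ$categories$count, as.integer(want))
  expect_equal(sum(summ$categories$percent), 100, tolerance = 1e-9)
  expect_equal(summ$percent_in_clusters,
               100 * mean(truth_cat == "piRNA_cluster"))
  expect_error(summarize_categories(sim$sample[0], sim$annotations), "empty")
})
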