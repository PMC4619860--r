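## piRNA calling and exclusive hierarchical genomic annotation.

ANNOTATION_PRIORITY <- c("piRNA_cluster", "repeat", "exon_coding",
                         "exon_noncoding", "intron", "intergenic")

#' Call piRNAs by length and 1U/10A sequence features
#'
#' A read is a piRNA when its length lies within the policy bounds (23--32 nt
#' by default). Primary piRNAs carry U at read position 1, secondary piRNAs
#' carry A at read position 10; positions are 1-based in read space (5'->3'
#' of the RNA, so position 1 is the 5' base regardless of genomic strand).
#' A read may be both primary and secondary; both flags are retained, and an
#' exclusive assignment for ratio reporting is available via
#' `exclusive = TRUE` (primary takes precedence, configurable).
#'
#' @param sample A SampleSet, or a character vector of read sequences.
#' @param policy A [filter_policy()] supplying the length bounds.
#' @param exclusive If `TRUE`, adds a `type` column with a single label per
#'   piRNA read (`primary`, `secondary` or `other`).
#' @param precedence Which flag wins for dual 1U+10A reads under
#'   `exclusive = TRUE`.
#' @return A data.frame with columns `read_id`, `length`, `is_pirna`,
#'   `is_primary`, `is_secondary` (the base flags are `NA` for non-piRNA
#'   reads).
#' @export
classify_pirna <- function(sample, policy = filter_policy(), exclusive = FALSE,
                           precedence = c("primary", "secondary")) {
  precedence <- match.arg(precedence)
  if (is.character(sample)) {
    seqs <- sample
    ids <- if (!is.null(names(sample))) names(sample) else as.character(seq_along(sample))
  } else {
    seqs <- sample$seq
    ids <- sample$read_id
  }
  len <- nchar(seqs)
  is_pirna <- len >= policy$pirna_min_len & len <= policy$pirna_max_len
  p1 <- substr(seqs, 1L, 1L) == "T"
  p10 <- len >= 10L & substr(seqs, 10L, 10L) == "A"
  out <- data.frame(read_id = ids, length = len, is_pirna = is_pirna,
                    is_primary = ifelse(is_pirna, p1, NA),
                    is_secondary = ifelse(is_pirna, p10, NA))
  if (exclusive) {
    type <- rep(NA_character_, length(len))
    pri <- out$is_pirna & out$is_primary
    sec <- out$is_pirna & out$is_secondary
    type[out$is_pirna] <- "other"
    if (precedence == "primary") {
      type[sec] <- "secondary"; type[pri] <- "primary"
    } else {
      type[pri] <- "primary"; type[sec] <- "secondary"
    }
    out$type <- type
  }
  out
}

## Build the ordered list of annotation feature sets from the annotation list.
annotation_tracks <- function(annotations) {
  genes <- annotations$genes
  ex <- genes[genes$type == "exon"]
  list(
    piRNA_cluster = GenomicRanges::granges(annotations$clusters, use.mcols = FALSE),
    `repeat` = GenomicRanges::granges(annotations$repeats, use.mcols = FALSE),
    exon_coding = GenomicRanges::granges(ex[ex$transcript_type == "coding"]),
    exon_noncoding = GenomicRanges::granges(ex[ex$transcript_type == "noncoding"]),
    intron = intron_ranges(genes)
  )
}

#' Annotate reads against a feature hierarchy
#'
#' Each read receives exactly one category: the highest-priority feature set
#' it overlaps by at least 1 bp, in the order piRNA cluster > repeat > coding
#' exon > non-coding exon > intron; reads overlapping nothing are intergenic.
#' Reads landing in piRNA clusters (candidate piRNAs) are additionally
#' re-classified against the remaining sets, giving a secondary category, and
#' candidate piRNAs over coding exons receive an mRNA subtype (5'UTR / CDS /
#' 3'UTR) by sub-feature overlap. A read is antisense when the feature that
#' decides its (secondary) category is stranded and opposite to the read;
#' among equal-priority features the one with the largest overlap decides,
#' and ties resolve to sense.
#'
#' @param sample A SampleSet (any stranded `GRanges` works).
#' @param annotations `list(clusters, repeats, genes)` as produced by
#'   [simulate_genome()] or [load_annotations()].
#' @return A data.frame with columns `read_id`, `category`,
#'   `secondary_category` (non-cluster category of cluster reads, else equal
#'   to `category`), `antisense`, `mrna_subtype`.
#' @export
annotate_reads <- function(sample, annotations) {
  tracks <- annotation_tracks(annotations)
  n <- length(sample)
  category <- rep("intergenic", n)
  hit_idx <- rep(NA_integer_, n)   # index into the winning track
  hit_track <- rep(NA_character_, n)

  assign_priority <- function(mask, skip_cluster = FALSE) {
    cat <- rep("intergenic", n)
    idx <- rep(NA_integer_, n)
    trk <- rep(NA_character_, n)
    remaining <- mask
    order <- if (skip_cluster) setdiff(names(tracks), "piRNA_cluster") else names(tracks)
    for (nm in order) {
      if (!any(remaining)) break
      f <- tracks[[nm]]
      if (!length(f)) next
      ov <- GenomicRanges::findOverlaps(sample, f, minoverlap = 1L,
                                        ignore.strand = TRUE)
      qh <- S4Vectors::queryHits(ov)
      hit <- remaining & seq_len(n) %in% qh
      if (!any(hit)) next
      ## per hit read, pick the feature with the largest overlap (ties: keep
      ## a sense feature if any tie includes one)
      sub <- ov[remaining[qh]]
      qs <- S4Vectors::queryHits(sub); ss <- S4Vectors::subjectHits(sub)
      w <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(sample)[qs], IRanges::ranges(f)[ss]))
      fstr <- as.character(GenomicRanges::strand(f))[ss]
      rstr <- as.character(GenomicRanges::strand(sample))[qs]
      sense <- fstr == "*" | fstr == rstr
      ord <- order(qs, -w, -sense)
      first <- !duplicated(qs[ord])
      sel_q <- qs[ord][first]; sel_s <- ss[ord][first]
      cat[sel_q] <- nm
      idx[sel_q] <- sel_s
      trk[sel_q] <- nm
      remaining[sel_q] <- FALSE
    }
    list(category = cat, idx = idx, track = trk)
  }

  all_mask <- rep(TRUE, n)
  top <- assign_priority(all_mask, skip_cluster = FALSE)
  category <- top$category

  ## candidate piRNAs (cluster reads) are re-classified against the rest
  in_cluster <- category == "piRNA_cluster"
  secondary <- category
  sec_idx <- top$idx; sec_trk <- top$track
  if (any(in_cluster)) {
    re <- assign_priority(in_cluster, skip_cluster = TRUE)
    secondary[in_cluster] <- re$category[in_cluster]
    sec_idx[in_cluster] <- re$idx[in_cluster]
    sec_trk[in_cluster] <- re$track[in_cluster]
  }

  ## antisense relative to the feature that decided the (secondary) category
  antisense <- rep(FALSE, n)
  decided <- !is.na(sec_trk)
  if (any(decided)) {
    fstr <- rep("*", n)
    for (nm in unique(sec_trk[decided])) {
      m <- decided & sec_trk == nm
      fstr[m] <- as.character(GenomicRanges::strand(tracks[[nm]]))[sec_idx[m]]
    }
    stranded <- fstr %in% c("+", "-")
    antisense[decided & stranded] <-
      fstr[decided & stranded] !=
      as.character(GenomicRanges::strand(sample))[decided & stranded]
  }

  ## mRNA subtype for reads whose (secondary) category is a coding exon
  mrna_subtype <- rep("none", n)
  coding <- secondary == "exon_coding"
  if (any(coding)) {
    genes <- annotations$genes
    subfeat <- list(`5'UTR` = genes[genes$type == "five_prime_UTR"],
                    CDS = genes[genes$type == "CDS"],
                    `3'UTR` = genes[genes$type == "three_prime_UTR"])
    best_w <- rep(0L, n)
    for (nm in names(subfeat)) {
      f <- subfeat[[nm]]
      if (!length(f)) next
      ov <- GenomicRanges::findOverlaps(sample, f, minoverlap = 1L,
                                        ignore.strand = TRUE)
      qs <- S4Vectors::queryHits(ov); ss <- S4Vectors::subjectHits(ov)
      keep <- coding[qs]
      qs <- qs[keep]; ss <- ss[keep]
      if (!length(qs)) next
      w <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(sample)[qs], IRanges::ranges(f)[ss]))
      agg <- tapply(w, qs, max)
      ids <- as.integer(names(agg))
      better <- agg > best_w[ids]
      mrna_subtype[ids[better]] <- nm
      best_w[ids[better]] <- agg[better]
    }
  }

  data.frame(read_id = sample$read_id, category = category,
             secondary_category = secondary, antisense = antisense,
             mrna_subtype = mrna_subtype)
}

#' Partition reads by an interval set
#'
#' Returns the reads overlapping an interval set (for example HITS-CLIP
#' derived MILI- or MIWI-bound coordinates) by at least 1 bp, together with
#' their percentage of the sample's size-selected (piRNA length) reads.
#'
#' @param sample A SampleSet.
#' @param intervals A `GRanges` interval set.
#' @param label Label attached to the result.
#' @param policy A [filter_policy()] defining the size-selected denominator.
#' @return `list(reads, label, n_overlap, n_size_selected, percent)`.
#' @export
partition_by_intervals <- function(sample, intervals, label = "partition",
                                   policy = filter_policy()) {
  sized <- pirna_reads(sample, policy)
  if (length(intervals) == 0L) {
    return(list(reads = sized[0], label = label, n_overlap = 0L,
                n_size_selected = length(sized), percent = 0))
  }
  hit <- IRanges::overlapsAny(sized, intervals, minoverlap = 1L,
                              ignore.strand = TRUE)
  list(reads = sized[hit], label = label, n_overlap = sum(hit),
       n_size_selected = length(sized),
       percent = if (length(sized)) 100 * sum(hit) / length(sized) else 0)
}

#' Summarise annotation categories and piRNA criteria over a sample
#'
#' @param sample A SampleSet.
#' @param annotations Annotation list; see [annotate_reads()].
#' @param policy A [filter_policy()].
#' @return `list(categories = data.frame(category, count, percent),
#'   secondary_categories, percent_in_clusters, percent_meeting_criteria,
#'   n_reads)`. Percentages are over all retained reads and sum to 100.
#' @export
summarize_categories <- function(sample, annotations, policy = filter_policy()) {
  if (length(sample) == 0L) stop("empty sample")
  ann <- annotate_reads(sample, annotations)
  tab <- function(x) {
    cnt <- table(factor(x, levels = ANNOTATION_PRIORITY))
    data.frame(category = names(cnt), count = as.integer(cnt),
               percent = 100 * as.integer(cnt) / length(x))
  }
  cls <- classify_pirna(sample, policy)
  list(categories = tab(ann$category),
       secondary_categories = tab(ann$secondary_category),
       percent_in_clusters = 100 * mean(ann$category == "piRNA_cluster"),
       percent_meeting_criteria = 100 * mean(cls$is_pirna),
       n_reads = length(sample))
}
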