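#' Alignment retention and piRNA definition policy
#'
#' A `FilterPolicy` bundles the thresholds that decide which alignments enter
#' an analysis and which read lengths count as piRNAs. The defaults encode the
#' usual working definition for mouse germ-cell libraries: piRNAs are 23--32 nt,
#' reads reported with more than 3 alignments are discarded, and no mapping
#' quality floor is imposed.
#'
#' @param pirna_min_len,pirna_max_len Inclusive read-length bounds (nt) for a
#'   read to be called a piRNA.
#' @param min_mapq Minimum mapping quality; alignments below it are dropped.
#' @param max_hits Maximum reported alignment count (`NH` tag or equivalent)
#'   for a read to be retained.
#' @param require_aligned_3prime If `TRUE`, reads whose 3'-terminal base is not
#'   aligned to the reference (soft-clipped) are excluded from 3'-end
#'   modification analysis rather than resolved against the adjacent genomic
#'   base.
#' @return An object of class `FilterPolicy`.
#' @examples
#' filter_policy()
#' filter_policy(min_mapq = 10)
#' @export
filter_policy <- function(pirna_min_len = 23L, pirna_max_len = 32L,
                          min_mapq = 0L, max_hits = 3L,
                          require_aligned_3prime = TRUE) {
  pirna_min_len <- as.integer(pirna_min_len)
  pirna_max_len <- as.integer(pirna_max_len)
  min_mapq <- as.integer(min_mapq)
  max_hits <- as.integer(max_hits)
  stopifnot(pirna_min_len <= pirna_max_len, max_hits >= 1L, min_mapq >= 0L,
            is.logical(require_aligned_3prime), length(require_aligned_3prime) == 1L)
  structure(
    list(pirna_min_len = pirna_min_len, pirna_max_len = pirna_max_len,
         min_mapq = min_mapq, max_hits = max_hits,
         require_aligned_3prime = require_aligned_3prime),
    class = "FilterPolicy"
  )
}

#' @export
print.FilterPolicy <- function(x, ...) {
  cat("FilterPolicy: piRNA length", x$pirna_min_len, "-", x$pirna_max_len,
      "nt; min mapq", x$min_mapq, "; max hits", x$max_hits,
      "; require aligned 3' end:", x$require_aligned_3prime, "\n")
  invisible(x)
}

#' Construct a sample of aligned small RNA reads
#'
#' A sample is represented as a [GenomicRanges::GRanges] whose ranges are the
#' genomic spans of the alignments (1-based, closed, the native Bioconductor
#' convention) and whose metadata columns carry the read-space information:
#'
#' * `read_id`: read identifier,
#' * `seq`: the read sequence 5'->3' of the sequenced RNA (for minus-strand
#'   alignments this is the reverse complement of the SAM `SEQ` field),
#' * `mapq`: mapping quality,
#' * `n_hits`: reported alignment count for the read,
#' * `ref_bases`: reference bases over the aligned span, in read orientation,
#'   with `"."` at read positions that are not aligned (soft-clipped or
#'   inserted bases).
#'
#' Sample-level labels (`sample_id`, `condition`, `cell_type`, `replicate`)
#' and the ingestion filter tally live in `S4Vectors::metadata()`.
#'
#' @param reads A `GRanges` with the metadata columns listed above, strand
#'   `+` or `-` for every alignment.
#' @param sample_id,condition,cell_type,replicate Sample labels.
#' @param filter_tally Named integer vector of reads dropped at ingestion,
#'   by reason.
#' @return A validated `GRanges` ("SampleSet").
#' @export
sample_set <- function(reads, sample_id = "sample", condition = NA_character_,
                       cell_type = NA_character_, replicate = 1L,
                       filter_tally = integer()) {
  reads <- validate_sample_set(reads)
  S4Vectors::metadata(reads) <- list(
    sample_id = sample_id, condition = condition, cell_type = cell_type,
    replicate = as.integer(replicate), filter_tally = filter_tally
  )
  reads
}

validate_sample_set <- function(reads) {
  stopifnot(methods::is(reads, "GRanges"))
  need <- c("read_id", "seq", "mapq", "n_hits", "ref_bases")
  missing <- setdiff(need, colnames(S4Vectors::mcols(reads)))
  if (length(missing))
    stop("SampleSet is missing metadata column(s): ", paste(missing, collapse = ", "))
  if (length(reads)) {
    if (any(!as.character(GenomicRanges::strand(reads)) %in% c("+", "-")))
      stop("every alignment must be stranded (+/-)")
    if (any(nchar(reads$seq) < 1L)) stop("empty read sequence")
    if (any(nchar(reads$ref_bases) != nchar(reads$seq)))
      stop("ref_bases must have one character per read base ('.' where unaligned)")
  }
  reads
}

#' Genomic 5' end position of each alignment
#'
#' The 5' end of a plus-strand alignment is its leftmost genomic position; for
#' a minus-strand alignment it is the rightmost. Because truncation of piRNAs
#' proceeds from the 3' end, the 5' position is invariant under 3' shortening
#' and is used throughout as a proxy key for the piRNA family/locus.
#'
#' @param reads A SampleSet `GRanges` (or any stranded `GRanges`).
#' @return Integer vector of 1-based genomic positions.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 130), strand = "+")
#' five_prime(gr)  # 101
#' @export
five_prime <- function(reads) {
  s <- as.character(GenomicRanges::strand(reads))
  if (any(!s %in% c("+", "-"))) stop("five_prime() requires stranded alignments")
  ifelse(s == "+", GenomicRanges::start(reads), GenomicRanges::end(reads))
}

#' Re-apply an alignment retention policy to a sample
#'
#' Drops alignments failing the mapping-quality or hit-count thresholds.
#' Idempotent: applying the same policy twice changes nothing. piRNA length
#' bounds are deliberately not applied here -- they select reads within
#' analyses, not membership in the sample.
#'
#' @param sample A SampleSet.
#' @param policy A [filter_policy()].
#' @return The filtered SampleSet; the metadata filter tally is extended.
#' @export
apply_filter_policy <- function(sample, policy = filter_policy()) {
  stopifnot(inherits(policy, "FilterPolicy"))
  low_mapq <- sample$mapq < policy$min_mapq
  many_hits <- sample$n_hits > policy$max_hits
  keep <- !(low_mapq | many_hits)
  tally <- c(low_mapq = sum(low_mapq), too_many_hits = sum(many_hits & !low_mapq))
  out <- sample[keep]
  md <- S4Vectors::metadata(sample)
  md$filter_tally <- merge_tallies(md$filter_tally, tally)
  S4Vectors::metadata(out) <- md
  out
}

merge_tallies <- function(a, b) {
  if (is.null(a)) a <- integer()
  for (nm in names(b)) a[nm] <- (if (nm %in% names(a)) a[[nm]] else 0L) + b[[nm]]
  a
}

#' Select the reads meeting the piRNA length definition
#'
#' @param sample A SampleSet.
#' @param policy A [filter_policy()] supplying the length bounds.
#' @return The subset of reads whose sequence length lies in
#'   `[pirna_min_len, pirna_max_len]`.
#' @export
pirna_reads <- function(sample, policy = filter_policy()) {
  len <- nchar(sample$seq)
  sample[len >= policy$pirna_min_len & len <= policy$pirna_max_len]
}

#' @noRd
sample_label <- function(sample, what) {
  md <- S4Vectors::metadata(sample)
  v <- md[[what]]
  if (is.null(v)) NA_character_ else v
}
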