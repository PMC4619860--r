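## Opposite-strand 5'-overlap (ping-pong) signature statistics.

#' Histogram of opposite-strand 5' overlap lengths
#'
#' For a plus-strand read P and a minus-strand read M on the same chromosome
#' the 5'-to-5' span is `o = end(M) - start(P) + 1` (the number of bases from
#' P's 5' end to M's 5' end inclusive). A pair is counted when `1 <= o <=
#' o_max` and the overlap region is covered by both reads, i.e. `start(M) <=
#' start(P)` and `end(M) <= end(P)`. Each unordered pair contributes once;
#' ping-pong amplification produces an excess at `o = 10`.
#'
#' @param sample A SampleSet.
#' @param o_max Largest overlap length tallied (>= 10).
#' @param policy A [filter_policy()]; reads are size-selected to the piRNA
#'   length range before pairing (disable with `size_select = FALSE`).
#' @param size_select Apply the piRNA length filter first.
#' @param weight_by_hits If `TRUE`, each pair contributes
#'   `1 / (n_hits_P * n_hits_M)` instead of 1, down-weighting multi-mapped
#'   reads.
#' @return An object of class `OverlapHistogram`: data.frame with `overlap`
#'   (1..`o_max`) and `count`.
#' @export
five_prime_overlaps <- function(sample, o_max = 20L, policy = filter_policy(),
                                size_select = TRUE, weight_by_hits = FALSE) {
  o_max <- as.integer(o_max)
  if (o_max < 10L) stop("o_max must be at least the focal overlap of 10")
  reads <- if (size_select) pirna_reads(sample, policy) else sample
  str <- as.character(GenomicRanges::strand(reads))
  plus <- reads[str == "+"]
  minus <- reads[str == "-"]
  counts <- rep(0, o_max)
  if (length(plus) && length(minus)) {
    ov <- GenomicRanges::findOverlaps(plus, minus, minoverlap = 1L,
                                      ignore.strand = TRUE)
    qs <- S4Vectors::queryHits(ov); ss <- S4Vectors::subjectHits(ov)
    o <- GenomicRanges::end(minus)[ss] - GenomicRanges::start(plus)[qs] + 1L
    covered <- GenomicRanges::start(minus)[ss] <= GenomicRanges::start(plus)[qs] &
      GenomicRanges::end(minus)[ss] <= GenomicRanges::end(plus)[qs]
    keep <- covered & o >= 1L & o <= o_max
    o <- o[keep]
    w <- if (weight_by_hits)
      1 / (plus$n_hits[qs[keep]] * minus$n_hits[ss[keep]]) else rep(1, length(o))
    if (length(o)) {
      agg <- tapply(w, factor(o, levels = seq_len(o_max)), sum)
      counts <- ifelse(is.na(agg), 0, agg)
    }
  }
  structure(data.frame(overlap = seq_len(o_max), count = as.numeric(counts)),
            class = c("OverlapHistogram", "data.frame"))
}

#' Ping-pong Z score at the focal overlap length
#'
#' Standardised excess of the focal overlap count (default 10 nt, the
#' ping-pong signature) over the background of the other overlap lengths in
#' the window: `z = (count[focal] - mean(background)) / sd(background)` with
#' the sample (n-1) standard deviation.
#'
#' @param hist An [five_prime_overlaps()] histogram.
#' @param focal Focal overlap length (default 10).
#' @param window Overlap lengths forming the analysis window (default 1..20);
#'   the background is the window minus the focal length and must contain at
#'   least 3 lengths with positive spread.
#' @return An object of class `PingPongResult`: `list(z, focal, focal_count,
#'   background_mean, background_sd, window, histogram)`.
#' @export
pingpong_z <- function(hist, focal = 10L, window = 1:20) {
  stopifnot(inherits(hist, "OverlapHistogram") ||
              all(c("overlap", "count") %in% names(hist)))
  if (!focal %in% window) stop("window must contain the focal overlap length")
  if (!all(window %in% hist$overlap))
    stop("histogram does not cover the requested window")
  bg_lens <- setdiff(window, focal)
  if (length(bg_lens) < 3L) stop("need at least 3 background overlap lengths")
  bg <- hist$count[match(bg_lens, hist$overlap)]
  fc <- hist$count[match(focal, hist$overlap)]
  s <- stats::sd(bg)
  if (s == 0)
    stop("degenerate background: zero variance across background overlap lengths")
  structure(list(z = (fc - mean(bg)) / s, focal = as.integer(focal),
                 focal_count = fc, background_mean = mean(bg),
                 background_sd = s, window = window, histogram = hist),
            class = "PingPongResult")
}

#' @export
print.PingPongResult <- function(x, ...) {
  cat(sprintf("Ping-pong Z at %d-nt 5' overlap: %.3f (focal %.0f vs background %.2f +/- %.2f)\n",
              x$focal, x$z, x$focal_count, x$background_mean, x$background_sd))
  invisible(x)
}

#' Criteria for stringent ping-pong pair calling
#'
#' @param min_len,max_len Size range for both members of a pair.
#' @param overlap Required exact 5' overlap (10 nt).
#' @param base_rule `"and"`: the primary must carry 1U and the secondary 10A;
#'   `"or"`: either condition admits the pair.
#' @return An object of class `StringentPairCriteria`.
#' @export
stringent_criteria <- function(min_len = 23L, max_len = 32L, overlap = 10L,
                               base_rule = c("and", "or")) {
  base_rule <- match.arg(base_rule)
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 overlap = as.integer(overlap), base_rule = base_rule),
            class = "StringentPairCriteria")
}

#' Stringent ping-pong pair calling
#'
#' Emits opposite-strand read pairs satisfying all of: both reads within the
#' size range; an exact 10-nt 5' overlap; the primary carrying U at position
#' 1 and the secondary A at position 10 (conjunction by default, see
#' [stringent_criteria()]); and the primary mapped sense -- the secondary
#' antisense -- to a repeat or a protein-coding exon. Within an
#' opposite-strand pair either read may take the primary role; a pair is
#' accepted if some role assignment satisfies every criterion.
#'
#' @param sample A SampleSet.
#' @param annotations Annotation list; see [annotate_reads()].
#' @param criteria A [stringent_criteria()].
#' @param policy A [filter_policy()].
#' @return `list(pairs, n_pairs, n_pirna, proportion_in_pairs,
#'   by_feature)`: `pairs` has primary/secondary read ids and the feature
#'   class (`repeat` or `gene`) of each role; `proportion_in_pairs` is the
#'   fraction of piRNA reads participating in at least one accepted pair;
#'   `by_feature` reports the primary/secondary splits over repeats and
#'   protein-coding genes as fractions of all piRNAs.
#' @export
stringent_pairs <- function(sample, annotations,
                            criteria = stringent_criteria(),
                            policy = filter_policy()) {
  if (is.null(annotations$repeats) || is.null(annotations$genes))
    stop("repeat and gene annotation tracks are required")
  len <- nchar(sample$seq)
  reads <- sample[len >= criteria$min_len & len <= criteria$max_len]
  n_pirna <- length(reads)
  if (n_pirna == 0L)
    return(list(pairs = data.frame(), n_pairs = 0L, n_pirna = 0L,
                proportion_in_pairs = 0, by_feature = NULL))

  rep_track <- GenomicRanges::granges(annotations$repeats, use.mcols = FALSE)
  genes <- annotations$genes
  gene_track <- GenomicRanges::granges(
    genes[genes$type == "exon" & genes$transcript_type == "coding"])

  sense_hit <- function(track) {
    if (!length(track)) return(list(sense = logical(length(reads)),
                                    anti = logical(length(reads))))
    ov <- GenomicRanges::findOverlaps(reads, track, minoverlap = 1L,
                                      ignore.strand = TRUE)
    qs <- S4Vectors::queryHits(ov); ss <- S4Vectors::subjectHits(ov)
    fs <- as.character(GenomicRanges::strand(track))[ss]
    rs <- as.character(GenomicRanges::strand(reads))[qs]
    sense <- logical(length(reads)); anti <- logical(length(reads))
    same <- fs == "*" | fs == rs
    sense[unique(qs[same])] <- TRUE
    anti[unique(qs[!same & fs != "*"])] <- TRUE
    list(sense = sense, anti = anti)
  }
  hr <- sense_hit(rep_track); hg <- sense_hit(gene_track)
  sense_any <- hr$sense | hg$sense
  anti_any <- hr$anti | hg$anti

  is_1U <- substr(reads$seq, 1L, 1L) == "T"
  is_10A <- nchar(reads$seq) >= 10L & substr(reads$seq, 10L, 10L) == "A"

  str <- as.character(GenomicRanges::strand(reads))
  plus <- which(str == "+"); minus <- which(str == "-")
  pairs <- NULL
  if (length(plus) && length(minus)) {
    ov <- GenomicRanges::findOverlaps(reads[plus], reads[minus],
                                      minoverlap = 1L, ignore.strand = TRUE)
    qs <- plus[S4Vectors::queryHits(ov)]; ss <- minus[S4Vectors::subjectHits(ov)]
    o <- GenomicRanges::end(reads)[ss] - GenomicRanges::start(reads)[qs] + 1L
    covered <- GenomicRanges::start(reads)[ss] <= GenomicRanges::start(reads)[qs] &
      GenomicRanges::end(reads)[ss] <= GenomicRanges::end(reads)[qs]
    keep <- covered & o == criteria$overlap
    qs <- qs[keep]; ss <- ss[keep]
    admit <- function(pri, sec) {
      base_ok <- if (criteria$base_rule == "and") is_1U[pri] & is_10A[sec]
                 else is_1U[pri] | is_10A[sec]
      base_ok & sense_any[pri] & anti_any[sec]
    }
    ## either member may take the primary role
    a <- admit(qs, ss); b <- admit(ss, qs)
    pri <- c(qs[a], ss[b]); sec <- c(ss[a], qs[b])
    if (length(pri)) {
      feat_of <- function(i) ifelse(hr$sense[i] | hr$anti[i], "repeat", "gene")
      pairs <- data.frame(
        primary_id = reads$read_id[pri], secondary_id = reads$read_id[sec],
        primary_feature = ifelse(hr$sense[pri], "repeat", "gene"),
        secondary_feature = ifelse(hr$anti[sec], "repeat", "gene"))
      pairs <- pairs[!duplicated(pairs[c("primary_id", "secondary_id")]), ]
    }
  }
  if (is.null(pairs))
    pairs <- data.frame(primary_id = character(), secondary_id = character(),
                        primary_feature = character(),
                        secondary_feature = character())
  involved <- unique(c(pairs$primary_id, pairs$secondary_id))
  ## distinct reads per role and feature class, as fractions of all piRNAs
  n_distinct <- function(ids) length(unique(ids))
  by_feature <- data.frame(
    feature = rep(c("repeat", "gene"), each = 2),
    role = rep(c("primary", "secondary"), 2),
    n = c(n_distinct(pairs$primary_id[pairs$primary_feature == "repeat"]),
          n_distinct(pairs$secondary_id[pairs$secondary_feature == "repeat"]),
          n_distinct(pairs$primary_id[pairs$primary_feature == "gene"]),
          n_distinct(pairs$secondary_id[pairs$secondary_feature == "gene"])))
  by_feature$fraction_of_pirnas <- by_feature$n / n_pirna
  list(pairs = pairs, n_pairs = nrow(pairs), n_pirna = n_pirna,
       proportion_in_pairs = length(involved) / n_pirna,
       by_feature = by_feature)
}
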