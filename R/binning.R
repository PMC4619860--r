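## Genome-binned, length-stratified piRNA expression with interval denesting.

#' Specification for binned expression profiling
#'
#' @param bin_size Genomic bin size in bases (default 10 Mbp).
#' @param length_min,length_max Read-length stratification range (nt).
#' @param long_pool,short_pool Inclusive length ranges `(min, max)` summed as
#'   the long (default 28--32 nt, MIWI-sized) and short (default 23--27 nt,
#'   MILI-sized) piRNA pools; the pools must be disjoint.
#' @param denest If `TRUE`, unique 5' ends are counted only over alignments
#'   not fully encompassed by another alignment.
#' @param per_bp If `TRUE`, per-base-pair normalised counts are emitted; the
#'   final partial bin of each chromosome is normalised by its actual width.
#' @return An object of class `BinningSpec`.
#' @export
binning_spec <- function(bin_size = 1e7, length_min = 20L, length_max = 35L,
                         long_pool = c(28L, 32L), short_pool = c(23L, 27L),
                         denest = FALSE, per_bp = TRUE) {
  bin_size <- as.numeric(bin_size)
  if (bin_size <= 0) stop("bin_size must be positive")
  stopifnot(length_min <= length_max,
            long_pool[1] <= long_pool[2], short_pool[1] <= short_pool[2],
            long_pool[1] >= length_min, long_pool[2] <= length_max,
            short_pool[1] >= length_min, short_pool[2] <= length_max)
  if (short_pool[2] >= long_pool[1] && long_pool[2] >= short_pool[1])
    stop("long and short pools must be disjoint")
  structure(list(bin_size = bin_size,
                 length_min = as.integer(length_min),
                 length_max = as.integer(length_max),
                 long_pool = as.integer(long_pool),
                 short_pool = as.integer(short_pool),
                 denest = isTRUE(denest), per_bp = isTRUE(per_bp)),
            class = "BinningSpec")
}

#' Reduce intervals to those with no containing interval
#'
#' Denesting: duplicates are removed, then every interval fully encompassed
#' by a distinct interval (`B.start <= A.start` and `A.end <= B.end`,
#' `B != A`) is discarded. The survivors form an antichain under containment
#' and every input interval is contained in some survivor; their 5' ends are
#' used as a proxy for distinct piRNA families, since truncated forms nest
#' inside their full-length parent.
#'
#' @param x An `IRanges` of intervals on one chromosome and strand, or a
#'   `GRanges` (denested per chromosome and strand).
#' @return The denested subset, same class as the input.
#' @export
denest <- function(x) {
  if (methods::is(x, "GRanges")) {
    key <- paste(GenomicRanges::seqnames(x), GenomicRanges::strand(x))
    keep <- logical(length(x))
    for (k in unique(key)) {
      idx <- which(key == k)
      keep[idx[denest_keep(GenomicRanges::start(x)[idx],
                           GenomicRanges::end(x)[idx])]] <- TRUE
    }
    return(x[keep])
  }
  if (!methods::is(x, "IRanges")) stop("denest() expects IRanges or GRanges")
  x[denest_keep(IRanges::start(x), IRanges::end(x))]
}

## Indices (into the original vectors) of deduplicated intervals that have no
## distinct containing interval. Sweep: after sorting by (start asc, end
## desc), an interval is contained iff some earlier interval ends at or after
## it does.
denest_keep <- function(start, end) {
  dup <- duplicated(paste(start, end))
  idx <- which(!dup)
  o <- order(start[idx], -end[idx])
  idx <- idx[o]
  e <- end[idx]
  prior_max <- c(-Inf, cummax(e)[-length(e)])
  sort(idx[e > prior_max])
}

#' Bin alignment counts by genomic position and read length
#'
#' Counts alignments per (chromosome, bin, alignment length), with bin index
#' `floor(start / bin_size)` from the leftmost aligned position. Alignment
#' lengths outside `[length_min, length_max]` are excluded from the matrix
#' but tallied (`n_out_of_range`), never silently dropped. Per-bin summaries
#' give the long-pool and short-pool sums and the number of distinct 5' ends
#' (keyed by chromosome, strand and 5' position; restricted to denested
#' alignments when `spec$denest`).
#'
#' @param sample A SampleSet with seqlengths set.
#' @param spec A [binning_spec()].
#' @param policy A [filter_policy()]; used for the optional piRNA-type filter.
#' @param pirna_type Restrict to `"primary"` (1U) or `"secondary"` (10A)
#'   piRNAs, or `"all"` (default, no restriction).
#' @param features Optional `GRanges`; when supplied only alignments
#'   overlapping it by at least 1 bp are counted.
#' @return An object of class `BinMatrix`: `counts` (long-format data.frame),
#'   `bins` (per-bin summaries), the spec, and input tallies.
#' @export
bin_expression <- function(sample, spec = binning_spec(),
                           policy = filter_policy(),
                           pirna_type = c("all", "primary", "secondary"),
                           features = NULL) {
  pirna_type <- match.arg(pirna_type)
  stopifnot(inherits(spec, "BinningSpec"))
  if (length(sample) == 0L) stop("empty sample")
  sl <- GenomeInfoDb::seqlengths(sample)
  if (any(is.na(sl))) stop("seqlengths must be set on the sample for binning")

  reads <- sample
  if (!is.null(features))
    reads <- reads[IRanges::overlapsAny(reads, features, minoverlap = 1L,
                                        ignore.strand = TRUE)]
  if (pirna_type != "all") {
    cls <- classify_pirna(reads, policy)
    keep <- cls$is_pirna & (if (pirna_type == "primary") cls$is_primary
                            else cls$is_secondary)
    reads <- reads[keep %in% TRUE]
  }
  n_total <- length(reads)
  len <- GenomicRanges::width(reads)
  in_range <- len >= spec$length_min & len <= spec$length_max
  n_out <- sum(!in_range)
  sel <- reads[in_range]
  len <- len[in_range]

  ## complete grid of bins over the genome
  grid <- do.call(rbind, lapply(names(sl), function(ch) {
    nb <- max(1L, as.integer(ceiling(sl[[ch]] / spec$bin_size)))
    bin <- seq_len(nb) - 1L
    bs <- bin * spec$bin_size
    be <- pmin(bs + spec$bin_size, sl[[ch]])
    data.frame(chrom = ch, bin = bin, bin_start = bs, bin_end = be,
               bin_width = be - bs)
  }))
  lens <- spec$length_min:spec$length_max
  counts <- grid[rep(seq_len(nrow(grid)), each = length(lens)), ]
  counts$length <- rep(lens, nrow(grid))
  rownames(counts) <- NULL

  bin_of <- function(pos) floor((pos - 1) / spec$bin_size)
  key <- paste(as.character(GenomicRanges::seqnames(sel)),
               bin_of(GenomicRanges::start(sel)), len)
  tab <- table(key)
  ckey <- paste(counts$chrom, counts$bin, counts$length)
  counts$count <- as.integer(ifelse(ckey %in% names(tab), tab[ckey], 0L))
  if (spec$per_bp) counts$count_per_bp <- counts$count / counts$bin_width

  bins <- grid
  sum_pool <- function(lo, hi) {
    m <- counts$length >= lo & counts$length <= hi
    agg <- tapply(counts$count[m], paste(counts$chrom[m], counts$bin[m]), sum)
    gkey <- paste(bins$chrom, bins$bin)
    as.integer(ifelse(gkey %in% names(agg), agg[gkey], 0L))
  }
  bins$long_sum <- sum_pool(spec$long_pool[1], spec$long_pool[2])
  bins$short_sum <- sum_pool(spec$short_pool[1], spec$short_pool[2])

  ## distinct 5' ends per bin
  fp_src <- if (spec$denest) denest(unique(GenomicRanges::granges(sel))) else sel
  fp <- five_prime(fp_src)
  ukey <- unique(paste(as.character(GenomicRanges::seqnames(fp_src)),
                       as.character(GenomicRanges::strand(fp_src)), fp))
  parts <- do.call(rbind, strsplit(ukey, " "))
  if (is.null(parts)) {
    bins$unique5 <- 0L
  } else {
    ub <- paste(parts[, 1], bin_of(as.numeric(parts[, 3])))
    utab <- table(ub)
    gkey <- paste(bins$chrom, bins$bin)
    bins$unique5 <- as.integer(ifelse(gkey %in% names(utab), utab[gkey], 0L))
  }

  structure(list(counts = counts, bins = bins, spec = spec,
                 n_total = n_total, n_in_range = length(sel),
                 n_out_of_range = n_out,
                 sample = sample_label(sample, "sample_id"),
                 condition = sample_label(sample, "condition")),
            class = "BinMatrix")
}

#' @export
print.BinMatrix <- function(x, ...) {
  cat("BinMatrix:", x$n_in_range, "alignments in range over",
      nrow(x$bins), "bins x", length(unique(x$counts$length)), "lengths",
      if (x$n_out_of_range) paste0("(", x$n_out_of_range, " out of range)"),
      "\n")
  invisible(x)
}

#' Differential binned expression between two samples
#'
#' Elementwise difference (`b - a`) of two [bin_expression()] matrices built
#' under an identical specification; unique 5'-end counts are kept separately
#' per sample rather than differenced.
#'
#' @param a,b `BinMatrix` objects (e.g. wild type and mutant).
#' @return An object of class `DiffBinMatrix` with `counts` (per-cell
#'   `count_diff`), `bins` (`long_diff`, `short_diff`, `unique5_a`,
#'   `unique5_b`).
#' @export
differential_bins <- function(a, b) {
  stopifnot(inherits(a, "BinMatrix"), inherits(b, "BinMatrix"))
  if (!identical(a$spec, b$spec))
    stop("BinMatrix inputs were built under different specifications")
  if (!identical(a$counts[c("chrom", "bin", "length")],
                 b$counts[c("chrom", "bin", "length")]))
    stop("BinMatrix inputs cover different genomes; refusing to rebin")
  counts <- a$counts[c("chrom", "bin", "bin_start", "bin_end", "bin_width", "length")]
  counts$count_diff <- b$counts$count - a$counts$count
  if (a$spec$per_bp)
    counts$count_per_bp_diff <- b$counts$count_per_bp - a$counts$count_per_bp
  bins <- a$bins[c("chrom", "bin", "bin_start", "bin_end", "bin_width")]
  bins$long_diff <- b$bins$long_sum - a$bins$long_sum
  bins$short_diff <- b$bins$short_sum - a$bins$short_sum
  bins$unique5_a <- a$bins$unique5
  bins$unique5_b <- b$bins$unique5
  structure(list(counts = counts, bins = bins, spec = a$spec,
                 sample_a = a$sample, sample_b = b$sample),
            class = "DiffBinMatrix")
}

#' @export
print.DiffBinMatrix <- function(x, ...) {
  cat("DiffBinMatrix:", x$sample_b, "-", x$sample_a, "over",
      nrow(x$bins), "bins\n")
  invisible(x)
}
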