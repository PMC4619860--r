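## Alignment ingestion and SAM emission.
##
## Reads come in via Rsamtools; reference bases over each aligned span are
## reconstructed from the MD tag when present, otherwise looked up in a FASTA.
## All read-space fields (seq, ref_bases) are stored 5'->3' of the RNA, i.e.
## reverse-complemented relative to SAM for minus-strand alignments.

#' Load and filter aligned small RNA reads
#'
#' Parses a SAM or BAM file into a SampleSet, dropping unmapped records and
#' alignments that fail the retention policy (mapping quality, reported hit
#' count). Each surviving alignment becomes one read; multi-mapped reads
#' contribute one entry per retained alignment. Counts of records dropped at
#' each step are kept in the sample metadata (`filter_tally`).
#'
#' Reference bases over the aligned span are rebuilt from the MD tag when the
#' record carries one, otherwise from `reference`; a record with neither is an
#' error naming the read.
#'
#' @param path SAM or BAM file. SAM input is converted on the fly.
#' @param policy A [filter_policy()].
#' @param reference Optional reference genome: a [Biostrings::DNAStringSet],
#'   or the path to a FASTA file (indexed on first use).
#' @param sample_id,condition,cell_type,replicate Labels stored in the sample
#'   metadata.
#' @return A SampleSet (`GRanges`); see [sample_set()].
#' @export
load_alignments <- function(path, policy = filter_policy(), reference = NULL,
                            sample_id = basename(path), condition = NA_character_,
                            cell_type = NA_character_, replicate = 1L) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar", "seq"),
    tag = c("NH", "MD", "X0", "X1")
  )
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(x$qname)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets

  tally <- c(total = n, unmapped = 0L, low_mapq = 0L, too_many_hits = 0L)
  if (n == 0L) {
    return(empty_sample(hdr, sample_id, condition, cell_type, replicate, tally))
  }

  mapped <- bitwAnd(x$flag, 4L) == 0L
  tally["unmapped"] <- sum(!mapped)

  nh <- x$tag$NH
  if (is.null(nh)) nh <- rep(NA_integer_, n)
  x0 <- x$tag$X0; x1 <- x$tag$X1
  if (!is.null(x0)) {
    alt <- x0 + ifelse(is.na(x1), 0L, x1)
    nh <- ifelse(is.na(nh), alt, nh)
  }
  nh <- ifelse(is.na(nh), 1L, nh)

  mq <- ifelse(is.na(x$mapq), 255L, x$mapq)
  low <- mapped & mq < policy$min_mapq
  tally["low_mapq"] <- sum(low)
  many <- mapped & !low & nh > policy$max_hits
  tally["too_many_hits"] <- sum(many)

  keep <- which(mapped & !low & !many)
  if (!length(keep)) {
    return(empty_sample(hdr, sample_id, condition, cell_type, replicate, tally))
  }

  chrom <- as.character(x$rname[keep])
  strand <- as.character(x$strand[keep])
  pos <- x$pos[keep]
  cigar <- x$cigar[keep]
  seq_sam <- as.character(x$seq[keep])
  refwidth <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  md <- x$tag$MD
  md <- if (is.null(md)) rep(NA_character_, n) else md
  md <- md[keep]

  fa <- prepare_reference(reference)
  if (!is.null(fa)) {
    bad <- setdiff(unique(chrom), names(fa$lengths))
    if (length(bad)) stop("contig(s) absent from reference: ", paste(bad, collapse = ", "))
  }

  ref_sam <- character(length(keep))
  for (i in seq_along(keep)) {
    if (!is.na(md[i])) {
      ref_sam[i] <- ref_from_md(seq_sam[i], cigar[i], md[i])
    } else if (!is.null(fa)) {
      gref <- fetch_reference(fa, chrom[i], pos[i], refwidth[i])
      ref_sam[i] <- ref_from_fasta(seq_sam[i], cigar[i], gref)
    } else {
      stop("read '", x$qname[keep][i],
           "' has no MD tag and no reference genome was supplied")
    }
  }

  minus <- strand == "-"
  seq_rs <- seq_sam
  ref_rs <- ref_sam
  if (any(minus)) {
    seq_rs[minus] <- revcomp_chr(seq_sam[minus])
    ref_rs[minus] <- revcomp_chr(ref_sam[minus])
  }

  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = pos, width = refwidth),
    strand = strand,
    read_id = x$qname[keep], seq = seq_rs, mapq = mq[keep],
    n_hits = nh[keep], ref_bases = ref_rs
  )
  if (length(hdr)) {
    GenomeInfoDb::seqlevels(gr) <- union(names(hdr), GenomeInfoDb::seqlevels(gr))
    GenomeInfoDb::seqlengths(gr)[names(hdr)] <- unname(hdr)
  }
  tally <- c(tally, kept = length(gr))
  sample_set(gr, sample_id = sample_id, condition = condition,
             cell_type = cell_type, replicate = replicate, filter_tally = tally)
}

empty_sample <- function(hdr, sample_id, condition, cell_type, replicate, tally) {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    read_id = character(), seq = character(), mapq = integer(),
    n_hits = integer(), ref_bases = character()
  )
  if (length(hdr)) {
    GenomeInfoDb::seqlevels(gr) <- names(hdr)
    GenomeInfoDb::seqlengths(gr) <- unname(hdr)
  }
  sample_set(gr, sample_id = sample_id, condition = condition,
             cell_type = cell_type, replicate = replicate,
             filter_tally = c(tally, kept = 0L))
}

prepare_reference <- function(reference) {
  if (is.null(reference)) return(NULL)
  if (methods::is(reference, "DNAStringSet")) {
    return(list(kind = "dss", seq = reference,
                lengths = stats::setNames(Biostrings::width(reference), names(reference))))
  }
  if (is.character(reference) && length(reference) == 1L) {
    if (!file.exists(paste0(reference, ".fai"))) Rsamtools::indexFa(reference)
    fa <- Rsamtools::FaFile(reference)
    si <- GenomeInfoDb::seqinfo(fa)
    return(list(kind = "fa", fa = fa,
                lengths = stats::setNames(GenomeInfoDb::seqlengths(si),
                                          GenomeInfoDb::seqnames(si))))
  }
  stop("reference must be a DNAStringSet or a FASTA path")
}

fetch_reference <- function(fa, chrom, pos, width) {
  rng <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = width))
  if (fa$kind == "dss") {
    as.character(Biostrings::subseq(fa$seq[[chrom]], pos, pos + width - 1L))
  } else {
    as.character(Rsamtools::scanFa(fa$fa, rng)[[1]])
  }
}

parse_cigar <- function(cigar) {
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(len) != length(op)) stop("malformed CIGAR: ", cigar)
  list(len = len, op = op)
}

## Reference bases in SAM (reference) orientation, one character per read
## base, "." where the read base is not aligned (S/I). MD describes only the
## aligned portion; deleted reference bases (^...) are skipped because they
## correspond to no read position.
ref_from_md <- function(seq_sam, cigar, md) {
  L <- nchar(seq_sam)
  cg <- parse_cigar(cigar)
  aligned <- logical(L)
  r <- 0L
  for (k in seq_along(cg$op)) {
    op <- cg$op[k]; n <- cg$len[k]
    if (op %in% c("M", "=", "X")) { aligned[(r + 1L):(r + n)] <- TRUE; r <- r + n }
    else if (op %in% c("S", "I")) r <- r + n
    ## D, N, H, P consume no read bases
  }
  idx <- which(aligned)
  read_aln <- strsplit(substring_vec(seq_sam, idx), "")[[1]]
  ref_aln <- character(length(idx))
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Za-z]+|[A-Za-z]", md))[[1]]
  p <- 0L
  for (t in toks) {
    if (grepl("^[0-9]+$", t)) {
      n <- as.integer(t)
      if (n > 0L) { ref_aln[(p + 1L):(p + n)] <- read_aln[(p + 1L):(p + n)]; p <- p + n }
    } else if (startsWith(t, "^")) {
      ## deletion from the reference: no read positions consumed
    } else {
      p <- p + 1L
      ref_aln[p] <- toupper(t)
    }
  }
  if (p != length(idx)) stop("MD tag inconsistent with CIGAR: ", md, " / ", cigar)
  out <- rep(".", L)
  out[idx] <- ref_aln
  paste(out, collapse = "")
}

ref_from_fasta <- function(seq_sam, cigar, genome_ref) {
  L <- nchar(seq_sam)
  cg <- parse_cigar(cigar)
  out <- rep(".", L)
  gchars <- strsplit(genome_ref, "")[[1]]
  r <- 0L; g <- 0L
  for (k in seq_along(cg$op)) {
    op <- cg$op[k]; n <- cg$len[k]
    if (op %in% c("M", "=", "X")) {
      out[(r + 1L):(r + n)] <- toupper(gchars[(g + 1L):(g + n)])
      r <- r + n; g <- g + n
    } else if (op %in% c("S", "I")) {
      r <- r + n
    } else if (op %in% c("D", "N")) {
      g <- g + n
    }
  }
  paste(out, collapse = "")
}

substring_vec <- function(x, idx) {
  paste(strsplit(x, "")[[1]][idx], collapse = "")
}

## Reverse complement for plain character vectors, preserving "." markers.
revcomp_chr <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), character(1))
}

md_from_alignment <- function(read_sam, ref_sam) {
  rd <- strsplit(read_sam, "")[[1]]
  rf <- strsplit(ref_sam, "")[[1]]
  out <- character(0)
  run <- 0L
  for (i in seq_along(rd)) {
    if (rd[i] == rf[i]) run <- run + 1L
    else { out <- c(out, as.character(run), rf[i]); run <- 0L }
  }
  paste(c(out, as.character(run)), collapse = "")
}

#' Write a SampleSet to a SAM file
#'
#' Emits one fully aligned (`<len>M`) record per read with `NH` and `MD` tags,
#' suitable for re-ingestion with [load_alignments()]. Reads containing
#' unaligned positions (`.` in `ref_bases`) cannot be represented by this
#' writer and are an error.
#'
#' @param sample A SampleSet with seqlengths set on its `GRanges`.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sample_sam <- function(sample, path) {
  sl <- GenomeInfoDb::seqlengths(sample)
  if (any(is.na(sl))) stop("seqlengths must be set to write SAM")
  if (length(sample) && any(grepl(".", sample$ref_bases, fixed = TRUE)))
    stop("cannot write reads with unaligned positions as fully aligned records")
  if (length(sample) && any(nchar(sample$seq) != GenomicRanges::width(sample)))
    stop("read length and alignment width differ; not representable as <len>M")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sl), sl))
  if (length(sample) == 0L) { writeLines(hdr, path); return(invisible(path)) }
  minus <- as.character(GenomicRanges::strand(sample)) == "-"
  seq_sam <- ifelse(minus, revcomp_chr(sample$seq), sample$seq)
  ref_sam <- ifelse(minus, revcomp_chr(sample$ref_bases), sample$ref_bases)
  md <- mapply(md_from_alignment, seq_sam, ref_sam, USE.NAMES = FALSE)
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s\tNH:i:%d\tMD:Z:%s",
                 sample$read_id, ifelse(minus, 16L, 0L),
                 as.character(GenomicRanges::seqnames(sample)),
                 GenomicRanges::start(sample), sample$mapq,
                 GenomicRanges::width(sample), seq_sam,
                 strrep("I", nchar(seq_sam)), sample$n_hits, md)
  writeLines(c(hdr, rec), path)
  invisible(path)
}
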