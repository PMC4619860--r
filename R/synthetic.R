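## Synthetic piRNA library generator.
##
## A toy genome with disjoint piRNA-cluster / repeat / gene annotation is
## simulated, a fixed set of piRNA source loci is laid out on it, and reads
## are drawn from those loci under a configurable model: a mixture of length
## modes, optional extra 5'/3' truncation, single-base non-templated 3'
## tailing (A or U), a 1U bias at the source, and opposite-strand partner
## pairs with an exact 10-nt 5' overlap (the ping-pong geometry). Every read
## carries a ground-truth record, so each downstream estimator can be
## validated by parameter recovery.

#' Configuration for the synthetic piRNA library generator
#'
#' The two condition presets emulate adult mouse germ-cell libraries: the
#' wild type has a single length mode at 30 nt, low 3' tailing and a modest
#' ping-pong fraction; the mutant (loss of 3'-end 2'-O-methylation) has a
#' bimodal length profile with modes at 26 and 30 nt, elevated adenylation
#' (10%) and uridylation (5%), and a halved ping-pong fraction.
#'
#' @param condition `"wild_type"` or `"mutant"`; selects preset values for
#'   `length_mixture`, `tail_A_rate`, `tail_U_rate` and `pingpong_pair_frac`,
#'   each overridable.
#' @param seed Random seed for read sampling.
#' @param n_chroms,chrom_length Shape of the toy genome.
#' @param n_clusters,cluster_length,n_repeats,repeat_length Number and size
#'   of piRNA-cluster and repeat intervals.
#' @param n_genes_coding,n_genes_noncoding,exons_per_gene,exon_length,intron_length
#'   Gene-model shape; coding genes carry 5'UTR/CDS/3'UTR sub-features.
#' @param n_reads Reads per sample.
#' @param n_loci Number of piRNA source loci laid out on the genome.
#' @param locus_seed Seed for the locus layout. It is independent of `seed`
#'   so samples of different conditions share the same source loci, as
#'   biological replicates of one genome do.
#' @param length_mixture `data.frame(mode, weight, spread)`: mixture of
#'   discretised normal length components (nt); weights must sum to 1.
#' @param trunc3_dist,trunc5_dist Named numeric vectors: names are truncation
#'   amounts (bases removed from that end), values are probabilities summing
#'   to 1.
#' @param tail_A_rate,tail_U_rate Probabilities that a read receives one
#'   non-templated 3' A (adenylation) or U (uridylation); their sum must not
#'   exceed 1.
#' @param frac_primary_1U Probability a source locus starts with U.
#' @param abundance_sd Log-normal sigma of per-locus expression; `0` gives
#'   equal locus abundances (a flat, ping-pong-free sample then yields a
#'   near-uniform 5'-overlap background).
#' @param pingpong_pair_frac Fraction of reads emitted as members of
#'   opposite-strand pairs with an exact 10-nt 5' overlap.
#' @param antisense_frac Probability a locus on a stranded feature is placed
#'   antisense to it.
#' @param placement Named weights over source categories
#'   (`cluster`, `repeat`, `exon_coding`, `exon_noncoding`, `intron`,
#'   `intergenic`); must sum to 1.
#' @param pingpong_feature Where ping-pong pair loci are placed: on repeats
#'   (`"repeat"`, sense primary / antisense secondary, satisfying the
#'   stringent pair criteria), on coding exons (`"gene"`), or anywhere
#'   (`"any"`).
#' @return An object of class `SyntheticConfig`.
#' @export
synthetic_config <- function(condition = c("wild_type", "mutant"),
                             seed = 1L,
                             n_chroms = 2L, chrom_length = 1e6,
                             n_clusters = 4L, cluster_length = 20000L,
                             n_repeats = 60L, repeat_length = 300L,
                             n_genes_coding = 30L, n_genes_noncoding = 15L,
                             exons_per_gene = 3L, exon_length = 200L,
                             intron_length = 500L,
                             n_reads = 20000L, n_loci = 400L,
                             locus_seed = 7717L,
                             length_mixture = NULL,
                             trunc3_dist = c(`0` = 1), trunc5_dist = c(`0` = 1),
                             tail_A_rate = NULL, tail_U_rate = NULL,
                             frac_primary_1U = 0.8,
                             abundance_sd = 1,
                             pingpong_pair_frac = NULL,
                             antisense_frac = 0.3,
                             placement = c(cluster = 0.80, `repeat` = 0.005,
                                           exon_coding = 0.04, exon_noncoding = 0.04,
                                           intron = 0.015, intergenic = 0.10),
                             pingpong_feature = c("repeat", "gene", "any")) {
  condition <- match.arg(condition)
  pingpong_feature <- match.arg(pingpong_feature)
  preset <- if (condition == "wild_type") {
    list(length_mixture = data.frame(mode = 30, weight = 1, spread = 1),
         tail_A_rate = 0.02, tail_U_rate = 0.02, pingpong_pair_frac = 0.10)
  } else {
    list(length_mixture = data.frame(mode = c(30, 26), weight = c(0.55, 0.45),
                                     spread = c(1, 1)),
         tail_A_rate = 0.10, tail_U_rate = 0.05, pingpong_pair_frac = 0.05)
  }
  if (is.null(length_mixture)) length_mixture <- preset$length_mixture
  if (is.null(tail_A_rate)) tail_A_rate <- preset$tail_A_rate
  if (is.null(tail_U_rate)) tail_U_rate <- preset$tail_U_rate
  if (is.null(pingpong_pair_frac)) pingpong_pair_frac <- preset$pingpong_pair_frac

  stopifnot(is.data.frame(length_mixture),
            all(c("mode", "weight", "spread") %in% names(length_mixture)),
            abs(sum(length_mixture$weight) - 1) < 1e-9,
            all(length_mixture$spread >= 0))
  for (r in list(tail_A_rate, tail_U_rate, frac_primary_1U, pingpong_pair_frac,
                 antisense_frac))
    stopifnot(length(r) == 1L, r >= 0, r <= 1)
  stopifnot(tail_A_rate + tail_U_rate <= 1)
  check_dist <- function(d, nm) {
    if (is.null(names(d)) || abs(sum(d) - 1) > 1e-9 || any(d < 0))
      stop(nm, " must be a named probability vector summing to 1")
    if (any(is.na(as.integer(names(d)))) || any(as.integer(names(d)) < 0))
      stop(nm, " names must be non-negative truncation amounts")
  }
  check_dist(trunc3_dist, "trunc3_dist"); check_dist(trunc5_dist, "trunc5_dist")
  stopifnot(abs(sum(placement) - 1) < 1e-9,
            setequal(names(placement), c("cluster", "repeat", "exon_coding",
                                         "exon_noncoding", "intron", "intergenic")))
  structure(list(
    condition = condition, seed = as.integer(seed),
    n_chroms = as.integer(n_chroms), chrom_length = as.integer(chrom_length),
    n_clusters = as.integer(n_clusters), cluster_length = as.integer(cluster_length),
    n_repeats = as.integer(n_repeats), repeat_length = as.integer(repeat_length),
    n_genes_coding = as.integer(n_genes_coding),
    n_genes_noncoding = as.integer(n_genes_noncoding),
    exons_per_gene = as.integer(exons_per_gene),
    exon_length = as.integer(exon_length), intron_length = as.integer(intron_length),
    n_reads = as.integer(n_reads), n_loci = as.integer(n_loci),
    locus_seed = as.integer(locus_seed),
    length_mixture = length_mixture,
    trunc3_dist = trunc3_dist, trunc5_dist = trunc5_dist,
    tail_A_rate = tail_A_rate, tail_U_rate = tail_U_rate,
    frac_primary_1U = frac_primary_1U, abundance_sd = abundance_sd,
    pingpong_pair_frac = pingpong_pair_frac, antisense_frac = antisense_frac,
    placement = placement, pingpong_feature = pingpong_feature
  ), class = "SyntheticConfig")
}

#' @export
print.SyntheticConfig <- function(x, ...) {
  cat("SyntheticConfig (", x$condition, "): ", x$n_reads, " reads, ",
      x$n_chroms, " x ", x$chrom_length, " bp genome, ", x$n_loci, " loci\n",
      "  length modes: ", paste(x$length_mixture$mode, collapse = "/"),
      "; tail A/U: ", x$tail_A_rate, "/", x$tail_U_rate,
      "; ping-pong frac: ", x$pingpong_pair_frac, "\n", sep = "")
  invisible(x)
}

random_dna <- function(n, chunk = 1e6L) {
  parts <- character(ceiling(n / chunk))
  done <- 0L; i <- 0L
  while (done < n) {
    m <- min(chunk, n - done); i <- i + 1L
    parts[i] <- paste(sample(c("A", "C", "G", "T"), m, replace = TRUE),
                      collapse = "")
    done <- done + m
  }
  Biostrings::DNAString(paste(parts, collapse = ""))
}

#' Simulate a toy genome with annotation
#'
#' Generates random chromosome sequences and mutually disjoint piRNA-cluster,
#' repeat and gene intervals. Coding genes carry exon, CDS and UTR
#' sub-features; introns are implied by the gene body minus its exons.
#' Deterministic for a fixed `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return `list(genome = DNAStringSet, annotations = list(clusters, repeats,
#'   genes))`; `genes` is a GFF3-style `GRanges` with `type`, `ID`, `Parent`,
#'   `gene_id` and `transcript_type` columns.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  genome <- Biostrings::DNAStringSet(lapply(chroms, function(ch)
    random_dna(config$chrom_length)))
  names(genome) <- chroms

  gene_span <- config$exons_per_gene * config$exon_length +
    (config$exons_per_gene - 1L) * config$intron_length
  reqs <- rbind(
    data.frame(kind = "cluster", len = rep(config$cluster_length, config$n_clusters)),
    data.frame(kind = "repeat", len = rep(config$repeat_length, config$n_repeats)),
    data.frame(kind = "gene_coding", len = rep(gene_span, config$n_genes_coding)),
    data.frame(kind = "gene_noncoding", len = rep(gene_span, config$n_genes_noncoding))
  )
  reqs <- reqs[sample.int(nrow(reqs)), , drop = FALSE]
  reqs$chrom <- sample(chroms, nrow(reqs), replace = TRUE)

  placed <- list()
  for (ch in chroms) {
    sub <- reqs[reqs$chrom == ch, , drop = FALSE]
    if (!nrow(sub)) next
    need <- sum(sub$len)
    slack <- config$chrom_length - 200L - need
    if (slack < nrow(sub)) stop("annotation intervals exceed chromosome length")
    gaps <- stats::rmultinom(1, slack, rep(1, nrow(sub) + 1L))[, 1]
    cursor <- 100L
    for (i in seq_len(nrow(sub))) {
      cursor <- cursor + gaps[i]
      placed[[length(placed) + 1L]] <- data.frame(
        kind = sub$kind[i], chrom = ch, start = cursor,
        end = cursor + sub$len[i] - 1L)
      cursor <- cursor + sub$len[i]
    }
  }
  placed <- do.call(rbind, placed)

  mk_gr <- function(df, strand) GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end), strand = strand,
    seqinfo = GenomeInfoDb::Seqinfo(chroms, rep(config$chrom_length, length(chroms))))

  cl <- placed[placed$kind == "cluster", , drop = FALSE]
  clusters <- mk_gr(cl, "*")
  if (length(clusters)) clusters$name <- paste0("pi-cluster-", seq_along(clusters))

  rp <- placed[placed$kind == "repeat", , drop = FALSE]
  repeats <- mk_gr(rp, sample(c("+", "-"), nrow(rp), replace = TRUE))
  if (length(repeats)) repeats$name <- paste0("repeat-", seq_along(repeats))

  gn <- placed[grepl("^gene", placed$kind), , drop = FALSE]
  genes <- build_gene_models(gn, config, chroms)

  list(genome = genome, annotations = list(clusters = clusters,
                                           repeats = repeats, genes = genes))
}

build_gene_models <- function(gn, config, chroms) {
  si <- GenomeInfoDb::Seqinfo(chroms, rep(config$chrom_length, length(chroms)))
  if (!nrow(gn)) {
    gr <- GenomicRanges::GRanges(seqinfo = si)
    gr$type <- character(); gr$ID <- character(); gr$Parent <- character()
    gr$gene_id <- character(); gr$transcript_type <- character()
    return(gr)
  }
  recs <- list()
  for (i in seq_len(nrow(gn))) {
    gid <- sprintf("gene%03d", i)
    coding <- gn$kind[i] == "gene_coding"
    strand <- sample(c("+", "-"), 1L)
    ex_starts <- gn$start[i] +
      (seq_len(config$exons_per_gene) - 1L) * (config$exon_length + config$intron_length)
    ex_ends <- ex_starts + config$exon_length - 1L
    add <- function(type, start, end, id = NA_character_, parent = gid) {
      recs[[length(recs) + 1L]] <<- data.frame(
        chrom = gn$chrom[i], start = start, end = end, strand = strand,
        type = type, ID = id, Parent = parent, gene_id = gid,
        transcript_type = if (coding) "coding" else "noncoding")
    }
    recs[[length(recs) + 1L]] <- data.frame(
      chrom = gn$chrom[i], start = gn$start[i], end = gn$end[i], strand = strand,
      type = "gene", ID = gid, Parent = NA_character_, gene_id = gid,
      transcript_type = if (coding) "coding" else "noncoding")
    for (e in seq_along(ex_starts))
      add("exon", ex_starts[e], ex_ends[e], sprintf("%s.exon%d", gid, e))
    if (coding) {
      half <- config$exon_length %/% 2L
      ## UTRs occupy half of the terminal exons, strand-aware
      if (strand == "+") {
        add("five_prime_UTR", ex_starts[1], ex_starts[1] + half - 1L,
            paste0(gid, ".5utr"))
        add("three_prime_UTR", ex_ends[length(ex_ends)] - half + 1L,
            ex_ends[length(ex_ends)], paste0(gid, ".3utr"))
        cds_start <- ex_starts[1] + half; cds_end <- ex_ends[length(ex_ends)] - half
      } else {
        add("five_prime_UTR", ex_ends[length(ex_ends)] - half + 1L,
            ex_ends[length(ex_ends)], paste0(gid, ".5utr"))
        add("three_prime_UTR", ex_starts[1], ex_starts[1] + half - 1L,
            paste0(gid, ".3utr"))
        cds_start <- ex_starts[1] + half; cds_end <- ex_ends[length(ex_ends)] - half
      }
      for (e in seq_along(ex_starts)) {
        s <- max(ex_starts[e], cds_start); en <- min(ex_ends[e], cds_end)
        if (s <= en) add("CDS", s, en, sprintf("%s.cds%d", gid, e))
      }
    }
  }
  df <- do.call(rbind, recs)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               strand = df$strand, seqinfo = si)
  gr$type <- df$type; gr$ID <- df$ID; gr$Parent <- df$Parent
  gr$gene_id <- df$gene_id; gr$transcript_type <- df$transcript_type
  gr
}

#' Lay out piRNA source loci on a simulated genome
#'
#' Places `config$n_loci` source loci (5' positions with strand, category and
#' 1U status) over the annotated toy genome, plus opposite-strand ping-pong
#' pair loci at exact 10-nt 5'-overlap geometry when
#' `config$pingpong_pair_frac > 0`. Seeded by `config$locus_seed` — not the
#' read-sampling seed — so samples of different conditions drawn on one
#' genome share their source loci, the way biological samples of one genome
#' do. [simulate_reads()] derives the layout itself when not given one;
#' computing it once with this function and passing it in is worthwhile when
#' many samples are drawn on the same genome.
#'
#' @param config A [synthetic_config()].
#' @param genome,annotations Output of [simulate_genome()].
#' @return A data.frame of loci (`chrom`, `pos5`, `strand`, `category`,
#'   `feature_strand`, `is_1U`, `pair_id`, `role`, `locus_id`).
#' @export
layout_loci <- function(config, genome, annotations) {
  make_loci(config, genome, annotations)
}

## Lay out the piRNA source loci on the toy genome. Uses config$locus_seed so
## the layout is shared by all samples drawn on the same genome.
## Implemented on plain vectors (not GRanges) because it runs one rejection
## loop per locus.
make_loci <- function(config, genome, annotations) {
  set.seed(config$locus_seed)
  chroms <- names(genome)
  chrlen <- stats::setNames(Biostrings::width(genome), chroms)
  chrseq <- lapply(as.list(as.character(genome)), identity)
  names(chrseq) <- chroms
  margin <- 60L

  as_df <- function(gr) {
    if (is.null(gr) || !length(gr)) return(NULL)
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)))
  }
  genes <- annotations$genes
  feats <- list(
    cluster = as_df(annotations$clusters),
    `repeat` = as_df(annotations$repeats),
    exon_coding = as_df(genes[genes$type == "exon" &
                                genes$transcript_type == "coding"]),
    exon_noncoding = as_df(genes[genes$type == "exon" &
                                   genes$transcript_type == "noncoding"]),
    intron = as_df(intron_ranges(genes)),
    intergenic = NULL
  )
  occ_gr <- GenomicRanges::reduce(c(
    GenomicRanges::granges(annotations$clusters),
    GenomicRanges::granges(annotations$repeats),
    GenomicRanges::granges(genes[genes$type == "gene"])),
    ignore.strand = TRUE)
  occ_df <- as_df(occ_gr)
  ## per-chrom sorted occupied intervals, expanded so a +/-40 bp probe around
  ## a position can be tested with findInterval
  occupied <- lapply(stats::setNames(chroms, chroms), function(ch) {
    d <- occ_df[occ_df$chrom == ch, , drop = FALSE]
    if (is.null(d) || !nrow(d)) return(list(start = numeric(), end = numeric()))
    o <- order(d$start)
    list(start = d$start[o] - 40, end = d$end[o] + 40)
  })
  hits_occupied <- function(ch, pos) {
    occ <- occupied[[ch]]
    if (!length(occ$start)) return(FALSE)
    i <- findInterval(pos, occ$start)
    i > 0 && occ$end[i] >= pos
  }

  n_pair <- if (config$pingpong_pair_frac > 0)
    max(1L, ceiling(config$n_loci * config$pingpong_pair_frac)) else 0L
  n_single <- config$n_loci - n_pair

  cats <- sample(names(config$placement), n_single, replace = TRUE,
                 prob = config$placement)

  base_at <- function(chrom, pos, strand) {
    b <- substr(chrseq[[chrom]], pos, pos)
    if (strand == "-") chartr("ACGT", "TGCA", b) else b
  }

  ## loci on the same chromosome and strand are kept at least 40 bp apart so
  ## that no read from one locus can contain a read from another: distinct
  ## piRNA families occupy distinct positions, and containment relations then
  ## hold only between reads of the same family
  placed_env <- new.env(parent = emptyenv())
  sep_ok <- function(chrom, strand, pos) {
    key <- paste0(chrom, strand)
    v <- placed_env[[key]]
    if (is.null(v)) return(TRUE)
    i <- findInterval(pos, v)
    (i == 0L || pos - v[i] >= 40L) &&
      (i == length(v) || v[i + 1L] - pos >= 40L)
  }
  sep_add <- function(chrom, strand, pos) {
    key <- paste0(chrom, strand)
    v <- placed_env[[key]]
    if (is.null(v)) { placed_env[[key]] <- pos; return(invisible()) }
    placed_env[[key]] <- append(v, pos, after = findInterval(pos, v))
  }

  place_one <- function(cat, want_1U) {
    for (try in 1:200) {
      if (cat == "intergenic") {
        chrom <- sample(chroms, 1L)
        pos <- sample.int(chrlen[[chrom]] - 2L * margin, 1L) + margin
        if (hits_occupied(chrom, pos)) next
        strand <- sample(c("+", "-"), 1L)
        fstrand <- "*"
      } else {
        f <- feats[[cat]]
        if (is.null(f)) return(NULL)
        j <- sample.int(nrow(f), 1L)
        lo <- f$start[j] + margin
        hi <- f$end[j] - margin
        if (hi <= lo) next
        chrom <- f$chrom[j]
        pos <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        fstrand <- f$strand[j]
        strand <- if (fstrand %in% c("+", "-")) {
          anti <- stats::runif(1) < config$antisense_frac
          if (anti) setdiff(c("+", "-"), fstrand) else fstrand
        } else sample(c("+", "-"), 1L)
      }
      ## the locus 5' position: for "-" the read grows leftwards from pos
      if (strand == "-" && pos < 50L) next
      if (strand == "+" && pos > chrlen[[chrom]] - 50L) next
      if (!sep_ok(chrom, strand, pos)) next
      is_1U <- base_at(chrom, pos, strand) == "T"
      if (is_1U == want_1U) {
        sep_add(chrom, strand, pos)
        return(list(chrom = chrom, pos5 = pos, strand = strand,
                    category = cat, feature_strand = fstrand, is_1U = is_1U))
      }
    }
    NULL
  }

  rows <- vector("list", n_single)
  for (i in seq_len(n_single)) {
    want_1U <- stats::runif(1) < config$frac_primary_1U
    r <- place_one(cats[i], want_1U)
    if (is.null(r)) r <- place_one(cats[i], !want_1U)
    if (is.null(r)) r <- place_one("intergenic", want_1U)
    rows[[i]] <- r
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  rows_df <- function(rs) data.frame(
    chrom = vapply(rs, `[[`, "", "chrom"),
    pos5 = vapply(rs, `[[`, 0L, "pos5"),
    strand = vapply(rs, `[[`, "", "strand"),
    category = vapply(rs, `[[`, "", "category"),
    feature_strand = vapply(rs, `[[`, "", "feature_strand"),
    is_1U = vapply(rs, `[[`, NA, "is_1U"))
  loci <- rows_df(rows)
  loci$pair_id <- NA_integer_
  loci$role <- "single"

  ## ping-pong pair loci: secondary 5' end sits 9 bases downstream of the
  ## primary 5' end on the opposite strand, giving an exact 10-nt 5' overlap
  if (n_pair > 0L) {
    pcat <- switch(config$pingpong_feature,
                   `repeat` = "repeat", gene = "exon_coding", any = "intergenic")
    prow <- list()
    pair_ids <- integer(0)
    roles <- character(0)
    for (p in seq_len(n_pair)) {
      want_1U <- stats::runif(1) < config$frac_primary_1U
      pri <- NULL
      for (try in 1:200) {
        cand <- place_one(pcat, want_1U)
        if (is.null(cand)) cand <- place_one(pcat, !want_1U)
        if (is.null(cand)) break
        ## pair loci on stranded features must be sense-primary
        if (cand$feature_strand %in% c("+", "-") &&
            cand$strand != cand$feature_strand) next
        pri <- cand; break
      }
      if (is.null(pri)) next
      sec <- pri
      sec$strand <- setdiff(c("+", "-"), pri$strand)
      sec$pos5 <- if (pri$strand == "+") pri$pos5 + 9L else pri$pos5 - 9L
      sec$is_1U <- base_at(sec$chrom, sec$pos5, sec$strand) == "T"
      sep_add(sec$chrom, sec$strand, sec$pos5)
      prow <- c(prow, list(pri), list(sec))
      pair_ids <- c(pair_ids, p, p)
      roles <- c(roles, "pp_primary", "pp_secondary")
    }
    if (length(prow)) {
      pdf <- rows_df(prow)
      pdf$pair_id <- pair_ids
      pdf$role <- roles
      loci <- rbind(loci, pdf)
    }
  }
  loci$locus_id <- sprintf("locus%04d", seq_len(nrow(loci)))
  rownames(loci) <- NULL
  loci
}

## Introns are implied: the gene body minus its exons. Computed with plain
## interval arithmetic (sorted exon gaps per gene) rather than per-gene
## GRanges setdiff calls, which dominate runtime when the locus layout is
## rebuilt repeatedly.
intron_ranges <- function(genes) {
  body <- genes[genes$type == "gene"]
  ex <- genes[genes$type == "exon"]
  if (!length(body)) return(GenomicRanges::granges(body))
  b_id <- body$gene_id
  b_start <- GenomicRanges::start(body); b_end <- GenomicRanges::end(body)
  b_chrom <- as.character(GenomicRanges::seqnames(body))
  b_strand <- as.character(GenomicRanges::strand(body))
  e_id <- ex$gene_id
  e_start <- GenomicRanges::start(ex); e_end <- GenomicRanges::end(ex)
  chroms <- character(0); starts <- integer(0); ends <- integer(0)
  strands <- character(0)
  for (i in seq_along(b_id)) {
    j <- which(e_id == b_id[i])
    if (!length(j)) {
      ## exonless gene: the whole body is intronic
      chroms <- c(chroms, b_chrom[i]); strands <- c(strands, b_strand[i])
      starts <- c(starts, b_start[i]); ends <- c(ends, b_end[i])
      next
    }
    o <- order(e_start[j])
    es <- e_start[j][o]; ee <- e_end[j][o]
    gap_s <- c(b_start[i], ee + 1L)
    gap_e <- c(es - 1L, b_end[i])
    keep <- gap_s <= gap_e
    if (any(keep)) {
      chroms <- c(chroms, rep(b_chrom[i], sum(keep)))
      strands <- c(strands, rep(b_strand[i], sum(keep)))
      starts <- c(starts, gap_s[keep]); ends <- c(ends, gap_e[keep])
    }
  }
  if (!length(starts)) return(GenomicRanges::granges(body)[0])
  GenomicRanges::GRanges(chroms, IRanges::IRanges(starts, ends),
                         strand = strands,
                         seqinfo = GenomeInfoDb::seqinfo(genes))
}

#' Simulate an aligned small RNA library with ground truth
#'
#' Draws `config$n_reads` reads from the genome's piRNA source loci. Each read
#' takes a length from the configured mixture, optional extra 5'/3'
#' truncation, and with the configured probabilities a single non-templated
#' 3' A or U that extends the alignment by one base and mismatches the
#' reference there unless the adjacent genomic base happens to agree. A
#' configured fraction of reads is emitted as opposite-strand partner pairs
#' with an exact 10-nt 5' overlap; when the primary partner starts with U,
#' the overlap arithmetic automatically gives the secondary partner an A at
#' read position 10.
#'
#' @param config A [synthetic_config()].
#' @param genome,annotations Output of [simulate_genome()].
#' @param loci Optional precomputed locus layout from [layout_loci()];
#'   computing it once and passing it in avoids re-deriving the (identical)
#'   layout when many samples are drawn on one genome.
#' @return `list(sample = SampleSet, truth = data.frame, loci = data.frame)`;
#'   `truth` has one row per read: source locus and category, pre-truncation
#'   length, applied 5'/3' truncation, tail (`"A"`, `"U"` or `"none"`),
#'   1U/10A status, and partner read id for ping-pong pairs.
#' @export
simulate_reads <- function(config, genome, annotations, loci = NULL) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (is.null(loci)) loci <- make_loci(config, genome, annotations)
  set.seed(config$seed)
  chrlen <- stats::setNames(Biostrings::width(genome), names(genome))

  abundance <- stats::setNames(exp(stats::rnorm(nrow(loci), 0, config$abundance_sd)),
                               loci$locus_id)

  n_pairs_emit <- round(config$pingpong_pair_frac * config$n_reads / 2)
  n_single_emit <- config$n_reads - 2L * n_pairs_emit

  single_loci <- which(loci$role == "single")
  pair_primaries <- which(loci$role == "pp_primary")
  if (n_pairs_emit > 0L && !length(pair_primaries))
    stop("ping-pong pairs requested but no pair loci could be placed")

  draw_len <- function(n) {
    mix <- config$length_mixture
    comp <- sample.int(nrow(mix), n, replace = TRUE, prob = mix$weight)
    L <- mix$mode[comp] + round(stats::rnorm(n, 0, mix$spread[comp]))
    pmin(pmax(as.integer(L), 16L), 35L)
  }
  draw_dist <- function(d, n)
    as.integer(sample(names(d), n, replace = TRUE, prob = d))

  ## vectorised emission of a block of reads from locus rows `lidx`
  make_block <- function(lidx, forbid_trunc5 = FALSE) {
    m <- length(lidx)
    L0 <- draw_len(m)
    t5 <- if (forbid_trunc5) rep(0L, m) else draw_dist(config$trunc5_dist, m)
    t3 <- draw_dist(config$trunc3_dist, m)
    len <- pmax(L0 - t5 - t3, 12L)
    u <- stats::runif(m)
    tail <- ifelse(u < config$tail_A_rate, "A",
                   ifelse(u < config$tail_A_rate + config$tail_U_rate, "U",
                          "none"))
    span <- len + (tail != "none")
    strand <- loci$strand[lidx]
    pos5 <- loci$pos5[lidx]
    start <- ifelse(strand == "+", pos5 + t5, pos5 - t5 - span + 1L)
    end <- ifelse(strand == "+", pos5 + t5 + span - 1L, pos5 - t5)
    if (any(start < 1L | end > chrlen[loci$chrom[lidx]]))
      stop("read extends beyond chromosome; place loci further from the edges")
    data.frame(chrom = loci$chrom[lidx], start = start, end = end,
               strand = strand, L0 = L0, t5 = t5, t3 = t3, tail = tail,
               locus_id = loci$locus_id[lidx], category = loci$category[lidx])
  }

  blocks <- list()
  partner <- rep(NA_integer_, config$n_reads)
  if (n_single_emit > 0L) {
    pick <- sample(single_loci, n_single_emit, replace = TRUE,
                   prob = abundance[loci$locus_id[single_loci]])
    blocks$single <- make_block(pick)
  }
  if (n_pairs_emit > 0L) {
    pick <- sample(pair_primaries, n_pairs_emit, replace = TRUE,
                   prob = abundance[loci$locus_id[pair_primaries]])
    sec_of <- vapply(pick, function(i)
      which(loci$pair_id == loci$pair_id[i] & loci$role == "pp_secondary")[1],
      integer(1))
    ## interleave primary/secondary so partners are adjacent rows
    lidx <- as.integer(rbind(pick, sec_of))
    pri_rows <- n_single_emit + seq(1L, by = 2L, length.out = n_pairs_emit)
    partner[pri_rows] <- pri_rows + 1L
    partner[pri_rows + 1L] <- pri_rows
    blocks$pairs <- make_block(lidx, forbid_trunc5 = TRUE)
  }
  df <- do.call(rbind, blocks)
  rownames(df) <- NULL
  read_id <- sprintf("r%06d", seq_len(nrow(df)))

  gr <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end), strand = df$strand,
    seqinfo = GenomeInfoDb::Seqinfo(names(genome), unname(chrlen)))
  ref <- genome_seq(genome, gr)
  seq <- ref
  tailed <- df$tail != "none"
  tail_base <- ifelse(df$tail == "U", "T", df$tail)  # RNA U is DNA-space T
  if (any(tailed)) {
    n <- nchar(seq[tailed])
    substr(seq[tailed], n, n) <- tail_base[tailed]
  }

  gr$read_id <- read_id
  gr$seq <- seq
  gr$mapq <- 60L
  gr$n_hits <- 1L
  gr$ref_bases <- ref

  truth <- data.frame(
    read_id = read_id, locus_id = df$locus_id, category = df$category,
    pre_trunc_length = df$L0, trunc5 = df$t5, trunc3 = df$t3, tail = df$tail,
    is_1U = substr(seq, 1, 1) == "T",
    is_10A = nchar(seq) >= 10 & substr(seq, 10, 10) == "A",
    partner_id = ifelse(is.na(partner), NA_character_, read_id[partner]),
    chrom = df$chrom, strand = df$strand, start = df$start, end = df$end
  )

  sample <- sample_set(gr, sample_id = paste0(config$condition, "_s", config$seed),
                       condition = config$condition, replicate = 1L)
  list(sample = sample, truth = truth, loci = loci)
}

## Extract read-orientation genomic sequence for stranded ranges.
genome_seq <- function(genome, gr) {
  out <- character(length(gr))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    v <- Biostrings::extractAt(genome[[ch]],
                               IRanges::IRanges(GenomicRanges::start(gr)[idx],
                                                GenomicRanges::end(gr)[idx]))
    minus <- as.character(GenomicRanges::strand(gr))[idx] == "-"
    if (any(minus)) v[minus] <- Biostrings::reverseComplement(v[minus])
    out[idx] <- as.character(v)
  }
  out
}

#' Write simulator outputs to standard formats
#'
#' @param genome A `DNAStringSet`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @param annotations Annotation list from [simulate_genome()].
#' @param dir Output directory; writes `clusters.bed`, `repeats.bed`,
#'   `genes.gff3`.
#' @export
write_annotations <- function(annotations, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rtracklayer::export(annotations$clusters, file.path(dir, "clusters.bed"),
                      format = "BED")
  rtracklayer::export(annotations$repeats, file.path(dir, "repeats.bed"),
                      format = "BED")
  g <- annotations$genes
  g$Parent <- ifelse(is.na(g$Parent), "", g$Parent)
  g$phase <- cds_phase(g)
  rtracklayer::export(g, file.path(dir, "genes.gff3"), format = "GFF3")
  invisible(dir)
}

## GFF3 phase column for CDS features: bases to skip before the first
## complete codon, accumulated 5'->3' within each gene.
cds_phase <- function(genes) {
  phase <- rep(NA_integer_, length(genes))
  is_cds <- genes$type == "CDS"
  for (gid in unique(genes$gene_id[is_cds])) {
    idx <- which(is_cds & genes$gene_id == gid)
    minus <- as.character(GenomicRanges::strand(genes))[idx[1]] == "-"
    ord <- order(GenomicRanges::start(genes)[idx], decreasing = minus)
    len <- GenomicRanges::width(genes)[idx][ord]
    ph <- (3L - (cumsum(c(0L, len[-length(len)])) %% 3L)) %% 3L
    phase[idx[ord]] <- ph
  }
  phase
}

#' Load annotation tracks from disk
#'
#' @param clusters_bed,repeats_bed BED files of piRNA clusters and repeats.
#' @param genes_gff3 GFF3 gene models with exon/CDS/UTR features.
#' @return Annotation list as produced by [simulate_genome()].
#' @export
load_annotations <- function(clusters_bed, repeats_bed, genes_gff3) {
  for (f in c(clusters_bed, repeats_bed, genes_gff3))
    if (!file.exists(f)) stop("annotation track not found: ", f)
  genes <- rtracklayer::import(genes_gff3, format = "GFF3")
  genes$Parent <- vapply(as.list(genes$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  if (is.null(genes$gene_id)) {
    genes$gene_id <- ifelse(genes$type == "gene", genes$ID, genes$Parent)
  }
  list(clusters = rtracklayer::import(clusters_bed, format = "BED"),
       repeats = rtracklayer::import(repeats_bed, format = "BED"),
       genes = genes)
}
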