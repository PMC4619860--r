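## Read-length distributions and non-templated 3'-end modification.

#' Read-length distribution of piRNA reads
#'
#' Tallies read lengths over the piRNA length range and expresses each as a
#' percentage of the sample's total piRNA reads.
#'
#' @param sample A SampleSet.
#' @param policy A [filter_policy()] supplying the length range.
#' @return A data.frame with columns `sample`, `condition`, `length`,
#'   `count`, `percent`; percentages sum to 100 over the range.
#' @export
length_distribution <- function(sample, policy = filter_policy()) {
  pir <- pirna_reads(sample, policy)
  if (length(pir) == 0L)
    stop("no reads in the piRNA length range; cannot compute a distribution")
  lens <- policy$pirna_min_len:policy$pirna_max_len
  cnt <- table(factor(nchar(pir$seq), levels = lens))
  data.frame(
    sample = sample_label(sample, "sample_id"),
    condition = sample_label(sample, "condition"),
    length = lens,
    count = as.integer(cnt),
    percent = 100 * as.integer(cnt) / length(pir)
  )
}

#' Group replicate length distributions by condition
#'
#' @param distributions A list of [length_distribution()] outputs
#'   (one per replicate).
#' @return A data.frame with per-condition mean and SD of the percentage at
#'   each length.
#' @export
combine_length_distributions <- function(distributions) {
  all <- do.call(rbind, distributions)
  agg <- stats::aggregate(percent ~ condition + length, data = all,
                          FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
  data.frame(condition = agg$condition, length = agg$length,
             mean_percent = agg$percent[, "mean"], sd_percent = agg$percent[, "sd"])
}

#' Quantify non-templated 3' adenylation and uridylation
#'
#' Examines the 3'-terminal base of each piRNA read in read orientation. A
#' read is informative for adenylation when its terminal reference base is
#' not A (otherwise an added A would be indistinguishable from the template)
#' and counted adenylated when the read base there is A; uridylation is
#' measured the same way with T. Percentages are reported over informative
#' reads (the denominator under which modification status is determinable)
#' and, for comparability, over all piRNA reads.
#'
#' Reads whose terminal base is not aligned to the reference (soft-clipped)
#' are excluded and tallied when `policy$require_aligned_3prime` is `TRUE`
#' (the default); otherwise they are retained, but a clipped terminus has no
#' recorded reference base and remains uninformative for both tests.
#'
#' @param sample A SampleSet with `ref_bases` available.
#' @param policy A [filter_policy()].
#' @return An object of class `EndModSummary`: a list with fields
#'   `n_pirna`, `n_excluded_unaligned_3p`, `n_informative_A`, `n_adenylated`,
#'   `n_informative_U`, `n_uridylated`, `pct_adenylated_informative`,
#'   `pct_uridylated_informative`, `pct_adenylated_all`, `pct_uridylated_all`,
#'   `sample`, `condition`.
#' @export
end_modification <- function(sample, policy = filter_policy()) {
  pir <- pirna_reads(sample, policy)
  if (length(pir) == 0L) stop("no piRNA reads for 3' end analysis")
  n <- nchar(pir$seq)
  last_read <- substr(pir$seq, n, n)
  last_ref <- substr(pir$ref_bases, n, n)
  unaligned <- last_ref == "."
  n_excluded <- 0L
  if (policy$require_aligned_3prime && any(unaligned)) {
    n_excluded <- sum(unaligned)
    last_read <- last_read[!unaligned]
    last_ref <- last_ref[!unaligned]
  }
  info_A <- last_ref != "A" & last_ref != "."
  info_U <- last_ref != "T" & last_ref != "."
  aden <- info_A & last_read == "A"
  urid <- info_U & last_read == "T"
  n_all <- length(last_read)
  structure(list(
    n_pirna = length(pir),
    n_excluded_unaligned_3p = n_excluded,
    n_informative_A = sum(info_A), n_adenylated = sum(aden),
    n_informative_U = sum(info_U), n_uridylated = sum(urid),
    pct_adenylated_informative = 100 * sum(aden) / max(sum(info_A), 1L),
    pct_uridylated_informative = 100 * sum(urid) / max(sum(info_U), 1L),
    pct_adenylated_all = 100 * sum(aden) / n_all,
    pct_uridylated_all = 100 * sum(urid) / n_all,
    sample = sample_label(sample, "sample_id"),
    condition = sample_label(sample, "condition")
  ), class = "EndModSummary")
}

#' @export
print.EndModSummary <- function(x, ...) {
  cat("3' end modification (", x$n_pirna, " piRNA reads):\n",
      sprintf("  adenylation: %d/%d informative (%.2f%%)\n",
              x$n_adenylated, x$n_informative_A, x$pct_adenylated_informative),
      sprintf("  uridylation: %d/%d informative (%.2f%%)\n",
              x$n_uridylated, x$n_informative_U, x$pct_uridylated_informative),
      sep = "")
  invisible(x)
}

#' @export
#' @method as.data.frame EndModSummary
as.data.frame.EndModSummary <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(sample = x$sample, condition = x$condition,
             n_pirna = x$n_pirna,
             n_informative_A = x$n_informative_A, n_adenylated = x$n_adenylated,
             n_informative_U = x$n_informative_U, n_uridylated = x$n_uridylated,
             pct_adenylated_informative = x$pct_adenylated_informative,
             pct_uridylated_informative = x$pct_uridylated_informative,
             pct_adenylated_all = x$pct_adenylated_all,
             pct_uridylated_all = x$pct_uridylated_all)
}

#' Compare 3' end modification between conditions
#'
#' Emits one row per replicate plus condition means/SDs, and a two-sided
#' Welch test per modification between the two conditions (requires at least
#' two replicates per condition).
#'
#' @param summaries A list of [end_modification()] outputs.
#' @param denominator `"informative"` or `"all"`.
#' @return `list(replicates, by_condition, tests)`.
#' @export
compare_end_modification <- function(summaries,
                                     denominator = c("informative", "all")) {
  denominator <- match.arg(denominator)
  reps <- do.call(rbind, lapply(summaries, as.data.frame))
  acol <- paste0("pct_adenylated_", denominator)
  ucol <- paste0("pct_uridylated_", denominator)
  agg <- stats::aggregate(reps[, c(acol, ucol)], by = list(condition = reps$condition),
                          FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
  conds <- unique(reps$condition)
  tests <- NULL
  if (length(conds) == 2L &&
      all(table(reps$condition) >= 2L)) {
    tests <- do.call(rbind, lapply(c(adenylation = acol, uridylation = ucol),
      function(col) {
        a <- reps[reps$condition == conds[1], col]
        b <- reps[reps$condition == conds[2], col]
        w <- welch_test(b, a)
        data.frame(modification = NA_character_, t = w$t, df = w$df, p = w$p,
                   diff = mean(b) - mean(a), ci_lo = w$ci[1], ci_hi = w$ci[2])
      }))
    tests$modification <- c("adenylation", "uridylation")
  }
  list(replicates = reps, by_condition = agg, tests = tests)
}
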