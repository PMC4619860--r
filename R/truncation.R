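## Overlap-end analysis: 5' vs 3' truncation of short-pool alignments
## relative to containing long-pool alignments.

#' Build the long and short alignment pools
#'
#' Long alignments (default 28--32 nt) are taken from the first sample and
#' short alignments (default 23--27 nt) from the second; with one sample both
#' pools are drawn from it. The long pool is reduced to one instance of each
#' unique alignment by (chromosome, strand, start, length) identity -- the
#' map assignment -- and optionally denested.
#'
#' @param long_source SampleSet supplying long alignments (nominally wild
#'   type).
#' @param short_source SampleSet supplying short alignments (nominally
#'   mutant); defaults to `long_source` (single-sample mode).
#' @param spec A [binning_spec()] supplying the pool length ranges.
#' @param denest_long If `TRUE`, the unique long pool is denested.
#' @return `list(long, short, spec, denest_long)` of class `TruncationPools`.
#' @export
build_pools <- function(long_source, short_source = NULL,
                        spec = binning_spec(), denest_long = FALSE) {
  if (is.null(short_source)) short_source <- long_source
  wl <- GenomicRanges::width(long_source)
  long <- long_source[wl >= spec$long_pool[1] & wl <= spec$long_pool[2]]
  ws <- GenomicRanges::width(short_source)
  short <- short_source[ws >= spec$short_pool[1] & ws <= spec$short_pool[2]]
  if (length(long) == 0L) stop("long pool is empty after length filtering")
  if (length(short) == 0L) stop("short pool is empty after length filtering")
  key <- paste(GenomicRanges::seqnames(long), GenomicRanges::strand(long),
               GenomicRanges::start(long), GenomicRanges::width(long))
  long <- long[!duplicated(key)]
  if (denest_long) long <- denest(long)
  structure(list(long = long, short = short, spec = spec,
                 denest_long = denest_long),
            class = "TruncationPools")
}

#' Assign short alignments to long alignments and profile end changes
#'
#' In the default contained mode each short alignment is assigned to the
#' single longest long alignment on the same chromosome and strand that
#' completely contains it and is longer than it (ties broken by smallest
#' start, then input order); `all_containing = TRUE` records a pair for every
#' containing long alignment instead. With `contain = FALSE` any >= 1 bp
#' overlap qualifies and positive end changes (apparent lengthening) may
#' occur. For each pair the signed end changes are recorded with shortening
#' negative and lengthening positive:
#' on the plus strand `delta5 = long.start - short.start` and
#' `delta3 = short.end - long.end`; on the minus strand the roles of the two
#' interval ends swap. Short alignments with no eligible partner are tallied
#' as unassigned.
#'
#' @param pools A [build_pools()] result.
#' @param contain Require complete containment (default).
#' @param all_containing Record all containing long partners, not just the
#'   longest.
#' @return An object of class `TruncationProfile`: per-pair deltas, delta5
#'   and delta3 histograms with proportions summing to 1 over pairs, and
#'   assignment tallies.
#' @export
assign_and_profile <- function(pools, contain = TRUE, all_containing = FALSE) {
  stopifnot(inherits(pools, "TruncationPools"))
  if (!contain && all_containing)
    stop("all_containing applies to the contained mode only")
  short <- pools$short; long <- pools$long
  type <- if (contain) "within" else "any"
  ov <- GenomicRanges::findOverlaps(short, long, type = type, minoverlap = 1L,
                                    ignore.strand = FALSE)
  qs <- S4Vectors::queryHits(ov); ss <- S4Vectors::subjectHits(ov)
  if (contain) {
    keep <- GenomicRanges::width(long)[ss] > GenomicRanges::width(short)[qs]
    qs <- qs[keep]; ss <- ss[keep]
    if (!all_containing && length(qs)) {
      ## longest containing partner; ties -> smallest start, then input order
      o <- order(qs, -GenomicRanges::width(long)[ss],
                 GenomicRanges::start(long)[ss], ss)
      first <- !duplicated(qs[o])
      qs <- qs[o][first]; ss <- ss[o][first]
    }
  }
  if (length(qs)) {
    plus <- as.character(GenomicRanges::strand(short))[qs] == "+"
    ls <- GenomicRanges::start(long)[ss]; le <- GenomicRanges::end(long)[ss]
    sst <- GenomicRanges::start(short)[qs]; se <- GenomicRanges::end(short)[qs]
    delta5 <- ifelse(plus, ls - sst, se - le)
    delta3 <- ifelse(plus, se - le, ls - sst)
    pairs <- data.frame(short_idx = qs, long_idx = ss,
                        delta5 = as.integer(delta5),
                        delta3 = as.integer(delta3))
  } else {
    pairs <- data.frame(short_idx = integer(), long_idx = integer(),
                        delta5 = integer(), delta3 = integer())
  }
  hist_of <- function(d) {
    if (!length(d)) return(data.frame(delta = integer(), count = integer(),
                                      proportion = numeric()))
    tb <- table(d)
    data.frame(delta = as.integer(names(tb)), count = as.integer(tb),
               proportion = as.integer(tb) / length(d))
  }
  structure(list(
    pairs = pairs,
    hist5 = hist_of(pairs$delta5), hist3 = hist_of(pairs$delta3),
    n_short = length(short),
    n_assigned = length(unique(pairs$short_idx)),
    n_unassigned = length(short) - length(unique(pairs$short_idx)),
    contain = contain, all_containing = all_containing,
    spec = pools$spec, denest_long = pools$denest_long,
    sample_long = sample_label(pools$long, "sample_id"),
    sample_short = sample_label(pools$short, "sample_id")
  ), class = "TruncationProfile")
}

#' @export
print.TruncationProfile <- function(x, ...) {
  cat("TruncationProfile:", nrow(x$pairs), "pairs from", x$n_short,
      "short alignments (", x$n_unassigned, "unassigned )\n")
  cat("  mean |delta3| =", round(mean(abs(x$pairs$delta3)), 3),
      "; mean |delta5| =", round(mean(abs(x$pairs$delta5)), 3), "\n")
  invisible(x)
}

## Welch two-sample t statistic, Welch-Satterthwaite df, two-sided p, and
## confidence interval for mean(x) - mean(y). Implemented directly so the
## zero-variance degenerate cases have defined behaviour.
welch_test <- function(x, y, conf_level = 0.95) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 observations per group")
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  est <- m1 - m2
  if (se2 == 0) {
    if (est == 0) {
      return(list(t = 0, df = n1 + n2 - 2, p = 1, ci = c(0, 0), estimate = 0))
    }
    return(list(t = sign(est) * Inf, df = n1 + n2 - 2, p = 0,
                ci = c(est, est), estimate = est))
  }
  se <- sqrt(se2)
  t <- est / se
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  q <- stats::qt(1 - (1 - conf_level) / 2, df)
  list(t = t, df = df, p = p, ci = c(est - q * se, est + q * se), estimate = est)
}

#' Compare truncation magnitude at the 3' versus the 5' end
#'
#' Two-sided Welch two-sample t-test on the absolute end changes |delta3|
#' versus |delta5| over all pairs of a profile, with the 95% confidence
#' interval for the mean difference (the extent of 3' truncation beyond 5'
#' truncation).
#'
#' @param profile A [assign_and_profile()] result with at least 2 pairs.
#' @param conf_level Confidence level for the interval.
#' @return `list(t, df, p, ci, estimate, mean_abs_delta3, mean_abs_delta5)`.
#' @export
compare_ends <- function(profile, conf_level = 0.95) {
  stopifnot(inherits(profile, "TruncationProfile"))
  d3 <- abs(profile$pairs$delta3); d5 <- abs(profile$pairs$delta5)
  if (length(d3) < 2L) stop("need at least 2 pairs per end")
  w <- welch_test(d3, d5, conf_level)
  structure(c(w, list(mean_abs_delta3 = mean(d3), mean_abs_delta5 = mean(d5),
                      conf_level = conf_level)),
            class = "EndComparison")
}

#' @export
print.EndComparison <- function(x, ...) {
  cat(sprintf("Welch two-sample t-test, |delta3| vs |delta5|: t = %.1f, df = %.1f, p %s\n",
              x$t, x$df,
              if (x$p < 2.2e-16) "< 2.2e-16" else sprintf("= %.3g", x$p)))
  cat(sprintf("  mean |delta3| = %.3f, mean |delta5| = %.3f, %d%% CI of difference [%.3f, %.3f]\n",
              x$mean_abs_delta3, x$mean_abs_delta5,
              round(100 * x$conf_level), x$ci[1], x$ci[2]))
  invisible(x)
}

#' Compare truncation between two genotypes
#'
#' Per-end Welch difference of mean truncation magnitude (B - A) with
#' confidence intervals, and the per-length-change proportion differences of
#' the two delta3 (and delta5) histograms.
#'
#' @param profile_a,profile_b [assign_and_profile()] results built with
#'   identical pool specifications (e.g. wild type and mutant).
#' @param conf_level Confidence level.
#' @return `list(end3, end5, proportion_diff)`; `end3`/`end5` carry the
#'   Welch comparison of |delta| in B versus A, `proportion_diff` is a
#'   data.frame of per-delta proportion differences (B - A) for each end.
#' @export
compare_genotypes <- function(profile_a, profile_b, conf_level = 0.95) {
  stopifnot(inherits(profile_a, "TruncationProfile"),
            inherits(profile_b, "TruncationProfile"))
  if (!identical(profile_a$spec, profile_b$spec) ||
      !identical(profile_a$contain, profile_b$contain) ||
      !identical(profile_a$all_containing, profile_b$all_containing))
    stop("profiles were built under different pool specifications")
  cmp <- function(col) {
    a <- abs(profile_a$pairs[[col]]); b <- abs(profile_b$pairs[[col]])
    welch_test(b, a, conf_level)
  }
  prop_diff <- function(ha, hb, end) {
    deltas <- sort(union(ha$delta, hb$delta))
    pa <- stats::setNames(rep(0, length(deltas)), deltas)
    pb <- pa
    pa[as.character(ha$delta)] <- ha$proportion
    pb[as.character(hb$delta)] <- hb$proportion
    data.frame(end = end, delta = deltas, prop_a = unname(pa),
               prop_b = unname(pb), diff = unname(pb - pa))
  }
  list(end3 = cmp("delta3"), end5 = cmp("delta5"),
       proportion_diff = rbind(prop_diff(profile_a$hist3, profile_b$hist3, "3'"),
                               prop_diff(profile_a$hist5, profile_b$hist5, "5'")))
}
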