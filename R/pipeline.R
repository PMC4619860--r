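## Pipeline orchestration: run the requested stages in dependency order and
## write tabular outputs plus a machine-readable JSON summary.

#' Pipeline run configuration
#'
#' Validates inputs before any stage runs and is echoed verbatim (with a
#' content hash) into the output directory for provenance.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Seed applied before any simulation or sampling.
#' @param stages Stages to run, in any order; executed in dependency order.
#' @param alignments Optional named list of SAM/BAM paths
#'   (`list(a = ..., b = ...)`); when `NULL` a wild-type/mutant pair is
#'   simulated.
#' @param reference Optional FASTA path for MD-less alignments.
#' @param annotations Optional annotation list or
#'   `list(clusters_bed=, repeats_bed=, genes_gff3=)` paths; simulated
#'   otherwise.
#' @param policy A [filter_policy()].
#' @param bin_spec A [binning_spec()].
#' @param wt_config,mut_config [synthetic_config()]s used when simulating.
#' @param pingpong_window,pingpong_focal Window and focal overlap for
#'   [pingpong_z()].
#' @param contain,all_containing,denest_long Truncation stage flags; see
#'   [assign_and_profile()].
#' @return An object of class `RunConfig`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       stages = c("classify", "lengths", "tails", "bins",
                                  "diffbins", "trunc", "pingpong"),
                       alignments = NULL, reference = NULL, annotations = NULL,
                       policy = filter_policy(), bin_spec = binning_spec(),
                       wt_config = NULL, mut_config = NULL,
                       pingpong_window = 1:20, pingpong_focal = 10L,
                       contain = TRUE, all_containing = FALSE,
                       denest_long = FALSE) {
  known <- c("classify", "lengths", "tails", "bins", "diffbins", "trunc",
             "pingpong")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!is.null(alignments)) {
    for (p in unlist(alignments))
      if (!file.exists(p)) stop("alignment file not found: ", p)
    if (is.null(annotations) &&
        length(intersect(stages, c("classify", "pingpong"))))
      stop("annotation tracks are required for stages: classify, pingpong")
  }
  if (is.character(annotations)) stop("annotations must be a list")
  if (is.list(annotations) && !is.null(annotations$clusters_bed)) {
    for (nm in c("clusters_bed", "repeats_bed", "genes_gff3"))
      if (is.null(annotations[[nm]]) || !file.exists(annotations[[nm]]))
        stop("missing annotation track: ", nm)
  }
  seed <- as.integer(seed)
  if (is.null(wt_config)) wt_config <- synthetic_config("wild_type", seed = seed)
  if (is.null(mut_config))
    mut_config <- synthetic_config("mutant", seed = seed + 1L)
  structure(list(out_dir = out_dir, seed = seed, stages = stages,
                 alignments = alignments, reference = reference,
                 annotations = annotations, policy = policy,
                 bin_spec = bin_spec, wt_config = wt_config,
                 mut_config = mut_config, pingpong_window = pingpong_window,
                 pingpong_focal = as.integer(pingpong_focal),
                 contain = contain, all_containing = all_containing,
                 denest_long = denest_long),
            class = "RunConfig")
}

## hash of the analysis parameters (the output location does not change the
## analysis, so reruns into a different directory keep the same hash)
config_hash <- function(config) {
  config$out_dir <- NULL
  raw <- serialize(config, NULL, ascii = TRUE)
  sprintf("%08x", sum(as.double(raw)) %% 2^31)
}

#' Run the piRNA analysis pipeline
#'
#' Executes the configured stages in dependency order on the supplied (or
#' simulated) libraries and writes one TSV per stage output plus
#' `summary.json` carrying the configuration echo, its hash, the package
#' version and per-stage read tallies. Deterministic for a fixed
#' configuration and seed.
#'
#' @param config A [run_config()].
#' @return The result bundle (named list of stage results), invisibly;
#'   tables are written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  res <- list()
  tallies <- list()
  tsv <- function(df, name)
    utils::write.table(df, file.path(config$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)

  if (is.null(config$alignments)) {
    g <- simulate_genome(config$wt_config)
    ann <- g$annotations
    wt <- simulate_reads(config$wt_config, g$genome, ann)
    mut <- simulate_reads(config$mut_config, g$genome, ann)
    samples <- list(wild_type = wt$sample, mutant = mut$sample)
    res$truth <- list(wild_type = wt$truth, mutant = mut$truth)
  } else {
    samples <- lapply(names(config$alignments), function(nm)
      load_alignments(config$alignments[[nm]], config$policy,
                      reference = config$reference, sample_id = nm,
                      condition = nm))
    names(samples) <- names(config$alignments)
    ann <- if (is.list(config$annotations) &&
               !is.null(config$annotations$clusters_bed)) {
      load_annotations(config$annotations$clusters_bed,
                       config$annotations$repeats_bed,
                       config$annotations$genes_gff3)
    } else config$annotations
  }
  res$samples <- samples
  for (nm in names(samples))
    tallies[[nm]] <- as.list(S4Vectors::metadata(samples[[nm]])$filter_tally)

  run_stage <- function(stage, fun) {
    tryCatch(fun(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  if ("classify" %in% config$stages) {
    run_stage("classify", function() {
      res$classify <<- lapply(samples, function(s) {
        cls <- classify_pirna(s, config$policy, exclusive = TRUE)
        ann_df <- annotate_reads(s, ann)
        cbind(cls, ann_df[match(cls$read_id, ann_df$read_id), -1, drop = FALSE])
      })
      for (nm in names(res$classify))
        tsv(res$classify[[nm]], paste0("classify_", nm, ".tsv"))
      res$category_summary <<- lapply(samples, summarize_categories, ann,
                                      config$policy)
      tsv(do.call(rbind, lapply(names(res$category_summary), function(nm)
        cbind(sample = nm, res$category_summary[[nm]]$categories))),
        "category_summary.tsv")
    })
  }
  if ("lengths" %in% config$stages) {
    run_stage("lengths", function() {
      res$lengths <<- lapply(samples, length_distribution, config$policy)
      tsv(do.call(rbind, res$lengths), "length_distribution.tsv")
    })
  }
  if ("tails" %in% config$stages) {
    run_stage("tails", function() {
      res$tails <<- lapply(samples, end_modification, config$policy)
      tsv(do.call(rbind, lapply(res$tails, as.data.frame)),
          "end_modification.tsv")
    })
  }
  bins <- NULL
  if (length(intersect(config$stages, c("bins", "diffbins")))) {
    run_stage("bins", function() {
      bins <<- lapply(samples, bin_expression, config$bin_spec, config$policy)
      res$bins <<- bins
      for (nm in names(bins)) {
        tsv(bins[[nm]]$counts, paste0("bins_counts_", nm, ".tsv"))
        tsv(bins[[nm]]$bins, paste0("bins_summary_", nm, ".tsv"))
      }
    })
  }
  if ("diffbins" %in% config$stages && length(samples) >= 2L) {
    run_stage("diffbins", function() {
      d <- differential_bins(bins[[1]], bins[[2]])
      res$diffbins <<- d
      tsv(d$counts, "diffbins_counts.tsv")
      tsv(d$bins, "diffbins_summary.tsv")
    })
  }
  if ("trunc" %in% config$stages) {
    run_stage("trunc", function() {
      pools <- build_pools(samples[[1]],
                           if (length(samples) >= 2L) samples[[2]] else NULL,
                           config$bin_spec, config$denest_long)
      prof <- assign_and_profile(pools, contain = config$contain,
                                 all_containing = config$all_containing)
      res$truncation <<- prof
      utils::write.csv(prof$pairs, file.path(config$out_dir,
                                             "truncation_pairs.csv"),
                       row.names = FALSE)
      tsv(rbind(cbind(end = "5'", prof$hist5), cbind(end = "3'", prof$hist3)),
          "truncation_histograms.tsv")
      if (nrow(prof$pairs) >= 2L) res$compare_ends <<- compare_ends(prof)
    })
  }
  if ("pingpong" %in% config$stages) {
    run_stage("pingpong", function() {
      res$pingpong <<- lapply(samples, function(s) {
        h <- five_prime_overlaps(s, o_max = max(config$pingpong_window),
                                 policy = config$policy)
        z <- tryCatch(pingpong_z(h, config$pingpong_focal,
                                 config$pingpong_window),
                      error = function(e) NULL)
        list(histogram = h, z = z)
      })
      tsv(do.call(rbind, lapply(names(res$pingpong), function(nm)
        cbind(sample = nm, res$pingpong[[nm]]$histogram))),
        "pingpong_histograms.tsv")
      if (!is.null(ann)) {
        res$stringent <<- lapply(samples, stringent_pairs, ann,
                                 stringent_criteria(), config$policy)
        tsv(do.call(rbind, lapply(names(res$stringent), function(nm)
          cbind(sample = nm, res$stringent[[nm]]$by_feature))),
          "stringent_pairs.tsv")
      }
    })
  }

  summary <- list(
    package = "pirnakit",
    version = as.character(utils::packageVersion("pirnakit")),
    config_hash = config_hash(config),
    seed = config$seed,
    stages = config$stages,
    read_tallies = tallies,
    key_numbers = pipeline_key_numbers(res)
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("pipeline complete: ", length(config$stages), " stage(s); tallies: ",
          paste(names(tallies), collapse = ", "))
  invisible(res)
}

pipeline_key_numbers <- function(res) {
  out <- list()
  if (!is.null(res$lengths))
    out$length_mode <- lapply(res$lengths, function(d)
      d$length[which.max(d$count)])
  if (!is.null(res$tails))
    out$pct_adenylated_informative <- lapply(res$tails, function(t)
      t$pct_adenylated_informative)
  if (!is.null(res$compare_ends))
    out$truncation_p <- res$compare_ends$p
  if (!is.null(res$pingpong))
    out$pingpong_z <- lapply(res$pingpong, function(p)
      if (is.null(p$z)) NA else p$z$z)
  out
}
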