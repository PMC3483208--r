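#' Full detection-and-filtering pipeline with per-stage accounting
#'
#' Runs the published stage order on a tumor pair table and reports call
#' counts after every stage, intra- and inter-chromosomal separately:
#'
#' 1. `no_filter` — perfect duplicates and zero-MAPQ reads removed only;
#' 2. `mapping_quality` — both mates MAPQ >= `mq_min`;
#' 3. `imperfect_duplicates` — transitive 0-2 bp near-duplicate removal;
#' 4. `control`, `low_mappability`, `simple_repeats`, `custom` — the
#'    post-detection cascade (see [run_cascade()]).
#'
#' Calls are re-clustered after each pre-detection stage, so the report
#' traces how many candidate SVs each filter eliminates.
#'
#' @param tumor_pairs pair table for the tumor library.
#' @param control_pairs pair table for the control library (screened here
#'   with the same settings), or NULL to skip the comparison stage.
#' @param tracks list with `lowmap`, `simple_repeats`, `repeat_masker`
#'   tracks (any may be NULL).
#' @param lib a [library_model()].
#' @param cfg a [filter_config()].
#' @return list: `kept` (surviving high-confidence calls), `report`
#'   (stage-by-stage count table), `calls` (pre-cascade call set),
#'   `screen_stats`, `removed`.
#' @export
sv_pipeline <- function(tumor_pairs, control_pairs = NULL, tracks = list(),
                        lib = library_model(), cfg = filter_config()) {
  p <- as.data.table(tumor_pairs)[mapped == TRUE]
  count_calls <- function(pp, stage) {
    cl <- call_svs(cluster_pairs(pp, lib, cfg), cfg)
    data.table(stage = stage, intra = sum(cl$chromA == cl$chromB),
               inter = sum(cl$chromA != cl$chromB), total = nrow(cl))
  }
  # baseline: perfect duplicates and MAPQ-0 reads removed
  p0 <- remove_perfect_duplicates(p)
  n_perfect <- attr(p0, "n_removed")
  p0 <- filter_mapq(p0, filter_config(mq_min = 1L))
  rep0 <- count_calls(p0, "no_filter")
  p1 <- filter_mapq(p0, cfg)
  rep1 <- count_calls(p1, "mapping_quality")
  p2 <- remove_imperfect_duplicates(p1, cfg)
  n_imperfect <- attr(p2, "n_removed")
  p2 <- classify_pairs(p2, lib, cfg)
  calls <- call_svs(cluster_pairs(p2, lib, cfg), cfg)
  rep2 <- data.table(stage = "imperfect_duplicates",
                     intra = sum(calls$chromA == calls$chromB),
                     inter = sum(calls$chromA != calls$chromB),
                     total = nrow(calls))
  ctl <- NULL
  if (!is.null(control_pairs))
    ctl <- screen_pairs(control_pairs, lib, cfg)
  casc <- run_cascade(calls, ctl, tracks, lib, cfg)
  report <- rbind(rep0, rep1, rep2, casc$report[stage != "calls"])
  list(kept = casc$kept, report = report, calls = calls,
       screen_stats = list(total_pairs = nrow(as.data.table(tumor_pairs)),
                           unmapped = sum(!as.data.table(tumor_pairs)$mapped),
                           perfect_duplicates_removed = n_perfect,
                           imperfect_duplicates_removed = n_imperfect),
       removed = casc$removed)
}

#' Truth-recovery rate of the pipeline on an experiment
#'
#' For each seed: simulate a tumor library at the given physical coverage,
#' screen, cluster and call, then score the fraction of somatic truth
#' records matched by a call of the same type with anchors over the
#' breakpoints (see [match_calls_to_truth()]).
#'
#' @param exp an `sv_experiment`.
#' @param coverage physical coverage (x).
#' @param seeds integer vector of simulation seeds (one replicate each).
#' @param cfg a [filter_config()].
#' @return mean detection fraction across seeds; attribute `"per_seed"`
#'   carries the individual fractions.
#' @export
detect_truth_fraction <- function(exp, coverage, seeds, cfg = filter_config()) {
  truth <- as.data.table(exp$truth)[origin == "truth"]
  per_seed <- vapply(seeds, function(s) {
    pairs <- simulate_experiment(exp, "tumor", coverage = coverage, seed = s)
    scr <- screen_pairs(pairs, exp$lib, cfg)
    calls <- call_svs(cluster_pairs(scr, exp$lib, cfg), cfg)
    mean(match_calls_to_truth(calls, truth, exp$lib))
  }, numeric(1))
  out <- mean(per_seed)
  setattr(out, "per_seed", per_seed)
  out
}

#' End-to-end run from files or a fixture preset
#'
#' Chains screen -> call -> filter for a tumor (and optional control)
#' library and writes `kept.bedpe`, `cascade.json` and `stats.json` to
#' `out_dir`.  Inputs come either from a fixtures preset (built and
#' simulated on the fly) or from SAM/BED files.
#'
#' @param config flat named list; recognised keys: `preset`, `seed`,
#'   `tumor_sam`, `control_sam`, `lowmap_bed`, `simple_repeats_bed`,
#'   `repeat_masker_bed`, `read_len`, `insert_mean`, `insert_sd`, plus any
#'   [filter_config()] field.
#' @param out_dir output directory.
#' @return the [sv_pipeline()] result, invisibly.
#' @export
run_end_to_end <- function(config, out_dir = ".") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lib <- library_model(
    read_length = config$read_len %||% 50L,
    insert_mean = config$insert_mean %||% 315,
    insert_sd = config$insert_sd %||% 44
  )
  fc_args <- intersect(names(config), names(formals(filter_config)))
  cfg <- do.call(filter_config, config[fc_args])
  tracks <- list()
  if (!is.null(config$preset)) {
    exp <- suppressWarnings(
      build_experiment(experiment_config(config$preset, lib = lib),
                       seed = config$seed %||% 1L))
    if (config$preset == "dup-demo") {
      tumor <- exp$pairs
      control <- NULL
    } else {
      tumor <- simulate_experiment(exp, "tumor", seed = exp$sim_seeds[1])
      control <- simulate_experiment(exp, "control", seed = exp$sim_seeds[2])
      tracks <- list(lowmap = exp$tracks$lowmap,
                     simple_repeats = exp$tracks$repeats)
    }
  } else {
    if (is.null(config$tumor_sam)) stopf("either 'preset' or 'tumor_sam' is required")
    tumor <- read_pairs_sam(config$tumor_sam)
    control <- if (!is.null(config$control_sam)) read_pairs_sam(config$control_sam)
    tracks <- list(
      lowmap = if (!is.null(config$lowmap_bed)) read_track(config$lowmap_bed),
      simple_repeats = if (!is.null(config$simple_repeats_bed))
        read_track(config$simple_repeats_bed),
      repeat_masker = if (!is.null(config$repeat_masker_bed))
        read_track(config$repeat_masker_bed)
    )
  }
  res <- sv_pipeline(tumor, control, tracks, lib, cfg)
  write_bedpe(res$kept, file.path(out_dir, "kept.bedpe"))
  jsonlite::write_json(res$report, file.path(out_dir, "cascade.json"))
  jsonlite::write_json(c(res$screen_stats,
                         list(thresholds = unclass(cfg)[!vapply(cfg, is.null, TRUE)])),
                       file.path(out_dir, "stats.json"), auto_unbox = TRUE)
  invisible(res)
}
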