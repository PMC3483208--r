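#' Published simulated-SV truth layout
#'
#' The 20-entry truth set used throughout validation: 10 interchromosomal
#' translocation junctions (5 reciprocal events, each contributing a row per
#' direction) and 10 large deletions with verbatim sizes, each with a target
#' breakpoint mappability class.  Chromosome assignments follow the entry
#' names; breakpoints are placed deterministically on a toy genome (a
#' deletion starts at 20 kb on its chromosome; translocation breakpoints sit
#' at 30 kb).
#'
#' @return list with `tr` and `del` data.tables.
#' @keywords internal
.table1_layout <- function() {
  tr <- data.table(
    id = c("TR 15_12", "TR 12_15", "TR 10_X", "TR X_10", "TR 16_6",
           "TR 6_16", "TR 7_11", "TR 11_7", "TR 14_13", "TR 13_14"),
    chrom_a = paste0("chr", c("15", "12", "10", "X", "16", "6", "7", "11", "14", "13")),
    chrom_b = paste0("chr", c("12", "15", "X", "10", "6", "16", "11", "7", "13", "14")),
    mapp = c(100, 100, 50, 50, 70.2, 52.8, 66, 73.8, 18.5, 36.4)
  )
  del <- data.table(
    id = paste("DEL", c(1, 2, 3, 4, 5, 8, 9, 17, 18, 19)),
    chrom = paste0("chr", c(1, 2, 3, 4, 5, 8, 9, 17, 18, 19)),
    size = c(576373L, 46610L, 600033L, 5963L, 64735L, 1433L, 10789L,
             3066L, 1000440L, 21449L),
    mapp = c(100, 95.1, 85.3, 100, 100, 77.4, 100, 100, 100, 100)
  )
  list(tr = tr, del = del,
       del_start = 20000L, del_margin = 40000L,
       tr_len = 60000L, tr_pos = 30000L)
}

#' Experiment configuration presets
#'
#' * `"table1"` — the full benchmark: toy genome with one chromosome per
#'   truth entry, 10 deletions with verbatim sizes, 5 reciprocal
#'   translocations, breakpoint mappability classes engineered by 3-copy
#'   repeat spike-ins, library (50, 315, 44), 9.1% perfect + 1% imperfect
#'   duplicates.
#' * `"germline-demo"` — clean genome carrying germline retroelement and
#'   retrogene insertions (present in tumor AND control) plus a small
#'   somatic plan (tumor only); exercises the control-comparison stage.
#' * `"dup-demo"` — a 3-pair imperfect-duplicate cluster built directly as a
#'   pair table (no simulation); exercises duplicate handling.
#' * `"minimal"` — 2-chromosome smoke fixture with one deletion and one
#'   reciprocal translocation.
#'
#' @param preset preset name.
#' @param coverage tumor physical coverage (x); presets carry defaults.
#' @param control_coverage control physical coverage (x).
#' @param perfect_dup_rate,imperfect_dup_rate duplicate injection rates.
#' @param lib a [library_model()].
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(preset = c("table1", "germline-demo", "dup-demo",
                                         "minimal"),
                              coverage = NULL, control_coverage = NULL,
                              perfect_dup_rate = NULL, imperfect_dup_rate = NULL,
                              lib = library_model()) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    table1 = list(coverage = 19, control_coverage = 9,
                  perfect_dup_rate = 0.091, imperfect_dup_rate = 0.01),
    `germline-demo` = list(coverage = 15, control_coverage = 15,
                           perfect_dup_rate = 0, imperfect_dup_rate = 0),
    `dup-demo` = list(coverage = NA, control_coverage = NA,
                      perfect_dup_rate = 0, imperfect_dup_rate = 0),
    minimal = list(coverage = 30, control_coverage = 30,
                   perfect_dup_rate = 0, imperfect_dup_rate = 0)
  )
  structure(list(
    preset = preset,
    coverage = coverage %||% cfg$coverage,
    control_coverage = control_coverage %||% cfg$control_coverage,
    perfect_dup_rate = perfect_dup_rate %||% cfg$perfect_dup_rate,
    imperfect_dup_rate = imperfect_dup_rate %||% cfg$imperfect_dup_rate,
    lib = lib, kmer = lib$read_length
  ), class = "experiment_config")
}

# flank spike specification: n_dead dead windows on one flank of a breakpoint.
# Dead windows are the outermost of the five 50 bp flank windows; the repeat
# run covers them plus 49 bp toward the breakpoint (left flanks) or beyond
# the flank (right flanks), so that exactly the intended windows lose
# uniqueness while junction-crossing k-mers stay unique.
.flank_runs <- function(specs, window = 50L, flank_windows = 5L) {
  runs <- lapply(seq_len(nrow(specs)), function(i) {
    s <- specs[i]
    n <- s$n_dead
    if (n == 0) return(NULL)
    if (n > flank_windows) stopf("at most %d dead windows per flank", flank_windows)
    len <- window * n + window - 1L
    start <- if (s$side == "left") s$bp - flank_windows * window
             else s$bp + flank_windows * window - window * n
    data.table(chrom = s$chrom, start = start, end = start + len)
  })
  runs <- runs[!vapply(runs, is.null, logical(1))]
  if (length(runs)) rbindlist(runs) else
    data.table(chrom = character(0), start = integer(0), end = integer(0))
}

.replace_segment <- function(genome, chrom, start, seq) {
  s <- genome[[chrom]]
  if (start < 0 || start + nchar(seq) > nchar(s))
    stopf("spike-in out of bounds on %s", chrom)
  substr(s, start + 1L, start + nchar(seq)) <- seq
  genome[[chrom]] <- s
  genome
}

.rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

#' Build a synthetic tumor/control experiment
#'
#' One-command construction of everything a pipeline run needs: a reference
#' genome with engineered repeat structure, germline artifacts shared by the
#' tumor and control genomes, a somatic SV plan applied to the tumor only,
#' truth records for every event, k-mer occurrence counts, and the
#' low-mappability track.  All randomness flows from `seed`.
#'
#' @param config an [experiment_config()].
#' @param seed integer seed.
#' @param dir if non-NULL, also write the experiment to disk (FASTA, plan,
#'   truth BEDPE, tracks, truth SAMs, manifest.json).
#' @return an `sv_experiment` list: `ref`, `tumor_genome`, `control_genome`,
#'   `tumor_map`, `control_map`, `truth` (somatic + germline records),
#'   `plan`, `occ`, `scores`, `tracks`, `lib`, `config`, `seed`, and for
#'   `dup-demo` a ready-made `pairs` table.
#' @export
build_experiment <- function(config, seed = 1L, dir = NULL) {
  lib <- config$lib
  seeds <- derive_seeds(seed, 4L)
  if (config$preset == "dup-demo") {
    exp <- .build_dup_demo(config, lib)
  } else {
    exp <- switch(config$preset,
      table1 = .build_table1(config, seeds[1]),
      `germline-demo` = .build_germline_demo(config, seeds[1]),
      minimal = .build_minimal(config, seeds[1])
    )
    exp$lib <- lib
    exp$config <- config
    exp$seed <- seed
    exp$sim_seeds <- seeds[2:4]
    exp$occ <- kmer_occurrences(exp$ref, config$kmer)
    exp$scores <- uniqueness_scores(exp$ref, config$kmer, occ = exp$occ)
    exp$tracks$lowmap <- low_mappability_track(exp$ref, track_config(), exp$scores)
    exp$mapq_model <- default_mapq_model(exp$occ)
  }
  class(exp) <- "sv_experiment"
  if (!is.null(dir)) .write_experiment(exp, dir)
  exp
}

#' The packaged benchmark SV plan
#'
#' The 20-entry plan behind the `table1` preset: 10 deletions with verbatim
#' sizes and 10 translocation junctions (5 reciprocal events), placed at
#' fixed breakpoints on the preset's toy chromosomes.
#'
#' @return plan `data.table` (see [sv_plan]).
#' @export
table1_plan <- function() {
  lay <- .table1_layout()
  rbind(
    data.table(id = lay$del$id, type = "deletion", chrom_a = lay$del$chrom,
               pos_a = lay$del_start, chrom_b = NA_character_,
               pos_b = NA_integer_, size = lay$del$size),
    data.table(id = lay$tr$id, type = "translocation", chrom_a = lay$tr$chrom_a,
               pos_a = lay$tr_pos, chrom_b = lay$tr$chrom_b,
               pos_b = lay$tr_pos, size = NA_integer_)
  )
}

.build_table1 <- function(config, layout_seed) {
  lay <- .table1_layout()
  set.seed(layout_seed)
  # chromosome lengths: deletion hosts sized to fit; translocation hosts fixed
  lens <- c(setNames(lay$del$size + lay$del_margin, lay$del$chrom),
            setNames(rep(lay$tr_len, nrow(lay$tr)), unique(c(lay$tr$chrom_a))))
  ref <- random_genome(lens)
  plan <- table1_plan()
  # flank spike specification from the mappability classes
  n_dead <- function(f) as.integer(round((1 - f / 100) * 10))
  rounded <- 100 - 10 * vapply(c(lay$tr$mapp, lay$del$mapp), n_dead, integer(1))
  off_target <- c(lay$tr$mapp, lay$del$mapp) != rounded
  if (any(off_target))
    warnf("mappability target(s) rounded to the nearest multiple of 10: %s",
          paste(sprintf("%.1f->%d", c(lay$tr$mapp, lay$del$mapp)[off_target],
                        rounded[off_target]), collapse = ", "))
  specs <- list()
  for (i in seq_len(nrow(lay$tr))) {
    d <- n_dead(lay$tr$mapp[i])
    specs[[length(specs) + 1L]] <- data.table(
      chrom = c(lay$tr$chrom_a[i], lay$tr$chrom_b[i]),
      bp = lay$tr_pos, side = c("left", "right"),
      n_dead = c(ceiling(d / 2), floor(d / 2))
    )
  }
  for (i in seq_len(nrow(lay$del))) {
    d <- n_dead(lay$del$mapp[i])
    specs[[length(specs) + 1L]] <- data.table(
      chrom = lay$del$chrom[i],
      bp = c(lay$del_start, lay$del_start + lay$del$size[i]),
      side = c("left", "right"),
      n_dead = c(ceiling(d / 2), floor(d / 2))
    )
  }
  specs <- rbindlist(specs)[n_dead > 0]
  runs <- .flank_runs(specs)
  if (nrow(runs) > 1) {
    chk <- merge_intervals(runs)
    if (nrow(chk) != nrow(runs)) stopf("internal error: overlapping repeat spike-ins")
  }
  # write each repeat unit at its flank and twice more on a repeat landfill
  # chromosome, giving every spiked k-mer exactly 3 genomic copies.  Landfill
  # copies are wrapped in guard bases that differ from the unit's genomic
  # neighbours, so no k-mer crossing a unit boundary can match twice.
  other <- function(base) chartr("ACGTN", "CATGA", base)
  rep_parts <- character(0)
  for (i in seq_len(nrow(runs))) {
    unit <- .rand_seq(runs$end[i] - runs$start[i])
    ref <- .replace_segment(ref, runs$chrom[i], runs$start[i], unit)
    chromseq <- ref[[runs$chrom[i]]]
    prev <- substr(chromseq, runs$start[i], runs$start[i])        # base before run
    nxt <- substr(chromseq, runs$end[i] + 1L, runs$end[i] + 1L)   # base after run
    if (prev == "") prev <- "A"
    if (nxt == "") nxt <- "A"
    guard <- function() paste0(other(prev), unit, other(nxt))
    rep_parts <- c(rep_parts, guard(), .rand_seq(58L), guard(), .rand_seq(58L))
  }
  if (length(rep_parts)) {
    ref <- sv_genome(c(unclass(ref), chrRep = paste(rep_parts, collapse = "")))
  }
  res <- apply_plan(ref, plan)
  repeats <- interval_track(rbind(runs, if ("chrRep" %in% names(ref))
    data.table(chrom = "chrRep", start = 0L,
               end = nchar(ref[["chrRep"]]))), "repeats")
  list(ref = ref, tumor_genome = res$genome, control_genome = ref,
       tumor_map = res$map, control_map = identity_map(ref),
       truth = res$truth, plan = plan,
       tracks = list(repeats = repeats),
       mappability_targets = data.table(id = c(lay$tr$id, lay$del$id),
                                        target = rounded))
}

.build_germline_demo <- function(config, layout_seed) {
  set.seed(layout_seed)
  ref <- random_genome(c(chrA = 150000L, chrB = 150000L, chrC = 100000L))
  exons <- matrix(c(100000L, 100400L, 103400L, 103800L,
                    106800L, 107200L, 110200L, 110600L),
                  ncol = 2, byrow = TRUE)
  artifacts <- list(
    list(kind = "retroelement", src_chrom = "chrA", src_start = 50000L,
         src_end = 51200L, target_chrom = "chrB", target_pos = 60000L),
    list(kind = "retroelement", src_chrom = "chrC", src_start = 20000L,
         src_end = 21200L, target_chrom = "chrC", target_pos = 60000L),
    list(kind = "retrogene", src_chrom = "chrA", exons = exons,
         target_chrom = "chrB", target_pos = 120000L)
  )
  germ <- inject_germline_artifacts(identity_map(ref), artifacts)
  plan <- rbind(
    data.table(id = "SOM DEL 1", type = "deletion", chrom_a = "chrB",
               pos_a = 20000L, chrom_b = NA_character_, pos_b = NA_integer_,
               size = 5000L),
    data.table(id = c("SOM TR A_C", "SOM TR C_A"), type = "translocation",
               chrom_a = c("chrA", "chrC"), pos_a = c(130000L, 80000L),
               chrom_b = c("chrC", "chrA"), pos_b = c(80000L, 130000L),
               size = NA_integer_)
  )
  res <- apply_plan(ref, plan, map = germ$map)
  list(ref = ref, tumor_genome = res$genome,
       control_genome = derive_genome(germ$map),
       tumor_map = res$map, control_map = germ$map,
       truth = rbind(res$truth, germ$truth), plan = plan,
       tracks = list(repeats = interval_track(data.table(
         chrom = character(0), start = integer(0), end = integer(0)), "repeats")),
       artifacts = artifacts)
}

.build_minimal <- function(config, layout_seed) {
  set.seed(layout_seed)
  ref <- random_genome(c(chr1 = 60000L, chr2 = 60000L))
  plan <- rbind(
    data.table(id = "DEL A", type = "deletion", chrom_a = "chr1", pos_a = 15000L,
               chrom_b = NA_character_, pos_b = NA_integer_, size = 5000L),
    data.table(id = c("TR 1_2", "TR 2_1"), type = "translocation",
               chrom_a = c("chr1", "chr2"), pos_a = c(40000L, 30000L),
               chrom_b = c("chr2", "chr1"), pos_b = c(30000L, 40000L),
               size = NA_integer_)
  )
  res <- apply_plan(ref, plan)
  list(ref = ref, tumor_genome = res$genome, control_genome = ref,
       tumor_map = res$map, control_map = identity_map(ref),
       truth = res$truth, plan = plan,
       tracks = list(repeats = interval_track(data.table(
         chrom = character(0), start = integer(0), end = integer(0)), "repeats")))
}

.build_dup_demo <- function(config, lib) {
  # a deletion-signature locus supported by one fragment plus two imperfect
  # duplicates whose per-mate offsets reach +/-2 bp: without imperfect
  # de-duplication the cluster has support 3 and anchor spreads 4/3 bp
  # (enough to pass min_anchor), so it produces one spurious call; after
  # de-duplication a single pair remains and min_support 2 silences it.
  pairs <- data.table(
    frag_id = c("orig", "orig_dup1", "orig_dup2"),
    chromA = "chrD", posA = c(1000L, 998L, 1002L), strandA = "+",
    mapqA = 60L,
    chromB = "chrD", posB = c(5000L, 5002L, 4999L), strandB = "-",
    mapqB = 60L,
    rlen = lib$read_length, mapped = TRUE,
    dup = c(NA, "imperfect", "imperfect"),
    orig_id = c(NA, "orig", "orig")
  )
  list(pairs = pairs, truth = empty_calls(),
       tracks = list(), lib = lib, config = config, seed = NA_integer_)
}

#' Simulate a sequencing run over an experiment genome
#'
#' Draws fragments from the derived tumor (or control) genome at the
#' requested physical coverage, injects duplicates at the configured rates,
#' and places the fragments back on the reference through the liftover with
#' the k-mer MAPQ model — the closed-loop substitute for external alignment.
#'
#' @param exp an `sv_experiment` from [build_experiment()].
#' @param which `"tumor"` or `"control"`.
#' @param coverage physical coverage; defaults to the experiment config.
#' @param seed integer seed.
#' @return pair table in reference coordinates.
#' @export
simulate_experiment <- function(exp, which = c("tumor", "control"),
                                coverage = NULL, seed = 1L) {
  which <- match.arg(which)
  genome <- if (which == "tumor") exp$tumor_genome else exp$control_genome
  map <- if (which == "tumor") exp$tumor_map else exp$control_map
  coverage <- coverage %||%
    (if (which == "tumor") exp$config$coverage else exp$config$control_coverage)
  n <- pairs_for_coverage(coverage, exp$lib, sum(genome_lengths(genome)))
  scfg <- sim_config(n, seed = seed,
                     perfect_dup_rate = exp$config$perfect_dup_rate,
                     imperfect_dup_rate = exp$config$imperfect_dup_rate)
  frags <- simulate_pairs(genome, exp$lib, scfg)
  emit_truth_pairs(frags, map, exp$lib, mapq_model = exp$mapq_model,
                   ref_lengths = genome_lengths(exp$ref))
}

.write_experiment <- function(exp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "tracks"), showWarnings = FALSE)
  if (exp$config$preset == "dup-demo") {
    write_pairs_sam(exp$pairs, c(chrD = 20000L), file.path(dir, "tumor.sam"))
    jsonlite::write_json(list(preset = "dup-demo"), file.path(dir, "manifest.json"),
                         auto_unbox = TRUE)
    return(invisible(dir))
  }
  write_fasta(exp$ref, file.path(dir, "ref.fa"))
  write_fasta(exp$tumor_genome, file.path(dir, "tumor.fa"))
  write_fasta(exp$control_genome, file.path(dir, "control.fa"))
  write_plan(exp$plan, file.path(dir, "plan.tsv"))
  write_bedpe(exp$truth, file.path(dir, "truth.bedpe"))
  write_map_table(exp$tumor_map, file.path(dir, "tumor.liftover.tsv"))
  write_map_table(exp$control_map, file.path(dir, "control.liftover.tsv"))
  write_track(exp$tracks$lowmap, file.path(dir, "tracks", "lowmap.bed"))
  write_track(exp$tracks$repeats, file.path(dir, "tracks", "repeats.bed"))
  tum <- simulate_experiment(exp, "tumor", seed = exp$sim_seeds[1])
  ctl <- simulate_experiment(exp, "control", seed = exp$sim_seeds[2])
  write_pairs_sam(tum, genome_lengths(exp$ref), file.path(dir, "tumor.sam"))
  write_pairs_sam(ctl, genome_lengths(exp$ref), file.path(dir, "control.sam"))
  jsonlite::write_json(list(
    preset = exp$config$preset, seed = exp$seed, sim_seeds = exp$sim_seeds,
    coverage = exp$config$coverage, control_coverage = exp$config$control_coverage,
    n_truth = nrow(exp$truth),
    truth_ids = exp$truth$id, truth_origin = exp$truth$origin
  ), file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
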