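#' Tumor/control comparison
#'
#' Builds clusters from the (identically screened) control read pairs with a
#' relaxed support threshold — by default a single control read pair
#' suffices, since germline events often leave only one pair in a
#' lower-coverage control — and removes a tumor call when BOTH of its
#' anchors intersect the corresponding anchors of any control cluster,
#' ignoring SV type ("same SV type" comparison off).
#'
#' @param tumor_calls SV record table.
#' @param control_pairs screened control pair table (see [screen_pairs()]).
#' @param lib a [library_model()].
#' @param cfg a [filter_config()]; `control_min_support` is the control
#'   cluster support threshold.
#' @return `list(kept, removed_germline)` of SV record tables.
#' @export
compare_to_control <- function(tumor_calls, control_pairs, lib,
                               cfg = filter_config()) {
  ca <- as.data.table(tumor_calls)
  if (is.null(control_pairs)) {
    warnf("no control dataset: skipping tumor/control comparison")
    return(list(kept = ca, removed_germline = empty_calls()))
  }
  ctl <- cluster_pairs(control_pairs, lib, cfg)
  ctl <- ctl[support >= cfg$control_min_support]
  if (nrow(ca) == 0 || nrow(ctl) == 0)
    return(list(kept = ca, removed_germline = empty_calls()))
  germ <- vapply(seq_len(nrow(ca)), function(i) {
    x <- ca[i]
    any(ctl$chromA == x$chromA & ctl$chromB == x$chromB &
          ctl$startA < x$endA & x$startA < ctl$endA &
          ctl$startB < x$endB & x$startB < ctl$endB)
  }, logical(1))
  list(kept = ca[!germ], removed_germline = ca[germ])
}

#' Fraction of a call's anchors covered by a track
#'
#' covered bases of anchor A plus covered bases of anchor B, divided by the
#' summed anchor lengths.  With `per_anchor_max = TRUE` the maximum of the
#' two per-anchor fractions is returned instead.
#'
#' @param calls SV record table.
#' @param track merged `interval_track`.
#' @param per_anchor_max alternative denominator mode.
#' @return numeric vector in `[0, 1]` along the calls.
#' @export
overlap_fraction <- function(calls, track, per_anchor_max = FALSE) {
  x <- as.data.table(calls)
  if (nrow(x) == 0) return(numeric(0))
  lenA <- x$endA - x$startA
  lenB <- x$endB - x$startB
  if (any(lenA <= 0) || any(lenB <= 0)) stopf("zero-length anchor")
  covA <- covered_bases(x$chromA, x$startA, x$endA, track)
  covB <- covered_bases(x$chromB, x$startB, x$endB, track)
  if (per_anchor_max) pmax(covA / lenA, covB / lenB)
  else (covA + covB) / (lenA + lenB)
}

#' Repeat- and mappability-based call filtering
#'
#' Removes a call when any of the following holds (cutoffs inclusive for
#' removal):
#'
#' * low-mappability overlap >= 0.85 (intra-chromosomal) or >= 0.50
#'   (inter-chromosomal);
#' * simple-repeat overlap >= 0.50;
#' * the call is inter-chromosomal with 2 or 3 supporting pairs and its
#'   RepeatMasker overlap is >= 0.80 (RepeatMasker annotates many diverged,
#'   perfectly mappable elements, so it is applied only where false
#'   positives concentrate: weakly supported translocations).
#'
#' Empty or NULL tracks disable the corresponding criterion.
#'
#' @param calls SV record table.
#' @param lowmap,simple_repeats,repeat_masker `interval_track`s (or NULL).
#' @param cfg a [filter_config()].
#' @return `list(kept, removed)`; `removed` carries a `removed_by` column.
#' @export
filter_by_tracks <- function(calls, lowmap = NULL, simple_repeats = NULL,
                             repeat_masker = NULL, cfg = filter_config()) {
  x <- as.data.table(calls)
  if (nrow(x) == 0) return(list(kept = x, removed = empty_calls()))
  intra <- x$chromA == x$chromB
  why <- rep(NA_character_, nrow(x))
  if (!is.null(lowmap) && nrow(lowmap) > 0) {
    f <- overlap_fraction(x, lowmap)
    cut <- fifelse(intra, cfg$lowmap_cutoff_intra, cfg$lowmap_cutoff_inter)
    why[is.na(why) & f >= cut] <- "low_mappability"
  }
  if (!is.null(simple_repeats) && nrow(simple_repeats) > 0) {
    f <- overlap_fraction(x, simple_repeats)
    why[is.na(why) & f >= cfg$simple_repeat_cutoff] <- "simple_repeats"
  }
  if (!is.null(repeat_masker) && nrow(repeat_masker) > 0) {
    f <- overlap_fraction(x, repeat_masker)
    sel <- !intra & x$support %in% cfg$repeatmasker_support &
      f >= cfg$repeatmasker_cutoff
    why[is.na(why) & sel] <- "repeat_masker"
  }
  removed <- x[!is.na(why)]
  if (nrow(removed)) removed[, removed_by := why[!is.na(why)]]
  else removed <- empty_calls()
  list(kept = x[is.na(why)], removed = removed)
}

#' Size cutoffs for intra-chromosomal calls
#'
#' Removes deletions smaller than `del_min_size` (default 600 bp) and
#' duplications smaller than `dup_min_size` (default 300 bp) — calls that
#' more likely reflect the tails of the library fragment-size distribution
#' than real events.  Inversions and translocations pass through.
#'
#' @param calls SV record table.
#' @param cfg a [filter_config()].
#' @return `list(kept, removed)`.
#' @export
filter_by_size <- function(calls, cfg = filter_config()) {
  x <- as.data.table(calls)
  if (nrow(x) == 0) return(list(kept = x, removed = empty_calls()))
  rm <- (x$type == "deletion" & !is.na(x$size) & x$size < cfg$del_min_size) |
    (x$type == "duplication" & !is.na(x$size) & x$size < cfg$dup_min_size)
  list(kept = x[!rm], removed = x[rm])
}

#' Post-detection filter cascade
#'
#' Applies, in the published order: tumor/control comparison, low-mappability
#' overlap, simple-repeat overlap, then the "custom" stage (RepeatMasker on
#' weakly supported inter-chromosomal calls, and size cutoffs).  The report
#' records intra-/inter-chromosomal call counts after every stage; counts
#' are monotone non-increasing since every stage only removes.
#'
#' @param tumor_calls SV record table from [call_svs()].
#' @param control_pairs screened control pairs, or NULL to skip the stage.
#' @param tracks list with elements `lowmap`, `simple_repeats`,
#'   `repeat_masker` (each an `interval_track` or NULL).
#' @param lib a [library_model()].
#' @param cfg a [filter_config()].
#' @return `list(kept, report, removed)`: surviving calls (tagged
#'   `high_confidence` in a `confidence` column), per-stage count table, and
#'   a list of removed-call tables by stage.
#' @export
run_cascade <- function(tumor_calls, control_pairs, tracks = list(), lib,
                        cfg = filter_config()) {
  cur <- as.data.table(tumor_calls)
  removed <- list()
  count_row <- function(stage, x) {
    data.table(stage = stage,
               intra = sum(x$chromA == x$chromB),
               inter = sum(x$chromA != x$chromB),
               total = nrow(x))
  }
  report <- list(count_row("calls", cur))
  if (!is.null(control_pairs)) {
    res <- compare_to_control(cur, control_pairs, lib, cfg)
    removed$control <- res$removed_germline
    cur <- res$kept
  }
  report <- c(report, list(count_row("control", cur)))
  res <- filter_by_tracks(cur, lowmap = tracks$lowmap, cfg = cfg)
  removed$low_mappability <- res$removed
  cur <- res$kept
  report <- c(report, list(count_row("low_mappability", cur)))
  res <- filter_by_tracks(cur, simple_repeats = tracks$simple_repeats, cfg = cfg)
  removed$simple_repeats <- res$removed
  cur <- res$kept
  report <- c(report, list(count_row("simple_repeats", cur)))
  res <- filter_by_tracks(cur, repeat_masker = tracks$repeat_masker, cfg = cfg)
  sz <- filter_by_size(res$kept, cfg)
  removed$custom <- rbind(res$removed, sz$removed, fill = TRUE)
  cur <- sz$kept
  report <- c(report, list(count_row("custom", cur)))
  if (nrow(cur)) cur[, confidence := "high_confidence"]
  list(kept = cur, report = rbindlist(report), removed = removed)
}
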