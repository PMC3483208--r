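#' Filter configuration
#'
#' Every threshold of the detection and filtering method, in one place.
#' Defaults are the published operating point of the method:
#'
#' * `mq_min = 23` — a pair is kept only when both mates have BWA-style
#'   mapping quality >= 23 (the removed range is exactly 0-22);
#' * `sd_multiplier = 8` — a same-chromosome FR pair is discordant when its
#'   outer span deviates from the library mean by more than 8 SD;
#' * `min_support = 2` — minimum supporting read pairs per SV call;
#' * `min_anchor = 3` — minimum spread (bp) of mate start positions on each
#'   side of a cluster, which suppresses calls made purely from imperfect
#'   duplicate pile-ups;
#' * `dup_offset_max = 2` — two pairs are imperfect duplicates when both
#'   mates sit within 2 bp in the same orientation;
#' * overlap cutoffs for call removal: low-mappability 0.85
#'   (intra-chromosomal) / 0.50 (inter-chromosomal); simple repeats 0.50;
#'   RepeatMasker 0.80, applied only to inter-chromosomal calls with
#'   support 2-3;
#' * size cutoffs: deletions < 600 bp and duplications < 300 bp removed;
#' * `control_min_support = 1` — a single control read pair suffices to
#'   flag a tumor call as germline.
#'
#' All cutoffs are inclusive for the action they describe (e.g. an overlap
#' of at least 0.85 removes, a size of at least 600 retains).
#'
#' @param mq_min,sd_multiplier,min_support,min_anchor,dup_offset_max,lowmap_cutoff_intra,lowmap_cutoff_inter,simple_repeat_cutoff,repeatmasker_cutoff,repeatmasker_support,del_min_size,dup_min_size,control_min_support,cluster_dist see above;
#'   `cluster_dist = NULL` means "insert_mean + sd_multiplier * insert_sd".
#' @return a `filter_config` list.
#' @export
filter_config <- function(mq_min = 23L, sd_multiplier = 8, min_support = 2L,
                          min_anchor = 3L, dup_offset_max = 2L,
                          lowmap_cutoff_intra = 0.85, lowmap_cutoff_inter = 0.50,
                          simple_repeat_cutoff = 0.50, repeatmasker_cutoff = 0.80,
                          repeatmasker_support = c(2L, 3L),
                          del_min_size = 600L, dup_min_size = 300L,
                          control_min_support = 1L, cluster_dist = NULL) {
  if (mq_min < 0 || mq_min > 60) stopf("mq_min must be in [0, 60]")
  for (v in c(lowmap_cutoff_intra, lowmap_cutoff_inter, simple_repeat_cutoff,
              repeatmasker_cutoff))
    if (v < 0 || v > 1) stopf("overlap cutoffs must be in [0, 1]")
  structure(list(mq_min = as.integer(mq_min), sd_multiplier = sd_multiplier,
                 min_support = as.integer(min_support),
                 min_anchor = as.integer(min_anchor),
                 dup_offset_max = as.integer(dup_offset_max),
                 lowmap_cutoff_intra = lowmap_cutoff_intra,
                 lowmap_cutoff_inter = lowmap_cutoff_inter,
                 simple_repeat_cutoff = simple_repeat_cutoff,
                 repeatmasker_cutoff = repeatmasker_cutoff,
                 repeatmasker_support = as.integer(repeatmasker_support),
                 del_min_size = as.integer(del_min_size),
                 dup_min_size = as.integer(dup_min_size),
                 control_min_support = as.integer(control_min_support),
                 cluster_dist = cluster_dist),
            class = "filter_config")
}

.cluster_dist <- function(lib, cfg) {
  cfg$cluster_dist %||% (lib$insert_mean + cfg$sd_multiplier * lib$insert_sd)
}

#' Classify read pairs by SV signature
#'
#' Every mapped-mapped pair receives exactly one class:
#'
#' * different chromosomes — `translocation_signature`;
#' * same chromosome, FF or RR orientation — `inversion_signature`;
#' * same chromosome, RF orientation — `short_insert_signature`
#'   (tandem-duplication type);
#' * same chromosome, FR, outer span strictly greater than
#'   mean + k*SD — `del_signature`;
#' * FR with span strictly less than mean - k*SD — `short_insert_signature`
#'   (undersized fragments also arise from duplications);
#' * otherwise `concordant`.
#'
#' Pairs with an unmapped mate are `unusable`.  Orientation is read off the
#' canonically ordered mates (leftmost strand first), so FR means `+/-`.
#'
#' @param pairs pair table.
#' @param lib a [library_model()].
#' @param cfg a [filter_config()].
#' @return the pair table (copy) with a `pair_class` column.
#' @export
classify_pairs <- function(pairs, lib, cfg = filter_config()) {
  p <- canonicalize_pairs(pairs)
  if (nrow(p) == 0) {
    p[, pair_class := character(0)]
    return(p)
  }
  hi <- lib$insert_mean + cfg$sd_multiplier * lib$insert_sd
  lo <- lib$insert_mean - cfg$sd_multiplier * lib$insert_sd
  span <- p$posB + p$rlen - p$posA
  cls <- rep("concordant", nrow(p))
  ok <- p$mapped
  fr <- ok & p$strandA == "+" & p$strandB == "-"
  rf <- ok & p$strandA == "-" & p$strandB == "+"
  same <- ok & p$chromA == p$chromB
  span[!ok] <- 0L
  cls[same & !fr & !rf] <- "inversion_signature"
  cls[same & rf] <- "short_insert_signature"
  cls[same & fr & span > hi] <- "del_signature"
  cls[same & fr & span < lo] <- "short_insert_signature"
  cls[!same] <- "translocation_signature"
  cls[!p$mapped] <- "unusable"
  p[, pair_class := cls]
  p
}

#' Mapping-quality filter
#'
#' Keeps a pair iff *both* mates have MAPQ >= `mq_min` (removing a read
#' removes its pair).  Unmapped pairs are dropped here as well.
#'
#' @param pairs pair table.
#' @param cfg a [filter_config()].
#' @return filtered pair table; attribute `"n_removed"` counts removals.
#' @export
filter_mapq <- function(pairs, cfg = filter_config()) {
  p <- as.data.table(pairs)
  keep <- p$mapped & p$mapqA >= cfg$mq_min & p$mapqB >= cfg$mq_min
  out <- p[keep]
  setattr(out, "n_removed", sum(!keep))
  out
}

#' Remove perfect PCR duplicates
#'
#' Among pairs with identical (chromA, posA, strandA, chromB, posB, strandB)
#' exactly one representative is kept: the highest summed MAPQ, ties broken
#' by input order.
#'
#' @param pairs pair table.
#' @return de-duplicated pair table; attribute `"n_removed"`.
#' @export
remove_perfect_duplicates <- function(pairs) {
  p <- as.data.table(pairs)
  if (nrow(p) == 0) {
    setattr(p, "n_removed", 0L)
    return(p)
  }
  p[, `:=`(.ord = .I, summq = mapqA + mapqB)]
  setorder(p, chromA, posA, strandA, chromB, posB, strandB, -summq, .ord)
  keep <- !duplicated(p, by = c("chromA", "posA", "strandA",
                                "chromB", "posB", "strandB"))
  # unmapped pairs all share NA coordinates; never collapse them
  keep[!p$mapped] <- TRUE
  out <- p[keep]
  setorder(out, .ord)
  n_rm <- nrow(p) - nrow(out)
  out[, c(".ord", "summq") := NULL]
  setattr(out, "n_removed", n_rm)
  out
}

#' Remove imperfect PCR duplicates
#'
#' Two pairs are grouped when both mates have the same chromosome and
#' orientation and both mate offsets are at most `dup_offset_max` bp;
#' grouping is transitive (union-find), so chains of near-duplicates
#' collapse to one representative (highest summed MAPQ, ties by leftmost
#' position then input order).
#'
#' @param pairs pair table (perfect duplicates should be removed first for
#'   meaningful accounting; correctness does not depend on it).
#' @param cfg a [filter_config()].
#' @return de-duplicated pair table; attribute `"n_removed"`.
#' @export
remove_imperfect_duplicates <- function(pairs, cfg = filter_config()) {
  p <- as.data.table(pairs)
  if (nrow(p) <= 1) {
    setattr(p, "n_removed", 0L)
    return(copy(p))
  }
  d <- cfg$dup_offset_max
  p[, .ord := .I]
  mappedp <- p[mapped == TRUE]
  grp_cols <- c("chromA", "strandA", "chromB", "strandB")
  mappedp[, grp := .GRP, by = grp_cols]
  comp <- mappedp[, {
    e <- proximity_edges(posA, posB, d)
    cid <- uf_components(.N, e$from, e$to)
    list(.ord = .ord, comp = cid)
  }, by = grp]
  m <- merge(p, comp[, .(.ord, grp, comp)], by = ".ord", all.x = TRUE)
  m[, summq := mapqA + mapqB]
  setorder(m, grp, comp, -summq, posA, .ord, na.last = FALSE)
  keep <- is.na(m$grp) | !duplicated(m, by = c("grp", "comp"))
  out <- m[keep]
  setorder(out, .ord)
  n_rm <- nrow(p) - nrow(out)
  out[, c(".ord", "grp", "comp", "summq") := NULL]
  setattr(out, "n_removed", n_rm)
  out
}

#' Pre-detection screening of read pairs
#'
#' Applies, in order: removal of unmapped pairs (counted), perfect duplicate
#' removal, mapping-quality filtering, imperfect duplicate removal, and
#' classification.  Returns the screened discordant-analysis-ready table
#' plus library-statistics style accounting.
#'
#' @param pairs pair table (e.g. from [read_pairs_sam()] or
#'   [emit_truth_pairs()]).
#' @param lib a [library_model()].
#' @param cfg a [filter_config()].
#' @param dedup character subset of `c("perfect", "imperfect")`.
#' @return screened, classified pair table; attribute `"screen_stats"` is a
#'   list of category counts (total, unmapped, perfect/imperfect duplicates
#'   removed, low-MAPQ removed, anomalous same-chromosome, anomalous
#'   different-chromosome).
#' @export
screen_pairs <- function(pairs, lib, cfg = filter_config(),
                         dedup = c("perfect", "imperfect")) {
  p <- as.data.table(pairs)
  stats <- list(total = nrow(p), unmapped = sum(!p$mapped))
  p <- p[mapped == TRUE]
  if ("perfect" %in% dedup) {
    p <- remove_perfect_duplicates(p)
    stats$dup_perfect_removed <- attr(p, "n_removed")
  } else stats$dup_perfect_removed <- 0L
  p <- filter_mapq(p, cfg)
  stats$low_mapq_removed <- attr(p, "n_removed")
  if ("imperfect" %in% dedup) {
    p <- remove_imperfect_duplicates(p, cfg)
    stats$dup_imperfect_removed <- attr(p, "n_removed")
  } else stats$dup_imperfect_removed <- 0L
  p <- classify_pairs(p, lib, cfg)
  stats$anomalous_same_chrom <-
    sum(p$pair_class %in% c("del_signature", "short_insert_signature",
                            "inversion_signature"))
  stats$anomalous_diff_chrom <- sum(p$pair_class == "translocation_signature")
  stats$concordant <- sum(p$pair_class == "concordant")
  setattr(p, "screen_stats", stats)
  p
}
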