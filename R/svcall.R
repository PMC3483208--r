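#' Cluster discordant read pairs into SV candidates
#'
#' Two pairs of the same signature class join a cluster when their A-mates
#' lie within `d` bp of each other and their B-mates likewise, with matching
#' orientations on both sides; grouping is the transitive closure
#' (union-find).  The clustering distance defaults to
#' insert_mean + sd_multiplier * insert_sd, the same deviation threshold
#' used for classification.
#'
#' @param pairs screened, classified pair table (see [screen_pairs()]).
#' @param lib a [library_model()].
#' @param cfg a [filter_config()].
#' @return cluster `data.table`: class, chromosomes, anchor envelopes
#'   `[startA,endA) [startB,endB)` (min/max of mate intervals), per-side
#'   start-position spreads `widthA`/`widthB`, `support`, and the member
#'   `frag_id`s as a list column.
#' @export
cluster_pairs <- function(pairs, lib, cfg = filter_config()) {
  p <- as.data.table(pairs)
  if (!"pair_class" %in% names(p)) p <- classify_pairs(p, lib, cfg)
  disc <- p[pair_class %in% c("del_signature", "short_insert_signature",
                              "inversion_signature", "translocation_signature")]
  if (nrow(disc) == 0) {
    return(data.table(cluster_id = integer(0), pair_class = character(0),
                      chromA = character(0), startA = integer(0), endA = integer(0),
                      strandA = character(0),
                      chromB = character(0), startB = integer(0), endB = integer(0),
                      strandB = character(0),
                      widthA = integer(0), widthB = integer(0),
                      support = integer(0), members = list()))
  }
  d <- .cluster_dist(lib, cfg)
  disc[, grp := .GRP, by = .(pair_class, chromA, chromB, strandA, strandB)]
  comp <- disc[, {
    e <- proximity_edges(posA, posB, d)
    list(idx = .I, comp = uf_components(.N, e$from, e$to))
  }, by = grp]
  disc[comp$idx, cluster_id := comp$grp * 1e9 + comp$comp]
  cl <- disc[, .(
    pair_class = pair_class[1],
    chromA = chromA[1], startA = min(posA), endA = max(posA) + rlen[1],
    strandA = strandA[1],
    chromB = chromB[1], startB = min(posB), endB = max(posB) + rlen[1],
    strandB = strandB[1],
    widthA = max(posA) - min(posA), widthB = max(posB) - min(posB),
    support = .N, members = list(frag_id)
  ), by = cluster_id]
  cl[, cluster_id := seq_len(.N)]
  cl[]
}

#' Call structural variants from clusters
#'
#' A cluster becomes a call when its support is at least `min_support` and
#' the spread of mate start positions on *both* sides is at least
#' `min_anchor` bp (a cluster of imperfect duplicates collapses to a spread
#' of at most `dup_offset_max`, so it can never satisfy the default of 3).
#' Signature classes map to SV types: del -> deletion, short insert (RF or
#' undersized FR) -> duplication, FF/RR -> inversion, cross-chromosome ->
#' translocation.  Size is the inner distance between the two anchor
#' envelopes for intra-chromosomal calls; translocations carry no size.
#'
#' @param clusters output of [cluster_pairs()].
#' @param cfg a [filter_config()].
#' @return SV record table with `origin = "call"`.
#' @export
call_svs <- function(clusters, cfg = filter_config()) {
  cl <- as.data.table(clusters)
  keep <- cl$support >= cfg$min_support &
    cl$widthA >= cfg$min_anchor & cl$widthB >= cfg$min_anchor
  cl <- cl[keep]
  if (nrow(cl) == 0) return(empty_calls())
  type_map <- c(del_signature = "deletion", short_insert_signature = "duplication",
                inversion_signature = "inversion",
                translocation_signature = "translocation")
  # size from anchor geometry: deletion mates flank the lost segment (inner
  # distance); tandem-duplication mates face outward across the junction
  # (outer distance); inversion anchors shift in lockstep (start distance)
  typ <- unname(type_map[cl$pair_class])
  sz <- rep(NA_integer_, nrow(cl))
  intra <- cl$chromA == cl$chromB
  sz[intra & typ == "deletion"] <- pmax(cl$startB - cl$endA, 1L)[intra & typ == "deletion"]
  sz[intra & typ == "duplication"] <- pmax(cl$endB - cl$startA, 1L)[intra & typ == "duplication"]
  sz[intra & typ == "inversion"] <- pmax(cl$startB - cl$startA, 1L)[intra & typ == "inversion"]
  out <- cl[, .(
    id = sprintf("call%05d", .I), type = typ,
    chromA, startA, endA, strandA, chromB, startB, endB, strandB,
    size = sz, support, origin = "call"
  )]
  validate_calls(out)
}

#' Match calls against truth records
#'
#' A truth record is recovered when some call of the same type places its
#' anchors over the truth breakpoints: each truth breakpoint must lie within
#' the corresponding call anchor padded by `pad` bp (default: one insert
#' mean — anchors end flush at the breakpoint, and clustering cannot resolve
#' positions below fragment scale).  For translocation records, the strand
#' signature must also agree, which keeps the two junctions of a reciprocal
#' event distinct.
#'
#' @param calls SV record table (calls).
#' @param truth SV record table (truth; 1-bp anchors at breakpoints).
#' @param lib a [library_model()]; sets the default pad.
#' @param pad bp of slack around call anchors.
#' @return logical vector along `truth` rows; attribute `"match_idx"` gives
#'   the first matching call row (NA if none).
#' @export
match_calls_to_truth <- function(calls, truth, lib = library_model(),
                                 pad = NULL) {
  pad <- pad %||% lib$insert_mean
  tr <- as.data.table(truth)
  ca <- as.data.table(calls)
  hit <- logical(nrow(tr))
  idx <- rep(NA_integer_, nrow(tr))
  if (nrow(ca) == 0 || nrow(tr) == 0) {
    setattr(hit, "match_idx", idx)
    return(hit)
  }
  for (i in seq_len(nrow(tr))) {
    t <- tr[i]
    cand <- ca$type == t$type &
      ca$chromA == t$chromA & ca$chromB == t$chromB &
      ca$startA - pad <= t$startA & t$startA < ca$endA + pad &
      ca$startB - pad <= t$startB & t$startB < ca$endB + pad
    if (t$type == "translocation" && !is.na(t$strandA))
      cand <- cand & ca$strandA == t$strandA & ca$strandB == t$strandB
    if (any(cand)) {
      hit[i] <- TRUE
      idx[i] <- which(cand)[1]
    }
  }
  setattr(hit, "match_idx", idx)
  hit
}
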