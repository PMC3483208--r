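#' Track configuration
#'
#' Parameters of the mappability machinery: uniqueness is computed over
#' k-mers of the read length (k = window = 50 bp by default), windows whose
#' mean per-position score falls below 0.5 are "low mappability" (a score
#' below 0.5 means the k-mer occurs more than twice in the genome), and
#' breakpoint mappability is assessed over a flank of insert_mean - read_len
#' = 265 bp on each side of a breakpoint.
#'
#' @param window window size in bp.
#' @param uniqueness_threshold windows with mean score strictly below this
#'   are flagged.
#' @param flank bp examined on each side of a breakpoint.
#' @param kmer k-mer length; defaults to `window`.
#' @return a `track_config` list.
#' @export
track_config <- function(window = 50L, uniqueness_threshold = 0.5,
                         flank = 265L, kmer = window) {
  if (window <= 0) stopf("window must be > 0")
  if (uniqueness_threshold <= 0 || uniqueness_threshold > 1)
    stopf("uniqueness_threshold must be in (0, 1]")
  if (flank < window) stopf("flank must be >= window")
  structure(list(window = as.integer(window),
                 uniqueness_threshold = uniqueness_threshold,
                 flank = as.integer(flank), kmer = as.integer(kmer)),
            class = "track_config")
}

#' Genome-wide k-mer occurrence counts
#'
#' For every position i of every chromosome, the number of times the k-mer
#' starting at i occurs in the whole genome, counting both strands (a k-mer
#' and its reverse complement are the same key, since an aligner maps both
#' strands).  Positions within k-1 of a chromosome end have no count.
#'
#' @param genome an `sv_genome`.
#' @param k k-mer length.
#' @return named list of integer vectors; element `[[chrom]][i]` is the
#'   count for the k-mer starting at 0-based position i-1.
#' @export
kmer_occurrences <- function(genome, k) {
  if (k <= 0) stopf("k must be > 0")
  lens <- genome_lengths(genome)
  if (any(lens < k)) stopf("k exceeds the shortest chromosome")
  per_chrom <- lapply(names(genome), function(nm) {
    s <- genome[[nm]]
    n <- nchar(s) - k + 1L
    fwd <- substring(s, seq_len(n), seq_len(n) + k - 1L)
    rc <- substring(revcomp(s), seq_len(n), seq_len(n) + k - 1L)
    # reverse complement of the k-mer at i is the rc-string k-mer at n-i+1
    pmin(fwd, rev(rc))
  })
  all <- unlist(per_chrom, use.names = FALSE)
  m <- match(all, all)
  counts <- tabulate(m, nbins = length(all))[m]
  sizes <- lengths(per_chrom)
  out <- split(counts, rep.int(seq_along(sizes), sizes))
  names(out) <- names(genome)
  lapply(out, as.integer)
}

#' Per-position uniqueness scores
#'
#' `score(i) = 1 / occurrences(k-mer at i)`: 1 for unique positions, 0.5 for
#' two copies, below 0.5 for three or more ("occurs more than 2 times").
#'
#' @param genome an `sv_genome`.
#' @param k k-mer length.
#' @param occ optional precomputed [kmer_occurrences()].
#' @return named list of numeric score vectors.
#' @export
uniqueness_scores <- function(genome, k, occ = NULL) {
  occ <- occ %||% kmer_occurrences(genome, k)
  lapply(occ, function(o) 1 / o)
}

#' Interval tracks
#'
#' A track is a `data.table(chrom, start, end)` of 0-based half-open
#' intervals, sorted by (chrom, start) and free of overlaps, with a `name`
#' attribute.  BED input/output shifts coordinates by 0.
#'
#' @param dt interval table.
#' @param name track label.
#' @return merged, sorted `interval_track`.
#' @export
interval_track <- function(dt, name = "track") {
  x <- as.data.table(dt)
  if (nrow(x) == 0) {
    x <- data.table(chrom = character(0), start = integer(0), end = integer(0))
  } else {
    if (any(x$start < 0) || any(x$start >= x$end))
      stopf("track intervals must satisfy 0 <= start < end")
    x <- merge_intervals(x)
  }
  setattr(x, "track_name", name)
  setattr(x, "class", c("interval_track", class(x)))
  x
}

#' Merge overlapping or bookended intervals
#' @param dt `data.table(chrom, start, end)`.
#' @return merged table.
#' @export
merge_intervals <- function(dt) {
  x <- as.data.table(dt)[, .(chrom, start = as.integer(start), end = as.integer(end))]
  if (nrow(x) == 0) return(x)
  setorder(x, chrom, start, end)
  x[, grp := cumsum(start > shift(cummax(end), fill = -1L)), by = chrom]
  out <- x[, .(start = min(start), end = max(end)), by = .(chrom, grp)]
  out[, grp := NULL]
  out[]
}

#' Read a BED (3+ columns) file as an interval track
#' @param path BED file.
#' @param name track label.
#' @return `interval_track` (merged, sorted).
#' @export
read_track <- function(path, name = basename(path)) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0)
    return(interval_track(data.table(chrom = character(0), start = integer(0),
                                     end = integer(0)), name))
  f <- tstrsplit(lines, "\t", fixed = TRUE)
  if (length(f) < 3) stopf("BED needs >= 3 columns: %s", path)
  start <- suppressWarnings(as.integer(f[[2]]))
  end <- suppressWarnings(as.integer(f[[3]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stopf("malformed BED line %d in %s", bad[1], path)
  interval_track(data.table(chrom = f[[1]], start = start, end = end), name)
}

#' Write an interval track as BED3
#' @param track `interval_track`.
#' @param path output path.
#' @export
write_track <- function(track, path) {
  x <- as.data.table(track)
  if (nrow(x) == 0) writeLines(character(0), path)
  else writeLines(x[, sprintf("%s\t%d\t%d", chrom, start, end)], path)
  invisible(path)
}

#' Assemble the low-mappability track of a genome
#'
#' The genome is tiled into `window`-sized intervals; a window is low
#' mappability when the mean per-position uniqueness score inside it is
#' strictly below the threshold; adjacent flagged windows are merged.
#' Trailing positions without a score (within k-1 of the chromosome end)
#' are ignored in the window mean.
#'
#' @param genome an `sv_genome`.
#' @param cfg a [track_config()].
#' @param scores optional precomputed [uniqueness_scores()].
#' @return `interval_track` named "low_mappability".
#' @export
low_mappability_track <- function(genome, cfg = track_config(), scores = NULL) {
  scores <- scores %||% uniqueness_scores(genome, cfg$kmer)
  w <- cfg$window
  pieces <- lapply(names(genome), function(nm) {
    sc <- scores[[nm]]
    L <- nchar(genome[[nm]])
    nwin <- L %/% w
    if (nwin == 0) return(NULL)
    win <- rep(seq_len(nwin), each = w)[seq_len(min(nwin * w, length(sc)))]
    mu <- tapply(sc[seq_along(win)], win, mean)
    flag <- mu < cfg$uniqueness_threshold
    if (!any(flag)) return(NULL)
    idx <- which(flag)
    data.table(chrom = nm, start = (idx - 1L) * w, end = idx * w)
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  dt <- if (length(pieces)) rbindlist(pieces)
        else data.table(chrom = character(0), start = integer(0), end = integer(0))
  interval_track(dt, "low_mappability")
}

#' Breakpoint mappability
#'
#' Percentage of fully-unique windows among the `flank %/% window` windows
#' tiled outward from the breakpoint on each side (5 per side with the
#' defaults; the trailing 15 bp remainder of each 265 bp flank is dropped).
#' A window qualifies when *every* per-position score inside it equals 1.
#' Windows that run off the scored part of the chromosome are dropped from
#' the denominator and the result is flagged with attribute `"truncated"`.
#'
#' @param scores [uniqueness_scores()] of the genome.
#' @param chrom,breakpoint breakpoint location (0-based).
#' @param cfg a [track_config()].
#' @return percentage in `{0, 10, ..., 100}` for an untruncated flank pair.
#' @export
breakpoint_mappability <- function(scores, chrom, breakpoint, cfg = track_config()) {
  sc <- scores[[chrom]]
  if (is.null(sc)) stopf("no scores for chromosome '%s'", chrom)
  w <- cfg$window
  nwin <- cfg$flank %/% w
  starts <- c(breakpoint - seq_len(nwin) * w,           # left flank, inward-out
              breakpoint + (seq_len(nwin) - 1L) * w)    # right flank
  ok <- starts >= 0L & (starts + w) <= length(sc)
  qual <- vapply(starts[ok], function(s) all(sc[(s + 1L):(s + w)] == 1), logical(1))
  avail <- sum(ok)
  if (avail == 0) stopf("breakpoint %s:%d has no scorable window", chrom, breakpoint)
  res <- 100 * sum(qual) / avail
  if (avail < 2L * nwin) setattr(res, "truncated", TRUE)
  res
}

#' Mappability of an SV record's breakpoints
#'
#' For intra-chromosomal records, the flanks examined are those *outside*
#' the rearranged segment (left of the start breakpoint, right of the end
#' breakpoint) — the regions where anchoring mates must map.  For
#' translocation junction records, the left flank of anchor A's breakpoint
#' and the right flank of anchor B's (or as oriented by the record strands).
#'
#' @param scores [uniqueness_scores()] of the reference.
#' @param rec one-row SV record.
#' @param cfg a [track_config()].
#' @return percentage in `{0, 10, ..., 100}`.
#' @export
sv_breakpoint_mappability <- function(scores, rec, cfg = track_config()) {
  w <- cfg$window
  nwin <- cfg$flank %/% w
  side_windows <- function(chrom, bp, side) {
    if (side == "left") bp - seq_len(nwin) * w else bp + (seq_len(nwin) - 1L) * w
  }
  sideA <- if (!is.na(rec$strandA) && rec$strandA == "-") "right" else "left"
  sideB <- if (!is.na(rec$strandB) && rec$strandB == "+") "left" else "right"
  stA <- side_windows(rec$chromA, rec$startA, sideA)
  stB <- side_windows(rec$chromB, rec$startB, sideB)
  count_ok <- function(chrom, starts) {
    sc <- scores[[chrom]]
    ok <- starts >= 0L & (starts + w) <= length(sc)
    vapply(starts[ok], function(s) all(sc[(s + 1L):(s + w)] == 1), logical(1))
  }
  q <- c(count_ok(rec$chromA, stA), count_ok(rec$chromB, stB))
  100 * sum(q) / length(q)
}

#' Total bases of intervals covered by a track
#'
#' @param chrom,start,end parallel vectors of query intervals (0-based
#'   half-open).
#' @param track merged `interval_track`.
#' @return integer vector of covered base counts per query.
#' @export
covered_bases <- function(chrom, start, end, track) {
  t <- as.data.table(track)
  out <- integer(length(start))
  if (nrow(t) == 0 || length(start) == 0) return(out)
  for (nm in unique(chrom)) {
    sel <- which(chrom == nm)
    tt <- t[t$chrom == nm]
    if (nrow(tt) == 0) next
    q <- IRanges::IRanges(start[sel] + 1L, end[sel])
    s <- IRanges::IRanges(tt$start + 1L, tt$end)
    ov <- IRanges::findOverlaps(q, s)
    if (length(ov) == 0) next
    inter <- IRanges::pintersect(q[S4Vectors::queryHits(ov)],
                                 s[S4Vectors::subjectHits(ov)])
    covered <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
    out[sel[as.integer(names(covered))]] <- as.integer(covered)
  }
  out
}
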