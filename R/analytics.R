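#' Physical coverage
#'
#' Fold coverage counting the full DNA fragment span (both reads plus the
#' gap): `n_pairs * insert_mean / genome_size`.  `n_pairs` should count
#' mapped, non-duplicate pairs for an "effective" figure.
#'
#' @param n_pairs number of (effective) read pairs.
#' @param lib a [library_model()].
#' @param genome_size bp.
#' @return fold physical coverage.
#' @export
physical_coverage <- function(n_pairs, lib, genome_size) {
  if (genome_size <= 0) stopf("genome_size must be > 0")
  if (n_pairs < 0) stopf("n_pairs must be >= 0")
  n_pairs * lib$insert_mean / genome_size
}

#' Read pairs needed for a target physical coverage
#' @param coverage fold physical coverage.
#' @param lib a [library_model()].
#' @param genome_size bp.
#' @return integer pair count.
#' @export
pairs_for_coverage <- function(coverage, lib, genome_size) {
  as.integer(round(coverage * genome_size / lib$insert_mean))
}

#' Closed-form SV detection probability
#'
#' The expected number of read pairs that span a breakpoint with both mates
#' fully anchored and uniquely mapped is
#' `lambda = m * N * (mu - 2r) / G`: a fragment spans with both mates clear
#' of the junction when its start falls in a window of about `mu - 2r`
#' positions, and each such pair survives mapping-quality screening with
#' probability approximately the local mappability `m`.  Detection requires
#' at least `min_support` such pairs, so the probability is the Poisson tail
#' `P(X >= s)`, `X ~ Poisson(lambda)`.  The simpler `mu`-window variant is
#' available for comparison.
#'
#' @param n_pairs N, pairs sequenced.
#' @param genome_size G in bp.
#' @param lib a [library_model()].
#' @param mappability m in `[0, 1]`.
#' @param min_support s.
#' @param window `"inner"` (mu - 2r) or `"mu"`.
#' @return detection probability.
#' @export
detection_probability <- function(n_pairs, genome_size, lib = library_model(),
                                  mappability = 1, min_support = 2L,
                                  window = c("inner", "mu")) {
  window <- match.arg(window)
  if (mappability < 0 || mappability > 1) stopf("mappability must be in [0, 1]")
  if (genome_size <= 0) stopf("genome_size must be > 0")
  if (n_pairs == 0) return(0)
  w <- if (window == "inner") lib$insert_mean - 2 * lib$read_length else lib$insert_mean
  if (w <= 0) {
    warnf("insert_mean <= 2 * read_length: no fully-anchored spanning pairs")
    return(0)
  }
  lambda <- mappability * n_pairs * w / genome_size
  ppois(min_support - 1L, lambda, lower.tail = FALSE)
}

#' Library and dataset statistics
#'
#' Insert mean/SD estimated from concordant FR spans, a MAPQ histogram over
#' all mates, and per-category pair counts in the style of a sequencing-run
#' summary table (unmapped, duplicates flagged, anomalous same-chromosome,
#' anomalous different-chromosome).
#'
#' @param pairs pair table.
#' @param lib a [library_model()] used to classify concordant pairs.
#' @param cfg a [filter_config()].
#' @return list with `insert_mean`, `insert_sd`, `mapq_hist` (table),
#'   `counts` (list).
#' @export
library_stats <- function(pairs, lib = library_model(), cfg = filter_config()) {
  p <- classify_pairs(pairs, lib, cfg)
  conc <- p[pair_class == "concordant"]
  if (nrow(conc) == 0) stopf("no concordant pairs to estimate the insert size from")
  spans <- conc$posB + conc$rlen - conc$posA
  mq <- c(p$mapqA[p$mapped], p$mapqB[p$mapped])
  list(
    insert_mean = mean(spans),
    insert_sd = if (length(spans) > 1) sd(spans) else 0,
    mapq_hist = table(mq),
    counts = list(
      total = nrow(p),
      unmapped = sum(!p$mapped),
      duplicates = sum(!is.na(p$dup)),
      anomalous_same_chrom = sum(p$pair_class %in%
        c("del_signature", "short_insert_signature", "inversion_signature")),
      anomalous_diff_chrom = sum(p$pair_class == "translocation_signature")
    )
  )
}

#' Relative coverage per chromosome
#'
#' Bins fragment leftmost positions, normalises bin counts to a genome-wide
#' mean of 1, and reports the per-chromosome median relative depth — the
#' copy-number style view in which aneuploid chromosomes stand out.
#'
#' @param pairs pair table (mapped pairs are counted at `posA`).
#' @param genome `sv_genome` (defines bins).
#' @param bin_size bp per bin.
#' @return list: `bins` (data.table chrom/bin/start/n_frag/reldepth) and
#'   `chrom_median` (named vector).
#' @export
relative_coverage <- function(pairs, genome, bin_size = 10000L) {
  if (bin_size <= 0) stopf("bin_size must be > 0")
  lens <- genome_lengths(genome)
  bins <- rbindlist(lapply(names(lens), function(nm) {
    nb <- max(1L, as.integer(ceiling(lens[[nm]] / bin_size)))
    data.table(chrom = nm, bin = seq_len(nb), start = (seq_len(nb) - 1L) * bin_size)
  }))
  p <- as.data.table(pairs)
  p <- p[mapped == TRUE]
  if (nrow(p) == 0) {
    bins[, `:=`(n_frag = 0L, reldepth = 0)]
    return(list(bins = bins,
                chrom_median = setNames(rep(0, length(lens)), names(lens))))
  }
  cnt <- p[, .(n_frag = .N), by = .(chrom = chromA, bin = posA %/% bin_size + 1L)]
  bins <- merge(bins, cnt, by = c("chrom", "bin"), all.x = TRUE)
  bins[is.na(n_frag), n_frag := 0L]
  bins[, reldepth := n_frag / mean(n_frag)]
  med <- bins[, .(m = median(reldepth)), by = chrom]
  list(bins = bins[], chrom_median = setNames(med$m, med$chrom))
}
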