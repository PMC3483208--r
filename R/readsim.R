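#' Paired-end library model
#'
#' Defaults are the experimental library this pipeline was designed around:
#' 50 bp reads, 315 bp mean insert, 44 bp insert standard deviation.
#' "Insert size" throughout the package means the *outer* fragment length,
#' leftmost read start to rightmost read end.
#'
#' @param read_length read length r in bp.
#' @param insert_mean mean outer fragment length in bp.
#' @param insert_sd standard deviation of the fragment length in bp.
#' @return a `library_model` list.
#' @export
library_model <- function(read_length = 50L, insert_mean = 315, insert_sd = 44) {
  if (read_length <= 0) stopf("read_length must be > 0")
  if (insert_sd < 0) stopf("insert_sd must be >= 0")
  if (insert_mean < 2 * read_length)
    warnf("insert_mean < 2 * read_length: mates will overlap")
  structure(list(read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd),
            class = "library_model")
}

#' Simulation configuration
#'
#' @param n_pairs number of read pairs to draw.
#' @param seed integer seed; every source of randomness in a simulation run
#'   flows from it.
#' @param perfect_dup_rate fraction of the final library that consists of
#'   perfect PCR duplicates (identical fragment coordinates).
#' @param imperfect_dup_rate fraction consisting of imperfect duplicates
#'   (each mate independently offset by up to `imperfect_offset_max` bp,
#'   same orientation, at least one mate moved).
#' @param imperfect_offset_max maximum per-mate coordinate offset in bp.
#' @param base_quality constant Phred quality written to FASTQ (the method
#'   never uses base quality).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_pairs, seed = NULL, perfect_dup_rate = 0,
                       imperfect_dup_rate = 0, imperfect_offset_max = 2L,
                       base_quality = 30L) {
  if (n_pairs < 0) stopf("n_pairs must be >= 0")
  for (r in c(perfect_dup_rate, imperfect_dup_rate))
    if (r < 0 || r > 1) stopf("duplicate rates must be in [0, 1]")
  if (perfect_dup_rate + imperfect_dup_rate >= 1)
    stopf("duplicate rates must sum to < 1")
  if (imperfect_offset_max < 0) stopf("imperfect_offset_max must be >= 0")
  structure(list(n_pairs = as.integer(n_pairs), seed = seed,
                 perfect_dup_rate = perfect_dup_rate,
                 imperfect_dup_rate = imperfect_dup_rate,
                 imperfect_offset_max = as.integer(imperfect_offset_max),
                 base_quality = as.integer(base_quality)),
            class = "sim_config")
}

#' Simulate paired-end fragments from a genome
#'
#' Chromosomes are chosen with probability proportional to their length;
#' fragment starts are uniform over valid positions; fragment lengths are
#' Normal(mean, sd), rounded to the nearest integer and truncated below at
#' the read length.  Fragments that do not fit their chromosome (or that
#' contain an N run, if the genome has any Ns) are resampled; the resample
#' count is recorded in the `"sim_log"` attribute.  Read 1 is the first r
#' bases of the fragment (forward); read 2 is the reverse complement of the
#' last r bases (FR orientation).
#'
#' @param genome `sv_genome` to sample from (e.g. a derived tumor genome).
#' @param lib a [library_model()].
#' @param cfg a [sim_config()]; duplicate injection happens here when its
#'   rates are non-zero.
#' @param fastq_prefix if non-NULL, write `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq`.
#' @return truth fragment `data.table`: `frag_id, chrom, start, end, dup,
#'   orig_id` with coordinates on `genome` (the derived genome).
#' @export
simulate_pairs <- function(genome, lib, cfg, fastq_prefix = NULL) {
  r <- lib$read_length
  lens <- genome_lengths(genome)
  if (length(lens) == 0 || max(lens) < r)
    stopf("genome shorter than one read")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_pairs
  eligible <- lens >= r
  lens_e <- lens[eligible]
  n_resampled <- 0L
  if (n == 0) {
    truth <- data.table(frag_id = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        dup = character(0), orig_id = character(0))
  } else {
    ci <- sample.int(length(lens_e), n, replace = TRUE, prob = as.numeric(lens_e))
    fl <- pmax(r, as.integer(round(rnorm(n, lib$insert_mean, lib$insert_sd))))
    bad <- which(fl > lens_e[ci])
    while (length(bad)) {
      n_resampled <- n_resampled + length(bad)
      ci[bad] <- sample.int(length(lens_e), length(bad), replace = TRUE,
                            prob = as.numeric(lens_e))
      fl[bad] <- pmax(r, as.integer(round(rnorm(length(bad), lib$insert_mean,
                                                lib$insert_sd))))
      bad <- bad[fl[bad] > lens_e[ci[bad]]]
    }
    start <- as.integer(floor(runif(n) * (lens_e[ci] - fl + 1L)))
    truth <- data.table(frag_id = sprintf("frag%07d", seq_len(n)),
                        chrom = names(lens_e)[ci], start = start,
                        end = start + fl,
                        dup = NA_character_, orig_id = NA_character_)
    has_n <- any(vapply(genome, function(s) grepl("N", s, fixed = TRUE), logical(1)))
    if (has_n) {
      repeat {
        frs <- substring(genome[truth$chrom], truth$start + 1L, truth$end)
        bad <- which(grepl("N", frs, fixed = TRUE))
        if (!length(bad)) break
        n_resampled <- n_resampled + length(bad)
        ci2 <- sample.int(length(lens_e), length(bad), replace = TRUE,
                          prob = as.numeric(lens_e))
        fl2 <- pmax(r, as.integer(round(rnorm(length(bad), lib$insert_mean,
                                              lib$insert_sd))))
        fl2 <- pmin(fl2, lens_e[ci2])
        st2 <- as.integer(floor(runif(length(bad)) * (lens_e[ci2] - fl2 + 1L)))
        truth[bad, `:=`(chrom = names(lens_e)[ci2], start = st2, end = st2 + fl2)]
      }
    }
  }
  if (cfg$perfect_dup_rate > 0 || cfg$imperfect_dup_rate > 0)
    truth <- inject_duplicates(truth, cfg, chrom_lengths = lens)
  if (!is.null(fastq_prefix)) write_fastq_pairs(truth, genome, lib, cfg, fastq_prefix)
  setattr(truth, "sim_log", list(n_resampled = n_resampled))
  truth[]
}

#' Inject perfect and imperfect PCR duplicates into a truth stream
#'
#' Perfect duplicates copy the fragment coordinates exactly.  Imperfect
#' duplicates shift each fragment end independently by up to
#' `imperfect_offset_max` bp (same orientation), with at least one end moved
#' by >= 1 bp — the slippage/sequencing-error near-duplicates that escape
#' coordinate-identity de-duplication.  Rates are interpreted as fractions
#' of the *output* stream, so a rate of 0.091 yields about 9.1% duplicates.
#'
#' @param truth fragment table from [simulate_pairs()].
#' @param cfg a [sim_config()].
#' @param seed optional seed (defaults to continuing the current RNG stream).
#' @param chrom_lengths optional named lengths used to clamp shifted
#'   fragments inside their chromosome.
#' @return augmented truth table; duplicates carry `dup` in
#'   `c("perfect", "imperfect")` and `orig_id` pointing at their source.
#' @export
inject_duplicates <- function(truth, cfg, seed = NULL, chrom_lengths = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth)
  ptot <- cfg$perfect_dup_rate + cfg$imperfect_dup_rate
  if (n == 0 || ptot == 0) return(copy(truth))
  n_dup <- round(n * ptot / (1 - ptot))
  if (n_dup == 0) return(copy(truth))
  n_perf <- round(n_dup * cfg$perfect_dup_rate / ptot)
  n_imp <- n_dup - n_perf
  src <- truth[sample.int(n, n_dup, replace = TRUE)]
  dup_rows <- copy(src)
  dup_rows[, `:=`(orig_id = src$frag_id,
                  frag_id = sprintf("%s_dup%05d", src$frag_id, seq_len(n_dup)),
                  dup = c(rep("perfect", n_perf), rep("imperfect", n_imp)))]
  if (n_imp > 0) {
    m <- cfg$imperfect_offset_max
    off <- function(k) sample(seq(-m, m), k, replace = TRUE)
    dA <- off(n_imp); dB <- off(n_imp)
    zero <- dA == 0L & dB == 0L
    while (any(zero)) {
      dA[zero] <- off(sum(zero)); dB[zero] <- off(sum(zero))
      zero <- dA == 0L & dB == 0L
    }
    idx <- which(dup_rows$dup == "imperfect")
    dup_rows[idx, `:=`(start = start + dA, end = end + dB)]
    dup_rows[idx, start := pmax(start, 0L)]
    if (!is.null(chrom_lengths))
      dup_rows[idx, end := pmin(end, as.integer(chrom_lengths[chrom]))]
  }
  rbind(truth, dup_rows)
}

#' Write FASTQ for a truth stream
#' @keywords internal
write_fastq_pairs <- function(truth, genome, lib, cfg, prefix) {
  r <- lib$read_length
  qual <- paste(rep(rawToChar(as.raw(cfg$base_quality + 33L)), r), collapse = "")
  f1 <- paste0(prefix, "_R1.fastq")
  f2 <- paste0(prefix, "_R2.fastq")
  if (nrow(truth) == 0) {
    writeLines(character(0), f1); writeLines(character(0), f2)
    return(invisible(c(f1, f2)))
  }
  s1 <- substring(genome[truth$chrom], truth$start + 1L, truth$start + r)
  s2 <- revcomp(substring(genome[truth$chrom], truth$end - r + 1L, truth$end))
  l1 <- as.vector(rbind(paste0("@", truth$frag_id, "/1"), s1, "+", qual))
  l2 <- as.vector(rbind(paste0("@", truth$frag_id, "/2"), s2, "+", qual))
  writeLines(l1, f1); writeLines(l2, f2)
  invisible(c(f1, f2))
}

#' Build a mapping-quality model from reference k-mer occurrence counts
#'
#' The default model mirrors how a short-read aligner scores multi-mapping
#' reads: a mate whose read-length k-mer occurs exactly once in the
#' reference gets MAPQ 60, twice gets MAPQ 3, more than twice gets MAPQ 0.
#' Mates anchored across a rearrangement junction carry novel k-mers and get
#' MAPQ 60.  Real BAM/SAM input bypasses this model entirely.
#'
#' @param occ per-chromosome integer occurrence vectors from
#'   [kmer_occurrences()] on the *reference* genome.
#' @return function `(chrom, pos, spans_junction) -> integer MAPQ`.
#' @export
default_mapq_model <- function(occ) {
  force(occ)
  function(chrom, pos, spans_junction) {
    out <- rep(60L, length(pos))
    todo <- !spans_junction
    for (nm in unique(chrom[todo])) {
      sel <- which(todo & chrom == nm)
      o <- occ[[nm]]
      if (is.null(o)) stopf("no occurrence counts for chromosome '%s'", nm)
      idx <- pmin(pmax(pos[sel] + 1L, 1L), length(o))
      oc <- o[idx]
      out[sel] <- ifelse(oc <= 1L, 60L, ifelse(oc == 2L, 3L, 0L))
    }
    out
  }
}

#' Place simulated fragments as reference read-pair alignments
#'
#' Substitutes for an external aligner so the pipeline is closed: each mate
#' is placed at its true reference position via the derived-to-reference
#' liftover.  A mate overhanging a rearrangement junction by fewer than
#' `min_anchor` bases is anchored to the side carrying the rest of its
#' bases (a 1-2 bp overhang is invisible to an aligner), with its leftmost
#' position extrapolated so the anchored portion maps at its true location;
#' a mate with `min_anchor` or more bases on both sides of a junction is a
#' chimeric read that a gapped aligner fails to place, so its pair is
#' emitted as unmapped.  MAPQ comes from `mapq_model`; junction-anchored
#' mates carry novel k-mers and get MAPQ 60.
#'
#' @param truth fragment table from [simulate_pairs()] (derived coordinates).
#' @param map `genome_map` (or [map_table()] output) for liftover; NULL means
#'   the fragments already live on the reference.
#' @param lib a [library_model()].
#' @param mapq_model function from [default_mapq_model()], or NULL for a
#'   constant MAPQ 60.
#' @param ref_lengths named lengths of the reference chromosomes (for
#'   extrapolation clamping); required when `map` is NULL.
#' @param min_anchor bp a junction-spanning mate may overhang and still be
#'   anchored to its majority side.
#' @return pair table (see [pair_table]) in reference coordinates, carrying
#'   the truth duplicate labels.
#' @export
emit_truth_pairs <- function(truth, map, lib, mapq_model = NULL, ref_lengths = NULL,
                             min_anchor = 3L) {
  r <- lib$read_length
  n <- nrow(truth)
  if (is.null(map)) {
    if (is.null(ref_lengths)) stopf("ref_lengths required when map is NULL")
    mt <- data.table(dchrom = names(ref_lengths), dstart = 0L,
                     dend = as.integer(ref_lengths), src = names(ref_lengths),
                     sstart = 0L, send = as.integer(ref_lengths), strand = "+")
  } else {
    mt <- if (inherits(map, "genome_map")) map_table(map) else as.data.table(map)
  }
  ref_len <- if (!is.null(ref_lengths)) ref_lengths else {
    tapply(mt$send, mt$src, max)
  }
  lift_mate <- function(chrom, a, b, strand_in) {
    # a, b: derived half-open mate interval; returns ref chrom/pos/strand/mapq inputs
    out_chrom <- character(length(a)); out_pos <- integer(length(a))
    out_strand <- character(length(a)); spans <- logical(length(a))
    lost <- logical(length(a))
    for (nm in unique(chrom)) {
      sel <- which(chrom == nm)
      p <- mt[dchrom == nm]
      ia <- findInterval(a[sel], p$dstart)
      ib <- findInterval(b[sel] - 1L, p$dstart)
      same <- ia == ib
      # majority-side anchor for junction-overhanging mates; chimeric reads
      # (>= min_anchor bases on both sides) fail alignment
      use <- ia
      if (any(!same)) {
        left_bases <- p$dend[ia] - a[sel]          # bases on the first piece
        right_bases <- b[sel] - p$dstart[ib]       # bases on the last piece
        use[!same] <- ifelse(left_bases[!same] >= right_bases[!same],
                             ia[!same], ib[!same])
        lost[sel[!same]] <- pmin(left_bases[!same], right_bases[!same]) >= min_anchor
      }
      fw <- p$strand[use] == "+"
      # extrapolated leftmost ref position of the full-length mate
      pos <- ifelse(fw, p$sstart[use] + (a[sel] - p$dstart[use]),
                    p$send[use] - (b[sel] - p$dstart[use]))
      src <- p$src[use]
      pos <- pmax(pos, 0L)
      pos <- pmin(pos, as.integer(ref_len[src]) - r)
      out_chrom[sel] <- src
      out_pos[sel] <- as.integer(pos)
      out_strand[sel] <- ifelse(fw, strand_in, ifelse(strand_in == "+", "-", "+"))
      spans[sel] <- !same
    }
    list(chrom = out_chrom, pos = out_pos, strand = out_strand, spans = spans,
         lost = lost)
  }
  m1 <- lift_mate(truth$chrom, truth$start, truth$start + r, "+")
  m2 <- lift_mate(truth$chrom, truth$end - r, truth$end, "-")
  if (is.null(mapq_model)) {
    mq1 <- rep(60L, n); mq2 <- rep(60L, n)
  } else {
    mq1 <- mapq_model(m1$chrom, m1$pos, m1$spans)
    mq2 <- mapq_model(m2$chrom, m2$pos, m2$spans)
  }
  pairs <- data.table(
    frag_id = truth$frag_id,
    chromA = m1$chrom, posA = m1$pos, strandA = m1$strand, mapqA = mq1,
    chromB = m2$chrom, posB = m2$pos, strandB = m2$strand, mapqB = mq2,
    rlen = r, mapped = !(m1$lost | m2$lost),
    dup = truth$dup, orig_id = truth$orig_id
  )
  pairs[mapped == FALSE, `:=`(chromA = NA_character_, posA = NA_integer_,
                              chromB = NA_character_, posB = NA_integer_,
                              mapqA = 0L, mapqB = 0L)]
  canonicalize_pairs(pairs)
}

#' Emit a truth SAM file for simulated fragments
#'
#' Convenience wrapper: [emit_truth_pairs()] then [write_pairs_sam()].
#'
#' @inheritParams emit_truth_pairs
#' @param ref reference `sv_genome` (provides `@SQ` lengths).
#' @param path output SAM path.
#' @export
emit_truth_sam <- function(truth, map, ref, lib, path, mapq_model = NULL) {
  pairs <- emit_truth_pairs(truth, map, lib, mapq_model,
                            ref_lengths = genome_lengths(ref))
  write_pairs_sam(pairs, genome_lengths(ref), path)
  invisible(pairs)
}
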