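#' Read-pair alignment tables
#'
#' The central container of the pipeline is a `data.table` with one row per
#' read pair ("pair table"):
#'
#' * `frag_id` — fragment/pair identifier
#' * `chromA`, `posA`, `strandA`, `mapqA` — leftmost mate (0-based leftmost
#'   aligned position)
#' * `chromB`, `posB`, `strandB`, `mapqB` — rightmost mate
#' * `rlen` — read length in bp
#' * `mapped` — both mates mapped
#' * `dup`, `orig_id` — truth duplicate labels when the pairs come from the
#'   simulator (`NA` otherwise)
#'
#' Mates are stored in canonical order: `(chromA, posA) <= (chromB, posB)`
#' lexicographically, so FR/RF/FF/RR orientation is derived from the stored
#' strands, never stored redundantly.
#'
#' @name pair_table
NULL

#' Empty pair table with the canonical schema
#' @return zero-row pair `data.table`.
#' @export
empty_pairs <- function() {
  data.table(
    frag_id = character(0),
    chromA = character(0), posA = integer(0), strandA = character(0), mapqA = integer(0),
    chromB = character(0), posB = integer(0), strandB = character(0), mapqB = integer(0),
    rlen = integer(0), mapped = logical(0),
    dup = character(0), orig_id = character(0)
  )
}

#' Put mates of each pair in canonical order
#'
#' Swaps mates so that mate A is the leftmost by (chromosome name, position).
#' @param pairs pair table.
#' @return pair table (copy) with mates ordered.
#' @export
canonicalize_pairs <- function(pairs) {
  p <- copy(as.data.table(pairs))
  if (nrow(p) == 0) return(p)
  swap <- p$mapped & (p$chromB < p$chromA | (p$chromB == p$chromA & p$posB < p$posA))
  if (any(swap)) {
    sw <- function(a, b) {
      tmp <- p[[a]][swap]
      p[[a]][swap] <<- p[[b]][swap]
      p[[b]][swap] <<- tmp
    }
    sw("chromA", "chromB"); sw("posA", "posB")
    sw("strandA", "strandB"); sw("mapqA", "mapqB")
  }
  p
}

# SAM flag bits
.FLAG_PAIRED <- 1L
.FLAG_UNMAPPED <- 4L
.FLAG_MATE_UNMAPPED <- 8L
.FLAG_REVERSE <- 16L
.FLAG_MATE_REVERSE <- 32L
.FLAG_FIRST <- 64L
.FLAG_SECOND <- 128L

#' Write a pair table as SAM
#'
#' Minimal SAM 1.6: mate/flag/MAPQ information is preserved; sequences and
#' qualities are written as `*`.  Internal 0-based positions are shifted to
#' SAM's 1-based convention here and nowhere else.
#'
#' @param pairs pair table.
#' @param chrom_lengths named integer vector for the `@SQ` header lines.
#' @param path output path.
#' @export
write_pairs_sam <- function(pairs, chrom_lengths, path) {
  p <- as.data.table(pairs)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths), as.integer(chrom_lengths)))
  if (nrow(p) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  recs <- character(2L * nrow(p))
  mk <- function(first, chrom, pos, strand, mapq, ochrom, opos, ostrand, mapped, rlen, qname) {
    flag <- .FLAG_PAIRED + ifelse(first, .FLAG_FIRST, .FLAG_SECOND)
    flag <- flag + ifelse(mapped & strand == "-", .FLAG_REVERSE, 0L)
    flag <- flag + ifelse(mapped & ostrand == "-", .FLAG_MATE_REVERSE, 0L)
    flag <- flag + ifelse(!mapped, .FLAG_UNMAPPED + .FLAG_MATE_UNMAPPED, 0L)
    rname <- ifelse(mapped, chrom, "*")
    rnext <- ifelse(!mapped, "*", ifelse(ochrom == chrom, "=", ochrom))
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t*\t*",
            qname, flag, rname, ifelse(mapped, pos + 1L, 0L),
            ifelse(mapped, mapq, 0L),
            ifelse(mapped, paste0(rlen, "M"), "*"),
            rnext, ifelse(mapped, opos + 1L, 0L))
  }
  recs[c(TRUE, FALSE)] <- p[, mk(TRUE, chromA, posA, strandA, mapqA,
                                 chromB, posB, strandB, mapped, rlen, frag_id)]
  recs[c(FALSE, TRUE)] <- p[, mk(FALSE, chromB, posB, strandB, mapqB,
                                 chromA, posA, strandA, mapped, rlen, frag_id)]
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read mate-paired SAM records into a pair table
#'
#' One pair per primary record couple, joined on QNAME.  1-based SAM
#' positions become 0-based internal positions; strands come from flag bits;
#' mapping quality is preserved.  Orphan mates produce a warning and are
#' skipped; unsorted input is accepted.  Pairs with an unmapped mate are kept
#' with `mapped = FALSE` so screening can count them, but carry no
#' coordinates.
#'
#' @param path SAM file.
#' @return pair table; attribute `"sam_stats"` holds total/orphan counts.
#' @export
read_pairs_sam <- function(path) {
  if (!file.exists(path)) stopf("SAM file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) {
    out <- empty_pairs()
    setattr(out, "sam_stats", list(n_records = 0L, n_pairs = 0L, n_orphans = 0L))
    return(out)
  }
  f <- tstrsplit(lines, "\t", fixed = TRUE, keep = 1:9)
  rec <- data.table(
    qname = f[[1]], flag = as.integer(f[[2]]), rname = f[[3]],
    pos = as.integer(f[[4]]) - 1L, mapq = as.integer(f[[5]]), cigar = f[[6]]
  )
  rec[, `:=`(
    unmapped = bitwAnd(flag, .FLAG_UNMAPPED) > 0L,
    rev = bitwAnd(flag, .FLAG_REVERSE) > 0L,
    first = bitwAnd(flag, .FLAG_FIRST) > 0L
  )]
  # primary records only (ignore secondary 0x100 / supplementary 0x800)
  rec <- rec[bitwAnd(flag, 2304L) == 0L]
  cnt <- rec[, .N, by = qname]
  orphans <- cnt[N != 2L]
  if (nrow(orphans) > 0)
    warnf("skipping %d record(s) without a mate in %s", sum(orphans$N), basename(path))
  rec <- rec[qname %in% cnt[N == 2L, qname]]
  if (nrow(rec) == 0) {
    out <- empty_pairs()
  } else {
    setorder(rec, qname, -first)
    m1 <- rec[seq(1, .N, by = 2)]
    m2 <- rec[seq(2, .N, by = 2)]
    rl <- suppressWarnings(as.integer(sub("^([0-9]+)M.*$", "\\1", m1$cigar)))
    rl2 <- suppressWarnings(as.integer(sub("^([0-9]+)M.*$", "\\1", m2$cigar)))
    rl[is.na(rl)] <- rl2[is.na(rl)]
    rl[is.na(rl)] <- 0L
    out <- data.table(
      frag_id = m1$qname,
      chromA = m1$rname, posA = m1$pos, strandA = ifelse(m1$rev, "-", "+"), mapqA = m1$mapq,
      chromB = m2$rname, posB = m2$pos, strandB = ifelse(m2$rev, "-", "+"), mapqB = m2$mapq,
      rlen = rl,
      mapped = !(m1$unmapped | m2$unmapped),
      dup = NA_character_, orig_id = NA_character_
    )
    out[mapped == FALSE, `:=`(chromA = NA_character_, posA = NA_integer_,
                              chromB = NA_character_, posB = NA_integer_)]
    out <- canonicalize_pairs(out)
  }
  setattr(out, "sam_stats", list(
    n_records = length(lines), n_pairs = nrow(out), n_orphans = sum(orphans$N)
  ))
  out
}
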