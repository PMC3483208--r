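#' Derived genomes as piece lists
#'
#' A rearranged ("derived") genome is represented as an ordered list of
#' *pieces* per derived chromosome.  Each piece points at a reference
#' interval `[sstart, send)` on chromosome `src`, on strand `+` or `-`.
#' The derived sequence is the concatenation of the (reverse-complemented
#' where `-`) reference segments, so sequence construction and derived-to-
#' reference liftover are consistent by construction.
#'
#' @param genome reference `sv_genome`.
#' @return a `genome_map`: `list(ref = genome, pieces = <named list of
#'   data.tables with columns src, sstart, send, strand>)`.
#' @export
identity_map <- function(genome) {
  pieces <- lapply(names(genome), function(nm) {
    data.table(src = nm, sstart = 0L, send = nchar(genome[[nm]]), strand = "+")
  })
  names(pieces) <- names(genome)
  structure(list(ref = genome, pieces = pieces), class = "genome_map")
}

piece_widths <- function(p) p$send - p$sstart

#' Total length of each derived chromosome
#' @param map a `genome_map`.
#' @return named integer vector.
#' @export
derived_lengths <- function(map) {
  vapply(map$pieces, function(p) sum(piece_widths(p)), integer(1))
}

#' Materialise the derived genome sequence
#' @param map a `genome_map`.
#' @return an `sv_genome`.
#' @export
derive_genome <- function(map) {
  seqs <- vapply(map$pieces, function(p) {
    segs <- substring(map$ref[p$src], p$sstart + 1L, p$send)
    neg <- p$strand == "-"
    if (any(neg)) segs[neg] <- revcomp(segs[neg])
    paste(segs, collapse = "")
  }, character(1))
  sv_genome(seqs)
}

# Split the piece list of derived chromosome `dchrom` at reference position
# `refpos` of reference chromosome `chrom` (forward-strand pieces only).
# Returns list(pieces, idx) where idx is the index of the first piece at or
# after the cut.
.split_at_ref <- function(map, dchrom, chrom, refpos) {
  p <- map$pieces[[dchrom]]
  if (is.null(p)) stopf("no derived chromosome '%s'", dchrom)
  hit <- which(p$src == chrom & p$strand == "+" & p$sstart <= refpos & refpos <= p$send)
  if (length(hit) == 0)
    stopf("reference position %s:%d not found on derived chromosome %s",
          chrom, refpos, dchrom)
  i <- hit[1]
  if (refpos == p$sstart[i]) return(list(pieces = p, idx = i))
  if (refpos == p$send[i]) return(list(pieces = p, idx = i + 1L))
  top <- p[seq_len(i - 1L)]
  bot <- if (i < nrow(p)) p[seq(i + 1L, nrow(p))] else p[0]
  newp <- rbind(top,
                data.table(src = chrom, sstart = p$sstart[i], send = refpos, strand = "+"),
                data.table(src = chrom, sstart = refpos, send = p$send[i], strand = "+"),
                bot)
  list(pieces = newp, idx = i + 1L)
}

.edit_range <- function(map, chrom, s, e, action) {
  sp <- .split_at_ref(map, chrom, chrom, s)
  map$pieces[[chrom]] <- sp$pieces
  sp2 <- .split_at_ref(map, chrom, chrom, e)
  p <- sp2$pieces
  i <- sp$idx
  j <- sp2$idx - 1L
  if (j < i) stopf("empty edit range %s:[%d,%d)", chrom, s, e)
  inside <- p[i:j]
  if (any(inside$src != chrom | inside$strand != "+"))
    stopf("edit range %s:[%d,%d) overlaps a previous edit", chrom, s, e)
  top <- p[seq_len(i - 1L)]
  bot <- if (j < nrow(p)) p[seq(j + 1L, nrow(p))] else p[0]
  repl <- switch(action,
    delete = p[0],
    invert = data.table(src = chrom, sstart = s, send = e, strand = "-"),
    duplicate = rbind(inside, inside)
  )
  map$pieces[[chrom]] <- rbind(top, repl, bot)
  map
}

.apply_translocation <- function(map, c1, p1, c2, p2) {
  sp1 <- .split_at_ref(map, c1, c1, p1)
  map$pieces[[c1]] <- sp1$pieces
  sp2 <- .split_at_ref(map, c2, c2, p2)
  map$pieces[[c2]] <- sp2$pieces
  P1 <- map$pieces[[c1]]; P2 <- map$pieces[[c2]]
  head1 <- P1[seq_len(sp1$idx - 1L)]
  tail1 <- if (sp1$idx <= nrow(P1)) P1[seq(sp1$idx, nrow(P1))] else P1[0]
  head2 <- P2[seq_len(sp2$idx - 1L)]
  tail2 <- if (sp2$idx <= nrow(P2)) P2[seq(sp2$idx, nrow(P2))] else P2[0]
  map$pieces[[c1]] <- rbind(head1, tail2)
  map$pieces[[c2]] <- rbind(head2, tail1)
  map
}

.insert_segment <- function(map, target_chrom, pos, src_chrom, s, e, strand = "+") {
  if (e - s > nchar(map$ref[[target_chrom]]))
    stopf("donor segment longer than target chromosome %s", target_chrom)
  sp <- .split_at_ref(map, target_chrom, target_chrom, pos)
  p <- sp$pieces
  top <- p[seq_len(sp$idx - 1L)]
  bot <- if (sp$idx <= nrow(p)) p[seq(sp$idx, nrow(p))] else p[0]
  map$pieces[[target_chrom]] <-
    rbind(top, data.table(src = src_chrom, sstart = s, send = e, strand = strand), bot)
  map
}

#' SV plans
#'
#' A plan is a `data.table` with one row per planned edit (for reciprocal
#' translocations: one row per junction):
#'
#' * `id` — entry label (e.g. `"DEL 18"`, `"TR 15_12"`)
#' * `type` — `deletion`, `inversion`, `tandem_duplication`, `translocation`
#' * `chrom_a`, `pos_a` — for intra-chromosomal edits the edited chromosome
#'   and region start; for translocations the first junction partner
#' * `chrom_b`, `pos_b` — translocations only: second partner breakpoint
#' * `size` — bp of the edited region; `NA` for translocations
#'
#' @name sv_plan
NULL

.PLAN_TYPES <- c("deletion", "inversion", "tandem_duplication", "translocation")

#' Validate an SV plan
#' @param plan plan table (see [sv_plan]).
#' @param genome reference genome the plan applies to (bounds check), or NULL.
#' @return validated plan `data.table`.
#' @export
validate_plan <- function(plan, genome = NULL) {
  x <- as.data.table(plan)
  need <- c("id", "type", "chrom_a", "pos_a", "chrom_b", "pos_b", "size")
  miss <- setdiff(need, names(x))
  if (length(miss)) stopf("plan is missing column(s): %s", paste(miss, collapse = ", "))
  bad <- which(!x$type %in% .PLAN_TYPES)
  if (length(bad)) stopf("row %d: unknown plan type '%s'", bad[1], x$type[bad[1]])
  intra <- x$type != "translocation"
  bad <- which(intra & (is.na(x$size) | x$size <= 0))
  if (length(bad)) stopf("row %d: %s requires size > 0", bad[1], x$type[bad[1]])
  bad <- which(!intra & !is.na(x$size))
  if (length(bad)) stopf("row %d: translocation must have size '-'", bad[1])
  bad <- which(!intra & (is.na(x$chrom_b) | is.na(x$pos_b)))
  if (length(bad)) stopf("row %d: translocation needs both partners", bad[1])
  if (!is.null(genome)) {
    len <- genome_lengths(genome)
    bad <- which(!x$chrom_a %in% names(len) |
                   (!is.na(x$chrom_b) & !x$chrom_b %in% names(len)))
    if (length(bad)) stopf("row %d: unknown chromosome", bad[1])
    endp <- x$pos_a + fifelse(intra, as.integer(x$size), 0L)
    bad <- which(x$pos_a < 0 | endp > len[x$chrom_a] |
                   (!intra & (x$pos_b < 0 | x$pos_b > len[x$chrom_b])))
    if (length(bad)) stopf("row %d (%s): coordinates out of chromosome bounds",
                           bad[1], x$id[bad[1]])
    # overlap check among intra-chromosomal edit ranges
    iv <- x[x$type != "translocation", ]
    if (nrow(iv) > 1) {
      iv <- iv[order(iv$chrom_a, iv$pos_a), ]
      for (cc in unique(iv$chrom_a)) {
        sub <- iv[iv$chrom_a == cc, ]
        if (nrow(sub) < 2) next
        ends <- sub$pos_a + sub$size
        bad <- which(head(ends, -1) > tail(sub$pos_a, -1))
        if (length(bad))
          stopf("overlapping plan entries on %s: %s and %s",
                cc, sub$id[bad[1]], sub$id[bad[1] + 1L])
      }
    }
  }
  x
}

#' Read an SV plan from a tab-delimited table
#'
#' Columns: `id, type, chrom_a, pos_a, chrom_b, pos_b, size`; `-` marks an
#' absent value (allowed only for translocation size and partner fields of
#' intra-chromosomal edits).
#'
#' @param path TSV file.
#' @return plan `data.table`.
#' @export
plan_from_table <- function(path) {
  if (!file.exists(path)) stopf("plan file not found: %s", path)
  x <- fread(path, sep = "\t", header = TRUE, colClasses = list(character = 1:7),
             na.strings = NULL)
  for (cc in c("pos_a", "pos_b", "size")) {
    v <- x[[cc]]
    v[v == "-"] <- NA
    n <- suppressWarnings(as.integer(v))
    bad <- which(!is.na(v) & is.na(n))
    if (length(bad)) stopf("row %d: non-numeric %s '%s'", bad[1], cc, v[bad[1]])
    set(x, j = cc, value = n)
  }
  x[chrom_b == "-", chrom_b := NA_character_]
  validate_plan(x)
}

#' Write an SV plan to a tab-delimited table
#' @param plan plan table.
#' @param path output path.
#' @export
write_plan <- function(plan, path) {
  x <- as.data.table(plan)[, .(id, type, chrom_a, pos_a, chrom_b, pos_b, size)]
  out <- x[, lapply(.SD, function(v) {
    v <- as.character(v); v[is.na(v)] <- "-"; v
  })]
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Truth SV records implied by a plan
#'
#' Breakpoints are in reference coordinates; anchors are 1-bp intervals at
#' the breakpoints.  Translocation rows describe one junction each (a
#' reciprocal pair contributes two rows, one per direction); strand fields
#' record the expected orientation signature of supporting read pairs.
#'
#' @param plan validated plan table.
#' @param origin record origin label.
#' @return SV record table.
#' @export
truth_from_plan <- function(plan, origin = "truth") {
  x <- as.data.table(plan)
  if (nrow(x) == 0) return(empty_calls())
  recs <- lapply(seq_len(nrow(x)), function(i) {
    r <- x[i]
    if (r$type == "translocation") {
      data.table(id = r$id, type = "translocation",
                 chromA = r$chrom_a, startA = r$pos_a, endA = r$pos_a + 1L, strandA = "+",
                 chromB = r$chrom_b, startB = r$pos_b, endB = r$pos_b + 1L, strandB = "-",
                 size = NA_integer_, support = 0L, origin = origin)
    } else {
      e <- r$pos_a + r$size
      typ <- c(deletion = "deletion", inversion = "inversion",
               tandem_duplication = "duplication")[[r$type]]
      str <- switch(typ, deletion = c("+", "-"), duplication = c("-", "+"),
                    inversion = c(NA, NA))
      data.table(id = r$id, type = typ,
                 chromA = r$chrom_a, startA = r$pos_a, endA = r$pos_a + 1L, strandA = str[1],
                 chromB = r$chrom_a, startB = e, endB = e + 1L, strandB = str[2],
                 size = r$size, support = 0L, origin = origin)
    }
  })
  out <- rbindlist(recs)
  # canonical anchor order (relevant for translocation rows)
  swap <- out$chromA > out$chromB | (out$chromA == out$chromB & out$startA > out$startB)
  if (any(swap)) {
    tmp <- out[swap, .(chromA, startA, endA, strandA)]
    out[swap, `:=`(chromA = chromB, startA = startB, endA = endB, strandA = strandB)]
    out[swap, `:=`(chromB = tmp$chromA, startB = tmp$startA,
                   endB = tmp$endA, strandB = tmp$strandA)]
  }
  out[]
}

#' Apply an SV plan to a genome
#'
#' Intra-chromosomal edits are applied right-to-left per chromosome so that
#' earlier reference coordinates stay valid; overlapping edits are rejected,
#' not resolved.  Translocations are applied last, as reciprocal joins: a
#' pair of rows `(c1,p1,c2,p2)` and `(c2,p2,c1,p1)` describes one reciprocal
#' event (both junctions); an unpaired row produces a one-sided join.
#'
#' @param genome reference `sv_genome`.
#' @param plan plan table.
#' @param map optional starting `genome_map` (e.g. one already carrying
#'   germline insertions); defaults to the identity map of `genome`.
#' @return `list(genome = derived sv_genome, truth = SV record table,
#'   map = genome_map)`.
#' @export
apply_plan <- function(genome, plan, map = NULL) {
  plan <- validate_plan(plan, genome)
  map <- map %||% identity_map(genome)
  intra <- plan[type != "translocation"]
  if (nrow(intra)) {
    setorder(intra, chrom_a, -pos_a)
    for (i in seq_len(nrow(intra))) {
      r <- intra[i]
      action <- switch(r$type, deletion = "delete", inversion = "invert",
                       tandem_duplication = "duplicate")
      map <- .edit_range(map, r$chrom_a, r$pos_a, r$pos_a + r$size, action)
    }
  }
  tl <- plan[type == "translocation"]
  if (nrow(tl)) {
    key1 <- paste(tl$chrom_a, tl$pos_a, tl$chrom_b, tl$pos_b)
    key2 <- paste(tl$chrom_b, tl$pos_b, tl$chrom_a, tl$pos_a)
    done <- rep(FALSE, nrow(tl))
    for (i in seq_len(nrow(tl))) {
      if (done[i]) next
      partner <- which(!done & key2 == key1[i])
      partner <- setdiff(partner, i)
      map <- .apply_translocation(map, tl$chrom_a[i], tl$pos_a[i],
                                  tl$chrom_b[i], tl$pos_b[i])
      done[i] <- TRUE
      if (length(partner)) done[partner[1]] <- TRUE
    }
  }
  list(genome = derive_genome(map), truth = truth_from_plan(plan), map = map)
}

#' Flatten a genome map for liftover
#'
#' @param map a `genome_map`.
#' @return `data.table` with one row per piece: derived chromosome, derived
#'   interval `[dstart, dend)`, source chromosome/interval/strand.
#' @export
map_table <- function(map) {
  rbindlist(lapply(names(map$pieces), function(nm) {
    p <- map$pieces[[nm]]
    w <- piece_widths(p)
    data.table(dchrom = nm, dstart = cumsum(c(0L, head(w, -1))),
               dend = cumsum(w), src = p$src, sstart = p$sstart,
               send = p$send, strand = p$strand)
  }))
}

#' Lift derived-genome positions to reference coordinates
#'
#' @param map a `genome_map` (or the `data.table` from [map_table()]).
#' @param chrom derived chromosome names (vector).
#' @param pos derived 0-based positions (vector).
#' @return `data.table(chrom_r, pos_r, strand)`; strand is the strand of the
#'   piece a position falls in (`-` means the derived base is the reverse
#'   complement of the reference base).
#' @export
liftover <- function(map, chrom, pos) {
  mt <- if (inherits(map, "genome_map")) map_table(map) else as.data.table(map)
  out <- data.table(chrom_r = NA_character_, pos_r = NA_integer_,
                    strand = NA_character_)[rep(1L, length(pos))]
  for (nm in unique(chrom)) {
    sel <- which(chrom == nm)
    p <- mt[dchrom == nm]
    if (nrow(p) == 0) stopf("no derived chromosome '%s' in map", nm)
    idx <- findInterval(pos[sel], p$dstart)
    bad <- idx < 1L | pos[sel] >= p$dend[pmin(idx, nrow(p))]
    if (any(bad)) stopf("position out of range on derived chromosome %s", nm)
    off <- pos[sel] - p$dstart[idx]
    fw <- p$strand[idx] == "+"
    out$chrom_r[sel] <- p$src[idx]
    out$pos_r[sel] <- ifelse(fw, p$sstart[idx] + off, p$send[idx] - 1L - off)
    out$strand[sel] <- p$strand[idx]
  }
  out
}

#' Write a liftover table to TSV
#' @param map a `genome_map`.
#' @param path output path.
#' @export
write_map_table <- function(map, path) {
  fwrite(map_table(map), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a liftover table written by [write_map_table()]
#' @param path TSV file.
#' @return flattened map `data.table` usable by [liftover()].
#' @export
read_map_table <- function(path) {
  x <- fread(path, sep = "\t", header = TRUE)
  need <- c("dchrom", "dstart", "dend", "src", "sstart", "send", "strand")
  if (!all(need %in% names(x))) stopf("not a liftover table: %s", path)
  x
}

#' Inject germline retroelement / retrogene insertions
#'
#' Emulates strain-background germline events that masquerade as somatic SVs
#' when a sample is compared against the reference:
#'
#' * a retroelement copy inserted on *another* chromosome produces a false
#'   balanced-translocation pattern;
#' * a copy inserted on the *same* chromosome produces a false deletion
#'   pattern;
#' * a retrogene (exons of a donor gene concatenated and inserted elsewhere)
#'   produces one translocation pattern plus one deletion pattern per intron.
#'
#' @param map `genome_map` to edit (shared by tumor and control genomes).
#' @param artifacts list of artifact specs.  Each element is a list with
#'   `kind = "retroelement"` (`src_chrom`, `src_start`, `src_end`,
#'   `target_chrom`, `target_pos`) or `kind = "retrogene"` (`src_chrom`,
#'   `exons` = 2-column matrix of 0-based half-open exon intervals,
#'   `target_chrom`, `target_pos`).
#' @return `list(map, truth)`; truth records carry `origin = "germline"`.
#' @export
inject_germline_artifacts <- function(map, artifacts) {
  truth <- list()
  for (k in seq_along(artifacts)) {
    a <- artifacts[[k]]
    if (a$kind == "retroelement") {
      map <- .insert_segment(map, a$target_chrom, a$target_pos,
                             a$src_chrom, a$src_start, a$src_end)
      if (a$target_chrom != a$src_chrom) {
        rec <- data.table(id = sprintf("germ_re_%d", k), type = "translocation",
                          chromA = a$target_chrom, startA = a$target_pos,
                          endA = a$target_pos + 1L, strandA = "+",
                          chromB = a$src_chrom, startB = a$src_start,
                          endB = a$src_end, strandB = "-",
                          size = NA_integer_, support = 0L, origin = "germline")
      } else {
        # the deletion-signature junction joins the donor's end to the
        # insertion site (forward mates in the donor copy, reverse mates
        # downstream of the insertion point)
        rec <- data.table(id = sprintf("germ_re_%d", k), type = "deletion",
                          chromA = a$src_chrom, startA = a$src_end,
                          endA = a$src_end + 1L, strandA = "+",
                          chromB = a$target_chrom, startB = a$target_pos,
                          endB = a$target_pos + 1L, strandB = "-",
                          size = abs(a$target_pos - a$src_end),
                          support = 0L, origin = "germline")
      }
      truth[[length(truth) + 1L]] <- rec
    } else if (a$kind == "retrogene") {
      ex <- a$exons
      stopifnot(is.matrix(ex), ncol(ex) == 2, nrow(ex) >= 2)
      pos <- a$target_pos
      # repeated insertion at one reference position stacks segments before
      # the previous ones, so insert exons in reverse to keep genomic order
      for (j in rev(seq_len(nrow(ex)))) {
        map <- .insert_segment(map, a$target_chrom, a$target_pos,
                               a$src_chrom, ex[j, 1], ex[j, 2])
      }
      truth[[length(truth) + 1L]] <-
        data.table(id = sprintf("germ_rg_%d", k), type = "translocation",
                   chromA = a$target_chrom, startA = pos, endA = pos + 1L, strandA = "+",
                   chromB = a$src_chrom, startB = ex[1, 1], endB = ex[nrow(ex), 2],
                   strandB = "-", size = NA_integer_, support = 0L, origin = "germline")
      for (j in seq_len(nrow(ex) - 1L)) {
        intron <- c(ex[j, 2], ex[j + 1L, 1])
        truth[[length(truth) + 1L]] <-
          data.table(id = sprintf("germ_rg_%d_intron_%d", k, j), type = "deletion",
                     chromA = a$src_chrom, startA = intron[1], endA = intron[1] + 1L,
                     strandA = "+",
                     chromB = a$src_chrom, startB = intron[2], endB = intron[2] + 1L,
                     strandB = "-", size = intron[2] - intron[1],
                     support = 0L, origin = "germline")
      }
    } else {
      stopf("unknown germline artifact kind '%s'", a$kind)
    }
  }
  tr <- if (length(truth)) rbindlist(truth) else empty_calls()
  # canonical anchor order
  if (nrow(tr)) {
    swap <- tr$chromA > tr$chromB | (tr$chromA == tr$chromB & tr$startA > tr$startB)
    if (any(swap)) {
      tmp <- tr[swap, .(chromA, startA, endA, strandA)]
      tr[swap, `:=`(chromA = chromB, startA = startB, endA = endB, strandA = strandB)]
      tr[swap, `:=`(chromB = tmp$chromA, startB = tmp$startA,
                    endB = tmp$endA, strandB = tmp$strandA)]
    }
  }
  list(map = map, truth = tr)
}
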