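#' SV record tables
#'
#' SV records (truth entries and calls share one schema) live in a
#' `data.table` with columns:
#'
#' * `id` — record identifier
#' * `type` — one of `deletion`, `duplication`, `inversion`, `translocation`
#' * `chromA`, `startA`, `endA`, `strandA` — first anchor (0-based half-open;
#'   truth breakpoints are 1-bp anchors)
#' * `chromB`, `startB`, `endB`, `strandB` — second anchor
#' * `size` — bp, `NA` for translocations
#' * `support` — supporting read-pair count (0 for truth records)
#' * `origin` — `"truth"`, `"germline"` or `"call"`
#'
#' Anchors are ordered: `(chromA, startA) <= (chromB, startB)`.
#'
#' @name sv_records
NULL

.SV_TYPES <- c("deletion", "duplication", "inversion", "translocation")

#' Empty SV record table
#' @return zero-row record `data.table`.
#' @export
empty_calls <- function() {
  data.table(
    id = character(0), type = character(0),
    chromA = character(0), startA = integer(0), endA = integer(0), strandA = character(0),
    chromB = character(0), startB = integer(0), endB = integer(0), strandB = character(0),
    size = integer(0), support = integer(0), origin = character(0)
  )
}

#' Validate an SV record table
#' @param calls record table.
#' @return the validated table (invisibly modified to canonical column order).
#' @export
validate_calls <- function(calls) {
  x <- as.data.table(calls)
  if (nrow(x) == 0) return(x)
  if (!all(x$type %in% .SV_TYPES))
    stopf("unknown SV type(s): %s", paste(setdiff(unique(x$type), .SV_TYPES), collapse = ", "))
  if (any(x$startA >= x$endA) || any(x$startB >= x$endB))
    stopf("zero- or negative-length anchor(s)")
  bad <- x$chromA > x$chromB | (x$chromA == x$chromB & x$startA > x$startB)
  if (any(bad))
    stopf("anchor order violation in record(s): %s", paste(x$id[bad], collapse = ", "))
  if (any(!is.na(x$size) & x$size <= 0)) stopf("size must be > 0 when present")
  if (any(x$support < 0)) stopf("support must be >= 0")
  x
}

#' Write SV records as 10-column BEDPE
#'
#' Both anchors are written 0-based half-open (BEDPE native convention, so
#' no coordinate shift).  The name column carries `type;id;size;origin` so a
#' round trip preserves every record field; the score column carries the
#' supporting-pair count.
#'
#' @param calls record table.
#' @param path output path.
#' @export
write_bedpe <- function(calls, path) {
  x <- validate_calls(calls)
  if (nrow(x) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- x[, sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t%d\t%s\t%s",
                       chromA, startA, endA, chromB, startB, endB,
                       paste(type, id, ifelse(is.na(size), ".", as.character(size)),
                             origin, sep = ";"),
                       support,
                       ifelse(is.na(strandA), ".", strandA),
                       ifelse(is.na(strandB), ".", strandB))]
  writeLines(lines, path)
  invisible(path)
}

#' Read a BEDPE file written by [write_bedpe()]
#' @param path BEDPE file.
#' @return SV record table.
#' @export
read_bedpe <- function(path) {
  if (!file.exists(path)) stopf("BEDPE file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(empty_calls())
  f <- tstrsplit(lines, "\t", fixed = TRUE)
  if (length(f) < 10) stopf("BEDPE needs 10 columns, found %d", length(f))
  meta <- tstrsplit(f[[7]], ";", fixed = TRUE)
  if (length(meta) < 4) stopf("malformed BEDPE name column (expect type;id;size;origin)")
  x <- data.table(
    id = meta[[2]], type = meta[[1]],
    chromA = f[[1]], startA = as.integer(f[[2]]), endA = as.integer(f[[3]]),
    strandA = ifelse(f[[9]] == ".", NA_character_, f[[9]]),
    chromB = f[[4]], startB = as.integer(f[[5]]), endB = as.integer(f[[6]]),
    strandB = ifelse(f[[10]] == ".", NA_character_, f[[10]]),
    size = suppressWarnings(as.integer(ifelse(meta[[3]] == ".", NA, meta[[3]]))),
    support = as.integer(f[[8]]),
    origin = meta[[4]]
  )
  validate_calls(x)
}
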