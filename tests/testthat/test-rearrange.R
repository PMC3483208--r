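toy <- function(len = 10000L, seed = 1) random_genome(c(chrT = len), seed)

test_that("empty plan leaves the genome unchanged", {
  g <- toy()
  res <- apply_plan(g, data.table::data.table(
    id = character(0), type = character(0), chrom_a = character(0),
    pos_a = integer(0), chrom_b = character(0), pos_b = integer(0),
    size = integer(0)))
  expect_identical(unclass(res$genome), unclass(g))
  expect_identical(nrow(res$truth), 0L)
})

test_that("deletion equals concatenated flanks (string oracle)", {
  g <- toy()
  plan <- data.table::data.table(id = "d", type = "deletion", chrom_a = "chrT",
                                 pos_a = 2000L, chrom_b = NA_character_,
                                 pos_b = NA_integer_, size = 1000L)
  res <- apply_plan(g, plan)
  expect_identical(nchar(res$genome[["chrT"]]), 9000L)
  expect_identical(res$genome[["chrT"]],
                   paste0(substr(g[["chrT"]], 1, 2000), substr(g[["chrT"]], 3001, 10000)))
})

test_that("inversion is the reverse complement in place; duplication doubles", {
  g <- toy()
  inv <- apply_plan(g, data.table::data.table(
    id = "i", type = "inversion", chrom_a = "chrT", pos_a = 4000L,
    chrom_b = NA_character_, pos_b = NA_integer_, size = 500L))
  s <- inv$genome[["chrT"]]
  expect_identical(nchar(s), 10000L)
  expect_identical(substr(s, 4001, 4500), revcomp(substr(g[["chrT"]], 4001, 4500)))
  expect_identical(substr(s, 1, 4000), substr(g[["chrT"]], 1, 4000))

  dup <- apply_plan(g, data.table::data.table(
    id = "u", type = "tandem_duplication", chrom_a = "chrT", pos_a = 7000L,
    chrom_b = NA_character_, pos_b = NA_integer_, size = 300L))
  s2 <- dup$genome[["chrT"]]
  expect_identical(nchar(s2), 10300L)
  expect_identical(substr(s2, 7001, 7300), substr(s2, 7301, 7600))
})

test_that("reciprocal translocation swaps tails and conserves total length", {
  g <- random_genome(c(c1 = 8000L, c2 = 6000L), seed = 2)
  plan <- data.table::data.table(
    id = c("TR a_b", "TR b_a"), type = "translocation",
    chrom_a = c("c1", "c2"), pos_a = c(3000L, 2000L),
    chrom_b = c("c2", "c1"), pos_b = c(2000L, 3000L), size = NA_integer_)
  res <- apply_plan(g, plan)
  expect_identical(res$genome[["c1"]],
                   paste0(substr(g[["c1"]], 1, 3000), substr(g[["c2"]], 2001, 6000)))
  expect_identical(res$genome[["c2"]],
                   paste0(substr(g[["c2"]], 1, 2000), substr(g[["c1"]], 3001, 8000)))
  expect_identical(sum(nchar(res$genome)), sum(nchar(g)))
  expect_identical(nrow(res$truth), 2L)
})

test_that("derived length bookkeeping: ref - deleted + duplicated", {
  g <- random_genome(c(c1 = 20000L, c2 = 20000L), seed = 3)
  plan <- data.table::data.table(
    id = c("d1", "u1", "i1"), type = c("deletion", "tandem_duplication", "inversion"),
    chrom_a = c("c1", "c1", "c2"), pos_a = c(2000L, 9000L, 5000L),
    chrom_b = NA_character_, pos_b = NA_integer_,
    size = c(1500L, 700L, 900L))
  res <- apply_plan(g, plan)
  expect_identical(sum(derived_lengths(res$map)), 40000L - 1500L + 700L)
  expect_identical(sum(nchar(res$genome)), 40000L - 1500L + 700L)
})

test_that("liftover round-trips non-breakpoint positions", {
  exp <- minimal_exp()
  set.seed(9)
  lens <- derived_lengths(exp$tumor_map)
  for (nm in names(lens)) {
    pos <- sort(sample.int(lens[[nm]], 50) - 1L)
    lifted <- liftover(exp$tumor_map, rep(nm, 50), pos)
    # forward map: derived base must equal (strand-adjusted) reference base
    dbase <- unname(substring(exp$tumor_genome[[nm]], pos + 1L, pos + 1L))
    rbase <- unname(substring(exp$ref[lifted$chrom_r], lifted$pos_r + 1L,
                              lifted$pos_r + 1L))
    flip <- lifted$strand == "-"
    rbase[flip] <- chartr("ACGT", "TGCA", rbase[flip])
    expect_identical(dbase, rbase)
  }
})

test_that("plan table I/O round-trips and rejects inconsistent rows", {
  plan <- table1_plan()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_plan(plan, f)
  back <- plan_from_table(f)
  expect_equal(as.data.frame(back), as.data.frame(plan))

  bad <- data.table::copy(plan)[1, size := 0L]
  write_plan(bad, f)
  expect_error(plan_from_table(f), "size > 0")

  writeLines(c("id\ttype\tchrom_a\tpos_a\tchrom_b\tpos_b\tsize",
               "D1\tdeletion\tchr1\toops\t-\t-\t100"), f)
  expect_error(plan_from_table(f), "row 1")
})

test_that("plan validation rejects out-of-bounds and overlapping edits", {
  g <- toy()
  oob <- data.table::data.table(id = "d", type = "deletion", chrom_a = "chrT",
                                pos_a = 9500L, chrom_b = NA_character_,
                                pos_b = NA_integer_, size = 1000L)
  expect_error(apply_plan(g, oob), "bounds")
  ovl <- data.table::data.table(
    id = c("d1", "d2"), type = "deletion", chrom_a = "chrT",
    pos_a = c(2000L, 2500L), chrom_b = NA_character_, pos_b = NA_integer_,
    size = c(1000L, 1000L))
  expect_error(apply_plan(g, ovl), "overlap")
})

test_that("germline artifacts produce the documented false-SV patterns", {
  g <- random_genome(c(cA = 50000L, cB = 50000L), seed = 4)
  re <- inject_germline_artifacts(identity_map(g), list(
    list(kind = "retroelement", src_chrom = "cA", src_start = 1000L,
         src_end = 2200L, target_chrom = "cB", target_pos = 30000L)))
  expect_identical(nrow(re$truth), 1L)
  expect_identical(re$truth$type, "translocation")
  expect_identical(re$truth$origin, "germline")
  expect_identical(sum(nchar(derive_genome(re$map))), 100000L + 1200L)

  rg <- inject_germline_artifacts(identity_map(g), list(
    list(kind = "retrogene", src_chrom = "cA",
         exons = matrix(c(10000L, 10400L, 13000L, 13300L, 16000L, 16500L,
                          19000L, 19250L), ncol = 2, byrow = TRUE),
         target_chrom = "cB", target_pos = 40000L)))
  expect_identical(sum(rg$truth$type == "translocation"), 1L)
  expect_identical(sum(rg$truth$type == "deletion"), 3L)  # one per intron
  # inserted sequence is the exon concatenation, in order
  ins <- substr(derive_genome(rg$map)[["cB"]], 40001, 40000 + 1450)
  expect_identical(ins, paste0(substr(g[["cA"]], 10001, 10400),
                               substr(g[["cA"]], 13001, 13300),
                               substr(g[["cA"]], 16001, 16500),
                               substr(g[["cA"]], 19001, 19250)))

  none <- inject_germline_artifacts(identity_map(g), list())
  expect_identical(unclass(derive_genome(none$map)), unclass(g))
  expect_identical(nrow(none$truth), 0L)
})
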