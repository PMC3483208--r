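test_that("degenerate simulations behave: n = 0 and sigma = 0", {
  g <- random_genome(c(c1 = 1000L), seed = 1)
  lib0 <- suppressWarnings(library_model(50, 300, 0))
  pre <- withr::local_tempfile()
  t0 <- simulate_pairs(g, lib0, sim_config(0, seed = 1), fastq_prefix = pre)
  expect_identical(nrow(t0), 0L)
  expect_identical(readLines(paste0(pre, "_R1.fastq")), character(0))
  expect_identical(readLines(paste0(pre, "_R2.fastq")), character(0))

  tr <- simulate_pairs(g, lib0, sim_config(200, seed = 2), fastq_prefix = pre)
  expect_true(all(tr$end - tr$start == 300L))
  r1 <- readLines(paste0(pre, "_R1.fastq"))
  r2 <- readLines(paste0(pre, "_R2.fastq"))
  expect_true(all(nchar(r1[c(FALSE, TRUE, FALSE, FALSE)]) == 50L))
  # R2 is the reverse complement of the fragment's last 50 bases
  i <- 5  # arbitrary pair
  frag <- substr(g[["c1"]], tr$start[i] + 1L, tr$end[i])
  expect_identical(r2[(i - 1) * 4 + 2], revcomp(substr(frag, 251, 300)))
  expect_identical(r1[(i - 1) * 4 + 2], substr(frag, 1, 50))
})

test_that("chromosomes are sampled proportional to length", {
  g <- random_genome(c(big = 9000L, small = 1000L), seed = 3)
  tr <- simulate_pairs(g, library_model(50, 300, 30), sim_config(10000, seed = 4))
  frac <- mean(tr$chrom == "big")
  ci <- qbinom(c(0.005, 0.995), 10000, 0.9) / 10000
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
  # chi-square goodness of fit does not reject at alpha = 0.01
  obs <- table(factor(tr$chrom, levels = c("big", "small")))
  pval <- chisq.test(obs, p = c(0.9, 0.1))$p.value
  expect_gt(pval, 0.01)
})

test_that("insert sizes are calibrated: mean/SD and KS shape at n = 1e5", {
  g <- random_genome(c(c1 = 1000000L), seed = 5)
  lib <- library_model()
  tr <- simulate_pairs(g, lib, sim_config(100000, seed = 6))
  ins <- tr$end - tr$start
  expect_lt(abs(mean(ins) - 315), 1)
  expect_lt(abs(sd(ins) - 44), 1)
  # de-rounding jitter: fragment lengths are integers, the model is continuous
  set.seed(7)
  ks <- ks.test(ins + runif(length(ins), -0.5, 0.5), "pnorm", 315, 44)
  expect_gt(ks$p.value, 0.01)
})

test_that("fixed seed gives byte-identical FASTQ output", {
  g <- random_genome(c(c1 = 50000L), seed = 8)
  lib <- library_model()
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  simulate_pairs(g, lib, sim_config(500, seed = 99, perfect_dup_rate = 0.05),
                 fastq_prefix = p1)
  simulate_pairs(g, lib, sim_config(500, seed = 99, perfect_dup_rate = 0.05),
                 fastq_prefix = p2)
  expect_identical(readLines(paste0(p1, "_R1.fastq")), readLines(paste0(p2, "_R1.fastq")))
  expect_identical(readLines(paste0(p1, "_R2.fastq")), readLines(paste0(p2, "_R2.fastq")))
})

test_that("duplicate injection hits the configured output fraction", {
  g <- random_genome(c(c1 = 500000L), seed = 10)
  cfg <- sim_config(50000, seed = 11, perfect_dup_rate = 0.091)
  tr <- simulate_pairs(g, library_model(), cfg)
  frac <- mean(!is.na(tr$dup))
  expect_lt(abs(frac - 0.091), 0.005)

  cfg0 <- sim_config(1000, seed = 12)
  tr0 <- simulate_pairs(g, library_model(), cfg0)
  expect_identical(nrow(tr0), 1000L)
  expect_true(all(is.na(tr0$dup)))

  # imperfect duplicates: every mate offset at most 2 bp, at least one moved
  cfg2 <- sim_config(2000, seed = 13, imperfect_dup_rate = 0.2)
  tr2 <- simulate_pairs(g, library_model(), cfg2)
  dups <- tr2[!is.na(tr2$dup)]
  orig <- tr2[match(dups$orig_id, tr2$frag_id)]
  dA <- abs(dups$start - orig$start)
  dB <- abs(dups$end - orig$end)
  expect_true(all(dA <= 2L & dB <= 2L))
  expect_true(all(dA + dB >= 1L))
})

test_that("truth pairs carry correct spans across a deletion (arithmetic oracle)", {
  g <- random_genome(c(c1 = 30000L), seed = 14)
  lib0 <- suppressWarnings(library_model(50, 400, 0))
  res <- apply_plan(g, data.table::data.table(
    id = "d", type = "deletion", chrom_a = "c1", pos_a = 10000L,
    chrom_b = NA_character_, pos_b = NA_integer_, size = 2000L))
  tr <- simulate_pairs(res$genome, lib0, sim_config(2000, seed = 15))
  pairs <- emit_truth_pairs(tr, res$map, lib0, ref_lengths = genome_lengths(g))
  pairs <- pairs[pairs$mapped, ]
  span <- pairs$posB + pairs$rlen - pairs$posA
  # every mapped pair whose fragment fully straddles the deletion junction
  # (both mates clear of it) has reference span = insert + deletion size
  m <- tr[match(pairs$frag_id, tr$frag_id)]
  full <- m$start + 50 <= 10000 & m$end - 50 >= 10000       # both mates clear
  onesided <- m$end <= 10000 | m$start >= 10000             # no junction contact
  expect_true(any(full))
  expect_true(all(span[full] == 400L + 2000L))
  expect_true(all(span[onesided] == 400L))
  # remaining mapped pairs have a 1-2 bp anchored overhang: depending on the
  # anchor side they look like the straddling pair (2400) or concordant (400),
  # in either case within 2 bp of the exact figure
  rest <- span[!full & !onesided]
  expect_true(all(pmin(abs(rest - 2400L), abs(rest - 400L)) <= 2L))
})

test_that("multi-copy reads get MAPQ 0 under the k-mer model", {
  set.seed(16)
  unit <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  g <- random_genome(c(c1 = 20000L, c2 = 20000L), seed = 17)
  raw <- unclass(g)
  substr(raw[["c1"]], 5001, 5300) <- unit
  substr(raw[["c1"]], 12001, 12300) <- unit
  substr(raw[["c2"]], 8001, 8300) <- unit
  g3 <- sv_genome(raw)
  occ <- kmer_occurrences(g3, 50)
  model <- default_mapq_model(occ)
  expect_identical(model("c1", 5100L, FALSE), 0L)       # 3 copies
  expect_identical(model("c1", 100L, FALSE), 60L)       # unique
  expect_identical(model("c1", 5100L, TRUE), 60L)       # junction-anchored
})

test_that("chimeric junction reads are lost; small overhangs are anchored", {
  g <- random_genome(c(c1 = 30000L), seed = 18)
  lib0 <- suppressWarnings(library_model(50, 400, 0))
  res <- apply_plan(g, data.table::data.table(
    id = "d", type = "deletion", chrom_a = "c1", pos_a = 10000L,
    chrom_b = NA_character_, pos_b = NA_integer_, size = 2000L))
  # mate 1 occupies [start, start+50): overhang over the junction at
  # derived position 10000 varies with start
  tr <- data.table::data.table(
    frag_id = sprintf("f%d", 1:4),
    chrom = "c1",
    start = c(9952L, 9960L, 9998L, 9000L),  # overhang 2 / 10 / 48(minority 2) / none
    dup = NA_character_, orig_id = NA_character_)
  tr[, end := start + 400L]
  pairs <- emit_truth_pairs(tr, res$map, lib0, ref_lengths = genome_lengths(g))
  expect_identical(pairs$mapped, c(TRUE, FALSE, TRUE, TRUE))
  # overhang 2: anchored left at its true position
  expect_identical(pairs$posA[1], 9952L)
  # minority side 2 on the left: anchored right of the junction (ref 12000),
  # extrapolated so the anchored bases sit at their true reference position
  expect_identical(pairs$posA[3], 12000L - 2L)
})
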