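lib <- library_model()
cfg <- filter_config()

mk_call <- function(id, type, chromA, startA, endA, chromB, startB, endB,
                    size = NA_integer_, support = 5L) {
  data.table::data.table(
    id = id, type = type, chromA = chromA, startA = as.integer(startA),
    endA = as.integer(endA), strandA = "+", chromB = chromB,
    startB = as.integer(startB), endB = as.integer(endB), strandB = "-",
    size = as.integer(size), support = as.integer(support), origin = "call")
}

test_that("overlap_fraction matches the per-base bitmap oracle", {
  track <- interval_track(data.table::data.table(
    chrom = "chr1", start = c(1000L, 5000L, 9000L), end = c(1700L, 5030L, 12000L)))
  set.seed(61)
  for (i in 1:25) {
    sA <- sample.int(90000L, 1); sB <- sample.int(90000L, 1)
    call <- mk_call("x", "deletion", "chr1", sA, sA + 100L, "chr1", sB, sB + 400L)
    f <- overlap_fraction(call, track)
    want <- (bitmap_covered("chr1", sA, sA + 100L, track) +
               bitmap_covered("chr1", sB, sB + 400L, track)) / 500
    expect_equal(f, want)
  }
  # 70 of 100 + 30 of 100 anchor bases covered -> 0.5
  tr2 <- interval_track(data.table::data.table(
    chrom = "chr1", start = c(0L, 1000L), end = c(70L, 1030L)))
  expect_equal(overlap_fraction(
    mk_call("y", "deletion", "chr1", 0, 100, "chr1", 1000, 1100), tr2), 0.5)
  expect_equal(overlap_fraction(
    mk_call("z", "deletion", "chr1", 40000, 40100, "chr1", 50000, 50100), tr2), 0)
  full <- interval_track(data.table::data.table(chrom = "chr1", start = 0L,
                                                end = 100000L))
  expect_equal(overlap_fraction(
    mk_call("w", "deletion", "chr1", 10, 110, "chr1", 500, 600), full), 1)
})

test_that("low-mappability cutoffs are inclusive and intra/inter specific", {
  # anchors 100+100 bp; covered 170 of 200 -> 0.85 exactly
  t85 <- interval_track(data.table::data.table(
    chrom = "chr1", start = c(0L, 1000L), end = c(100L, 1070L)))
  intra <- mk_call("a", "deletion", "chr1", 0, 100, "chr1", 1000, 1100)
  expect_identical(filter_by_tracks(intra, lowmap = t85, cfg = cfg)$kept[, .N], 0L)
  # 169/200 = 0.845 < 0.85 -> kept
  t849 <- interval_track(data.table::data.table(
    chrom = "chr1", start = c(0L, 1000L), end = c(100L, 1069L)))
  expect_identical(filter_by_tracks(intra, lowmap = t849, cfg = cfg)$kept[, .N], 1L)
  # inter-chromosomal cutoff is 0.50
  inter <- mk_call("b", "translocation", "chr1", 0, 100, "chr2", 1000, 1100)
  t50 <- interval_track(data.table::data.table(chrom = "chr1", start = 0L, end = 100L))
  expect_identical(filter_by_tracks(inter, lowmap = t50, cfg = cfg)$kept[, .N], 0L)
  t49 <- interval_track(data.table::data.table(chrom = "chr1", start = 0L, end = 99L))
  expect_identical(filter_by_tracks(inter, lowmap = t49, cfg = cfg)$kept[, .N], 1L)
})

test_that("RepeatMasker applies only to inter-chromosomal support 2-3", {
  rm_track <- interval_track(data.table::data.table(
    chrom = c("chr1", "chr2"), start = 0L, end = 100000L))
  hit <- function(support, type = "translocation", chromB = "chr2") {
    call <- mk_call("r", type, "chr1", 0, 100, chromB, 1000, 1100,
                    support = support,
                    size = if (type == "deletion") 900L else NA_integer_)
    nrow(filter_by_tracks(call, repeat_masker = rm_track, cfg = cfg)$kept)
  }
  expect_identical(hit(2L), 0L)
  expect_identical(hit(3L), 0L)
  expect_identical(hit(4L), 1L)   # support 4: RepeatMasker not applied
  expect_identical(hit(2L, type = "deletion", chromB = "chr1"), 1L)  # intra exempt
})

test_that("simple-repeat cutoff removes at 0.50 or greater", {
  sr <- interval_track(data.table::data.table(chrom = "chr1", start = 0L, end = 100L))
  half <- mk_call("s", "inversion", "chr1", 0, 100, "chr1", 1000, 1100)
  expect_identical(filter_by_tracks(half, simple_repeats = sr, cfg = cfg)$kept[, .N], 0L)
  less <- mk_call("s2", "inversion", "chr1", 1, 101, "chr1", 1000, 1100)
  expect_identical(filter_by_tracks(less, simple_repeats = sr, cfg = cfg)$kept[, .N], 1L)
  # all tracks empty: untouched
  res <- filter_by_tracks(half, cfg = cfg)
  expect_identical(nrow(res$kept), 1L)
})

test_that("size cutoffs: deletions 600, duplications 300, others exempt", {
  calls <- rbind(
    mk_call("d599", "deletion", "chr1", 0, 100, "chr1", 650, 750, size = 599L),
    mk_call("d600", "deletion", "chr1", 0, 100, "chr1", 650, 750, size = 600L),
    mk_call("u299", "duplication", "chr1", 0, 100, "chr1", 300, 400, size = 299L),
    mk_call("u300", "duplication", "chr1", 0, 100, "chr1", 300, 400, size = 300L),
    mk_call("tl", "translocation", "chr1", 0, 100, "chr2", 300, 400),
    mk_call("inv", "inversion", "chr1", 0, 100, "chr1", 200, 300, size = 150L))
  res <- filter_by_size(calls, cfg)
  expect_setequal(res$kept$id, c("d600", "u300", "tl", "inv"))
  expect_setequal(res$removed$id, c("d599", "u299"))
})

test_that("control comparison removes germline calls at the support boundary", {
  exp <- germline_exp()
  tum <- simulate_experiment(exp, "tumor", seed = 62)
  ctl <- simulate_experiment(exp, "control", seed = 63)
  scr_t <- screen_pairs(tum, exp$lib, cfg)
  scr_c <- screen_pairs(ctl, exp$lib, cfg)
  calls <- call_svs(cluster_pairs(scr_t, exp$lib, cfg), cfg)
  truth <- as.data.table(exp$truth)
  res <- compare_to_control(calls, scr_c, exp$lib, cfg)
  # all germline-pattern calls gone, somatic truth intact
  expect_identical(sum(match_calls_to_truth(res$kept, truth[origin == "germline"],
                                            exp$lib)), 0L)
  expect_true(all(match_calls_to_truth(res$kept, truth[origin == "truth"], exp$lib)))
  expect_true(all(match_calls_to_truth(calls, truth[origin == "truth"], exp$lib)))

  # a germline event with exactly one supporting control pair is removed at
  # control_min_support 1 but kept at 2
  germ_call <- mk_call("g", "deletion", "chr1", 1000, 1300, "chr1", 9000, 9300,
                       size = 8000L)
  one_ctl <- data.table::data.table(
    frag_id = "c1", chromA = "chr1", posA = 1100L, strandA = "+", mapqA = 60L,
    chromB = "chr1", posB = 9100L, strandB = "-", mapqB = 60L, rlen = 50L,
    mapped = TRUE, dup = NA_character_, orig_id = NA_character_)
  one_ctl <- classify_pairs(one_ctl, exp$lib, cfg)
  r1 <- compare_to_control(germ_call, one_ctl, exp$lib, cfg)
  expect_identical(nrow(r1$kept), 0L)
  cfg2 <- filter_config(control_min_support = 2L)
  r2 <- compare_to_control(germ_call, one_ctl, exp$lib, cfg2)
  expect_identical(nrow(r2$kept), 1L)

  # missing control: stage skipped with a warning
  expect_warning(r3 <- compare_to_control(germ_call, NULL, exp$lib, cfg),
                 "control")
  expect_identical(nrow(r3$kept), 1L)
})

test_that("cascade counts are monotone and stages idempotent", {
  exp <- germline_exp()
  tum <- simulate_experiment(exp, "tumor", seed = 64)
  ctl <- simulate_experiment(exp, "control", seed = 65)
  res <- sv_pipeline(tum, ctl, tracks = list(lowmap = exp$tracks$lowmap), exp$lib, cfg)
  counts <- res$report$total
  expect_true(all(diff(counts[-1]) <= 0))  # post-detection stages only remove
  # final kept set = somatic truth exactly (precision 1 on labels)
  truth <- as.data.table(exp$truth)
  expect_true(all(match_calls_to_truth(res$kept, truth[origin == "truth"], exp$lib)))
  expect_identical(sum(match_calls_to_truth(res$kept, truth[origin == "germline"],
                                            exp$lib)), 0L)
  # track and size filters are idempotent on their own output
  kept1 <- filter_by_tracks(res$calls, lowmap = exp$tracks$lowmap, cfg = cfg)$kept
  kept2 <- filter_by_tracks(kept1, lowmap = exp$tracks$lowmap, cfg = cfg)$kept
  expect_equal(as.data.frame(kept1), as.data.frame(kept2))
  s1 <- filter_by_size(res$calls, cfg)$kept
  s2 <- filter_by_size(s1, cfg)$kept
  expect_equal(as.data.frame(s1), as.data.frame(s2))
})
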