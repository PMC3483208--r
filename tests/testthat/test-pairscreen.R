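mk_pair <- function(posA, posB, strandA = "+", strandB = "-", chromA = "chr1",
                    chromB = chromA, mapqA = 60L, mapqB = 60L, id = "p",
                    rlen = 50L, mapped = TRUE) {
  canonicalize_pairs(data.table::data.table(
    frag_id = id, chromA = chromA, posA = as.integer(posA), strandA = strandA,
    mapqA = as.integer(mapqA), chromB = chromB, posB = as.integer(posB),
    strandB = strandB, mapqB = as.integer(mapqB), rlen = as.integer(rlen),
    mapped = mapped, dup = NA_character_, orig_id = NA_character_))
}

lib <- library_model()   # (50, 315, 44)
cfg <- filter_config()   # mu + 8 sd = 667

test_that("classification boundaries follow mu +/- k*sd strictly", {
  # outer span = posB + rlen - posA; posA 0 -> span = posB + 50
  cl <- function(p) classify_pairs(p, lib, cfg)$pair_class
  expect_identical(cl(mk_pair(0, 618)), "del_signature")       # span 668 > 667
  expect_identical(cl(mk_pair(0, 617)), "concordant")          # span 667, strict
  expect_identical(cl(mk_pair(0, 265)), "concordant")          # span = mu
  expect_identical(cl(mk_pair(0, 200, "+", "+")), "inversion_signature")
  expect_identical(cl(mk_pair(0, 200, "-", "-")), "inversion_signature")
  expect_identical(cl(mk_pair(0, 200, "-", "+")), "short_insert_signature")
  expect_identical(cl(mk_pair(1000, 500, chromA = "chr14", chromB = "chrX")),
                   "translocation_signature")
  expect_identical(cl(mk_pair(0, 100, mapped = FALSE)), "unusable")
})

test_that("classification partitions: every mapped pair gets exactly one class", {
  p <- rand_pairs(500, seed = 41)
  classed <- classify_pairs(p, lib, cfg)
  expect_identical(nrow(classed), 500L)
  expect_false(any(is.na(classed$pair_class)))
  expect_true(all(classed$pair_class %in%
    c("concordant", "del_signature", "short_insert_signature",
      "inversion_signature", "translocation_signature")))
})

test_that("MAPQ filter keeps a pair only when both mates reach the cutoff", {
  both <- rbind(mk_pair(0, 300, mapqA = 23, mapqB = 60, id = "keep"),
                mk_pair(0, 300, mapqA = 22, mapqB = 60, id = "drop"))
  out <- filter_mapq(both, cfg)
  expect_identical(out$frag_id, "keep")
  expect_identical(attr(out, "n_removed"), 1L)
  expect_identical(nrow(filter_mapq(empty_pairs(), cfg)), 0L)

  p <- rand_pairs(400, seed = 42)
  out <- filter_mapq(p, cfg)
  expect_identical(nrow(out), sum(p$mapqA >= 23 & p$mapqB >= 23))
})

test_that("perfect duplicate removal keeps one representative", {
  trip <- rbind(mk_pair(100, 400, id = "a", mapqA = 50),
                mk_pair(100, 400, id = "b", mapqA = 60),
                mk_pair(100, 400, id = "c", mapqA = 50))
  out <- remove_perfect_duplicates(trip)
  expect_identical(nrow(out), 1L)
  expect_identical(out$frag_id, "b")  # highest summed MAPQ wins

  distinct <- rand_pairs(200, seed = 43)
  out2 <- remove_perfect_duplicates(distinct)
  expect_identical(nrow(out2), nrow(unique(distinct,
    by = c("chromA", "posA", "strandA", "chromB", "posB", "strandB"))))
  # idempotent
  expect_identical(nrow(remove_perfect_duplicates(out2)), nrow(out2))
})

test_that("imperfect duplicate removal is transitive and orientation-aware", {
  # 3-pair near-duplicate cluster with 1-2 bp offsets collapses to one
  fig6 <- rbind(mk_pair(1000, 5000, id = "o"),
                mk_pair(998, 5002, id = "d1"),
                mk_pair(1002, 4999, id = "d2"))
  out <- remove_imperfect_duplicates(fig6, cfg)
  expect_identical(nrow(out), 1L)

  # chain: a~b and b~c but a!~c directly; union-find joins all three
  chain <- rbind(mk_pair(1000, 5000, id = "a"),
                 mk_pair(1002, 5002, id = "b"),
                 mk_pair(1004, 5004, id = "c"))
  expect_identical(nrow(remove_imperfect_duplicates(chain, cfg)), 1L)

  # 3 bp offset on one mate: not duplicates
  far <- rbind(mk_pair(1000, 5000, id = "a"),
               mk_pair(1003, 5000, id = "b"))
  expect_identical(nrow(remove_imperfect_duplicates(far, cfg)), 2L)

  # opposite strand on one mate: orientation must match
  flip <- rbind(mk_pair(1000, 5000, id = "a"),
                mk_pair(1000, 5000, strandA = "-", id = "b"))
  expect_identical(nrow(remove_imperfect_duplicates(flip, cfg)), 2L)
})

test_that("screening filters are idempotent and never increase pair count", {
  p <- rand_pairs(600, seed = 44)
  for (f in list(function(x) filter_mapq(x, cfg),
                 remove_perfect_duplicates,
                 function(x) remove_imperfect_duplicates(x, cfg))) {
    once <- f(p)
    expect_lte(nrow(once), nrow(p))
    expect_identical(as.data.frame(f(once))[1:11], as.data.frame(once)[1:11])
  }
})

test_that("de-duplication exactly recovers the original set on simulator output", {
  g <- random_genome(c(c1 = 400000L), seed = 45)
  scfg <- sim_config(1200, seed = 46, perfect_dup_rate = 0.08,
                     imperfect_dup_rate = 0.04)
  tr <- simulate_pairs(g, lib, scfg)
  pairs <- emit_truth_pairs(tr, NULL, lib, ref_lengths = genome_lengths(g))
  originals <- pairs[is.na(pairs$dup), ]
  dedup <- remove_imperfect_duplicates(remove_perfect_duplicates(pairs), cfg)
  # one representative per transitive near-duplicate group (oracle count)
  key_all <- data.table::copy(pairs)[, pair_class := "x"]
  grp_all <- brute_cluster_components(key_all, d = cfg$dup_offset_max)
  expect_identical(nrow(dedup), length(unique(grp_all)))
  # no false removals: an original with no other fragment within the offset
  # at either mate survives as its own representative
  key_orig <- data.table::copy(originals)[, pair_class := "x"]
  grp_orig <- brute_cluster_components(key_orig, d = cfg$dup_offset_max)
  lone_original <- ave(seq_along(grp_orig), grp_orig, FUN = length) == 1 &
    !originals$frag_id %in% pairs$orig_id
  expect_true(mean(lone_original) > 0.8)
  expect_true(all(originals$frag_id[lone_original] %in% dedup$frag_id))
})
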