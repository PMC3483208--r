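# Shared fixtures (built once per test session) and independent oracles.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fx)) assign(name, force(expr), envir = .fx)
  get(name, envir = .fx)
}

table1_exp <- function() fixture("table1", suppressWarnings(
  build_experiment(experiment_config("table1"), seed = 11)))

germline_exp <- function() fixture("germline",
  build_experiment(experiment_config("germline-demo"), seed = 5))

minimal_exp <- function() fixture("minimal",
  build_experiment(experiment_config("minimal"), seed = 42))

dup_demo_exp <- function() fixture("dupdemo",
  build_experiment(experiment_config("dup-demo"), seed = 1))

# random mapped pair table generator
rand_pairs <- function(n, seed, chroms = c("chr1", "chr2"), span = 100000L,
                       rlen = 50L) {
  set.seed(seed)
  p <- data.table::data.table(
    frag_id = sprintf("p%04d", seq_len(n)),
    chromA = sample(chroms, n, TRUE),
    posA = sample.int(span, n, TRUE) - 1L,
    strandA = sample(c("+", "-"), n, TRUE),
    mapqA = sample(0:60, n, TRUE),
    chromB = sample(chroms, n, TRUE),
    posB = sample.int(span, n, TRUE) - 1L,
    strandB = sample(c("+", "-"), n, TRUE),
    mapqB = sample(0:60, n, TRUE),
    rlen = rlen, mapped = TRUE,
    dup = NA_character_, orig_id = NA_character_
  )
  canonicalize_pairs(p)
}

# O(n^2) clustering oracle: full adjacency + BFS transitive closure
brute_cluster_components <- function(p, d) {
  n <- nrow(p)
  key <- paste(p$pair_class, p$chromA, p$chromB, p$strandA, p$strandB)
  adj <- outer(seq_len(n), seq_len(n), function(i, j) {
    key[i] == key[j] &
      abs(p$posA[i] - p$posA[j]) <= d &
      abs(p$posB[i] - p$posB[j]) <= d
  })
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

# per-base bitmap oracle for track coverage of one interval
bitmap_covered <- function(chrom, start, end, track, L = 200000L) {
  bm <- logical(L)
  t <- data.table::as.data.table(track)
  t <- t[t$chrom == chrom, ]
  for (i in seq_len(nrow(t))) bm[(t$start[i] + 1L):t$end[i]] <- TRUE
  sum(bm[(start + 1L):end])
}

# genome-wide double-stranded k-mer count oracle via Biostrings pattern match
oracle_kmer_count <- function(genome, kmer) {
  subject <- Biostrings::DNAStringSet(unclass(genome))
  fwd <- sum(Biostrings::vcountPattern(kmer, subject))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(kmer)))
  if (rc == kmer) fwd
  else fwd + sum(Biostrings::vcountPattern(rc, subject))
}

expect_pairs_equal <- function(a, b) {
  cols <- c("frag_id", "chromA", "posA", "strandA", "mapqA",
            "chromB", "posB", "strandB", "mapqB", "rlen", "mapped")
  testthat::expect_equal(as.data.frame(a)[cols], as.data.frame(b)[cols],
                         ignore_attr = TRUE)
}
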