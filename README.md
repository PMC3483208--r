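# svpipe

Detection of large somatic structural variants (SVs) — deletions,
inversions, tandem duplications and translocations — from discordant
paired-end (PE) read alignments of a tumor genome, with the false-positive
filtering cascade that makes low-coverage calling practical, plus the full
simulation machinery needed to validate every stage without external data.

It is aimed at people building or evaluating read-pair SV callers: the
package closes the loop from "rearranged genome with a known truth set"
through "simulated PE library" to "filtered, high-confidence calls scored
against the truth".

## The method

A PE library with read length *r*, insert mean μ and SD σ (defaults
50 / 315 / 44 bp, *insert* meaning the outer fragment span) implies a
signature for every mapped pair. With mates in leftmost order:

| signature | condition | SV type |
|---|---|---|
| translocation | mates on different chromosomes | translocation |
| inversion | FF or RR orientation | inversion |
| short insert | RF orientation, or FR span < μ − kσ | duplication |
| deletion | FR span > μ + kσ | deletion |
| concordant | otherwise | — |

with k = 8 (strict inequalities; μ + 8σ = 667 bp at the defaults).
Discordant pairs of the same signature whose mates co-locate within
d = μ + kσ on both sides are clustered by transitive closure; a cluster
becomes a call when it has ≥ 2 supporting pairs and the spread of mate
start positions on each side is ≥ 3 bp.

False positives are then removed in the published stage order:

1. **Mapping quality** — a pair is kept only when both mates have
   MAPQ ≥ 23 (multi-mapping reads in repeats are the dominant error source);
2. **Imperfect PCR duplicates** — pairs whose mates sit within 0–2 bp of
   another pair in the same orientation collapse to one representative
   (these near-duplicates escape coordinate-identity tools);
3. **Tumor/control comparison** — a call whose anchors are both hit by any
   control cluster with ≥ 1 supporting pair is germline, whatever its type;
4. **Overlap filters** — a call is removed when its anchors overlap
   low-mappability regions by ≥ 85% (intra-chromosomal) / ≥ 50%
   (inter-chromosomal), simple repeats by ≥ 50%, or — for inter-chromosomal
   calls with only 2–3 supporting pairs — RepeatMasker intervals by ≥ 80%;
5. **Size cutoffs** — deletions < 600 bp and duplications < 300 bp are
   artifacts of the insert-size distribution tails.

Mappability is computed from scratch: score(i) = 1 / (genome-wide
occurrences of the 50-mer starting at i, both strands), low-mappability =
50 bp windows with mean score < 0.5 (i.e. the 50-mer occurs more than
twice), and breakpoint mappability = the percentage of fully-unique 50 bp
windows within 265 bp (μ − r) of the breakpoint.

The closed-form detection model is Poisson: with N pairs on a genome of
G bp, a breakpoint with local mappability m collects
λ = m·N·(μ − 2r)/G fully-anchored spanning pairs, and
P(detect) = P(X ≥ s), X ~ Poisson(λ), s the support minimum.

## Worked example

A two-chromosome toy genome with one 5 kb deletion and one reciprocal
translocation, tumor and control libraries at 30x physical coverage:

```r
library(svpipe)
exp     <- build_experiment(experiment_config("minimal"), seed = 42)
tumor   <- simulate_experiment(exp, "tumor",   seed = 7)
control <- simulate_experiment(exp, "control", seed = 8)
res <- sv_pipeline(tumor, control, tracks = list(lowmap = exp$tracks$lowmap),
                   lib = exp$lib, cfg = filter_config())
res$kept
#>           id          type chromA startA  endA chromB startB  endB  size support
#> 1: call00001 translocation   chr1  39662 39990   chr2  30006 30282    NA      15
#> 2: call00002      deletion   chr1  14687 14982   chr1  19999 20327  5017      17
#> 3: call00003 translocation   chr1  39999 40324   chr2  29722 30002    NA      31
```

The deletion call spans the planted breakpoints (15 000 and 20 000; anchors
end flush at them, size estimated 5 017 vs 5 000 true), and the two
translocation calls are the two junctions of the reciprocal event at
chr1:40 000 / chr2:30 000, distinguished by strand signature. Scoring:

```r
truth <- exp$truth
sum(match_calls_to_truth(res$kept, truth, exp$lib))   # 3 of 3 recovered
```

The detection model reproduces why low-mappability breakpoints need more
coverage — at the coverage of 160 M mouse-genome pairs (~19x physical):

```r
detection_probability(160e6, 2.654e9, exp$lib)                     # 1.000
detection_probability(160e6, 2.654e9, exp$lib, mappability = 0.2)  # 0.731
```

A command-line front end wraps each stage
(`inst/cli/svpipe <command> ...`; commands: rearrange, simreads, tracks,
screen, call, filter, stats, power, fixtures, run, config), with every
published threshold as the default — `svpipe config` dumps them.

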