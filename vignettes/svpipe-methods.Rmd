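---
title: "Detecting somatic structural variants from discordant read pairs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{svpipe methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

svpipe implements a read-pair method for calling large tumor-specific
structural variants from short-read paired-end (PE) whole-genome data,
together with everything needed to validate it in silico. This vignette is
the package's own account of the science: the model and its assumptions,
the parameters that matter, what the synthetic data does and does not
emulate, and the design decisions taken where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The signal model

A PE library is summarised by three numbers: read length $r$, insert mean
$\mu$ and insert SD $\sigma$, where *insert* is the outer fragment span
(leftmost read start to rightmost read end). Defaults are
$(r, \mu, \sigma) = (50, 315, 44)$ bp, a realistic short-read tumor
library. A fragment that straddles a rearrangement junction produces a
*discordant* pair once mapped to the reference: mates on different
chromosomes (translocation), in FF/RR orientation (inversion), in RF
orientation or with an implausibly short FR span (tandem duplication), or
in FR orientation with span exceeding $\mu + k\sigma$ (deletion). The
deviation multiplier $k = 8$ sets the size floor of detectable events:
raising $k$ suppresses insert-size-tail artifacts at the price of a larger
minimum deletion/duplication size. All span comparisons are strict
inequalities, so with the defaults the removed mapping-quality range is
exactly 0–22 and the concordant span band is exactly
$[\mu - 8\sigma,\, \mu + 8\sigma]$.

Discordant pairs of one signature class cluster when their A-mates and
B-mates each co-locate within $d = \mu + k\sigma$, with matching
orientations; clustering is the transitive closure (union-find). The
clustering radius is a design choice — the method's original external
callers do not publish theirs — and reusing the classification deviation
threshold keeps a single scale parameter; it is exposed as `cluster_dist`.
A cluster becomes a call at support $\ge 2$ pairs with a per-side
anchor-start spread of $\ge 3$ bp (`min_anchor`); the spread gate exists
solely to stop clusters of imperfect PCR duplicates, whose spread cannot
exceed the 2 bp duplicate offset, from reaching the support threshold.

## The noise model and the filter cascade

Three error sources dominate false positives, and each has a dedicated
counter-measure, applied in a fixed order with per-stage accounting
(`sv_pipeline()`):

* **Multi-mapping reads.** Reads from repeats acquire wrong but confident-
  looking positions. Both mates must have MAPQ ≥ 23 (`mq_min`); calls are
  additionally screened against a low-mappability track (removal at ≥ 85%
  anchor overlap for intra-chromosomal, ≥ 50% for inter-chromosomal calls),
  a simple-repeat track (≥ 50%), and — only for inter-chromosomal calls
  with 2–3 supporting pairs — RepeatMasker intervals (≥ 80%). RepeatMasker
  is deliberately not applied more broadly: it annotates many anciently
  diverged, perfectly mappable elements, and a blanket filter discards real
  biology. All removal cutoffs are inclusive.
* **PCR duplicates.** Perfect duplicates share both mates' coordinates and
  strands; one representative (highest summed MAPQ) is kept. *Imperfect*
  duplicates — amplification plus slippage or read-edge sequencing error —
  sit 0–2 bp apart on both mates in the same orientation and evade
  coordinate-identity tools; they are grouped transitively
  (`dup_offset_max = 2`) and collapsed. Transitive grouping is a design
  choice: chains a~b~c with a and c 4 bp apart collapse to one fragment,
  which is the conservative reading for calling purposes.
* **Germline variation.** In any non-reference individual (hybrid mouse
  strains, human polymorphism), germline retroelement insertions mimic
  balanced translocations (insertion from another chromosome) or deletions
  (same chromosome), and retrogenes mimic a translocation plus one deletion
  per intron. A matched control library, screened identically, is clustered
  with a support threshold of just 1 (`control_min_support`) — a germline
  event may leave a single pair in a lower-coverage control, and demanding
  2 provably leaks germline calls — and a tumor call is removed when both
  anchors intersect a control cluster, ignoring SV type.

Finally, deletions < 600 bp and duplications < 300 bp are removed: at
$k = 8$ these sizes are reachable by the tails of the fragment-length
distribution alone. Type-specific size estimation follows anchor geometry:
deletion size is the inner anchor distance, duplication size the outer,
inversion size the start-to-start distance.

## Mappability from first principles

Rather than importing a uniqueness track, the package computes one: the
score of position $i$ is $1/\text{occ}(i)$ where occ counts genome-wide
occurrences of the $k$-mer starting at $i$ ($k = r = 50$), treating a
$k$-mer and its reverse complement as one key (aligners map both strands).
Low-mappability regions are 50 bp windows with mean score < 0.5 — i.e. the
window's 50-mers occur more than twice — merged when adjacent. A window
*mean* is used because the aggregation rule from per-position scores to
windows is an open choice; the mean makes the 2-copy boundary exact
(score 0.5 is *not* flagged). Breakpoint mappability is the percentage of
fully-unique 50 bp windows among the 5 tiled outward on each flank of the
breakpoint, the flank being $\mu - r = 265$ bp — exactly the region where
an anchoring mate of a junction-spanning fragment can sit; the trailing
15 bp remainder is dropped, giving 10% granularity.

## The simulator and its closed loop

`simulate_pairs()` draws chromosomes proportional to length, fragment
starts uniformly, and fragment lengths $\mathcal{N}(\mu, \sigma)$ rounded
and truncated below at $r$ (fragments that do not fit their chromosome, or
that contain an N run, are resampled and counted). Read 1 is the first $r$
bases, read 2 the reverse complement of the last $r$ (FR). Base qualities
are constant (Q30): the method never reads them. Duplicate injection
treats its rates as fractions of the *output* stream; imperfect duplicates
move each fragment end independently by up to 2 bp with at least one end
moved.

`emit_truth_pairs()` closes the loop without an external aligner: each
mate is placed at its true reference position through the derived-genome →
reference liftover that `apply_plan()` maintains as piece lists. Two
behaviours substitute for alignment physics:

* **MAPQ model** — a mate's MAPQ is 60/3/0 for a read-length $k$-mer with
  1/2/>2 reference copies at its (lifted) position. This makes the ≥ 23
  filter remove exactly the reads an aligner would consider multi-mapping,
  and 2-copy reads (MAPQ 3) are also removed, mirroring how
  low-but-nonzero MAPQ reads behave under the cutoff. The model is
  pluggable; real SAM input bypasses it.
* **Junction reads** — a mate overhanging a junction by fewer than 3 bases
  (`min_anchor`) is anchored to the side holding the rest of it, its
  position extrapolated so the anchored portion maps truly: a 1–2 bp
  overhang is invisible to an aligner. A mate with ≥ 3 bases on both sides
  is a chimeric read, and its pair is emitted as unmapped. The opposite
  convention — keeping balanced chimeras anchored with full confidence —
  was rejected on both physical and empirical grounds: it is not how
  gapped aligners treat novel junctions, and it makes every junction
  detectable at ~19x regardless of flank repeats, erasing the
  mappability-dependence that the coverage analysis is about.

With those two rules, the closed-form detection model
$\lambda = m \cdot N (\mu - 2r) / G$, $P(\text{detect}) = P(X \ge s)$,
$X \sim \text{Poisson}(\lambda)$, matches simulation within binomial error
(verified at five $(N, m)$ grid points). The $\mu - 2r$ window is used
rather than $\mu$ because a breakpoint inside either read destroys that
read's anchor; only the inner gap contributes fully-anchored spanning
pairs. In the closed-form check, $m < 1$ is exercised by random thinning
of pairs (survival probability $m$): the multiplicative-$m$ form is an
approximation of the mechanistic flank-repeat effect, whose exact
geometry (which windows of which flank are repetitive) is what the
benchmark fixture tests end to end.

## The benchmark fixture ("table1" preset)

The stated world of the headline validation: 20 truth SVs — 10 deletions
with sizes preserved verbatim (576,373; 46,610; 600,033; 5,963; 64,735;
1,433; 10,789; 3,066; 1,000,440; 21,449 bp) and 5 reciprocal
translocations listed junction-by-junction — each with a breakpoint
mappability class: 100, 95.1, 85.3, 100, 100, 77.4, 100, 100, 100, 100 for
the deletions; 100, 100, 50, 50, 70.2, 52.8, 66, 73.8, 18.5, 36.4 for the
junctions. Each truth entry gets its own toy chromosome (deletion hosts
are the deletion size plus 40 kb margin; junction hosts 60 kb), about
3.34 Mb in all — the smallest genome that can host the verbatim sizes.
Mappability classes are engineered at 10% granularity: a class of $f$
means $\mathrm{round}((1-f/100)\cdot 10)$ of the 10 flank windows are
overwritten with a repeat unit, split as evenly as possible across the two
flanks (ceil on the A side), outermost windows first — junction-proximal
sequence stays unique because real junctions are novel sequence. Each
unit is written once at its flank and twice on a landfill chromosome, so
spiked 50-mers have exactly 3 genomic copies (MAPQ 0, score 1/3); landfill
copies carry guard bases that differ from the unit's genomic neighbours,
otherwise boundary-crossing $k$-mers can coincidentally occur twice and
push a flank one window below its class. Tumor libraries default to 19x
physical coverage (what 160 M pairs give on a 2.65 Gb genome), with 9.1%
perfect and 1% imperfect duplicates.

What a green run establishes: the pipeline recovers ~90% of the truth set
at 19x with detection monotone in coverage, duplicates are removed without
losing true support, and engineered low-mappability flanks cost exactly
the detection the Poisson model predicts. What it does not establish: real
libraries have chimeric fragments, GC-dependent coverage, indels and
sequencing errors, alignment soft-clipping, and repeat families with
internal structure — none of which are emulated. Absolute call counts from
the original tumor data are therefore out of reach by construction and are
covered only qualitatively (cascade monotonicity, category accounting).

## Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open everywhere; SAM I/O shifts by
  exactly 1, BED/BEDPE by 0. Mates and anchors are stored in canonical
  (chromosome, position) order; orientation is derived, never stored.
* Ties in duplicate collapse go to the highest summed MAPQ, then leftmost
  position, then input order — deterministic under permutation.
* The overlap-fraction denominator is the summed anchor length (the
  per-anchor maximum is available behind `per_anchor_max`); the control
  comparison requires both anchors to intersect (single-anchor mode would
  be more aggressive and is the likelier explanation for residual germline
  leakage in practice).
* `breakpoint_mappability` near a chromosome end computes over the
  available full windows and flags the result; zero scorable windows is an
  error.
* Empty inputs flow through: zero-pair simulations give empty FASTQ,
  empty call sets give empty BEDPE, empty tracks disable their filter.
* Calls surviving the cascade are tagged `high_confidence`; no manual
  curation heuristics are imitated.
* Reciprocal translocations are reported as two calls (one per junction),
  matching how the truth set lists them; `match_calls_to_truth()` uses the
  strand signature to keep the two junctions distinct, and pads anchors by
  one insert mean, the position resolution of read-pair evidence.

## Known limitations

Breakpoints are resolved only to anchor envelopes (no split-read
refinement); duplication sizes from undersized-insert evidence are crude;
the clusterer is a single parameterised algorithm, not a reimplementation
of any external caller's; BAM input is not parsed (plain SAM is the tested
interchange; convert with `samtools view`); and coverage-based copy-number
inference is limited to the relative-depth view in `relative_coverage()`.
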