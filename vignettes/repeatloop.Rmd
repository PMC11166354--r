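---
title: "Methods: repeat-aware RdDM analysis with repeatloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat-aware RdDM analysis with repeatloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models and
procedures each module implements, the parameters that matter and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical and statistical choices made where the
design was genuinely open.

## The biological setting

RNA-directed DNA methylation (RdDM) in plants couples 24-nt siRNA
production by RNA polymerase IV to de novo cytosine methylation in all three
sequence contexts (CG, CHG, CHH; H = A, C or T). At loci showing
paramutation — heritable trans-homolog silencing — the repeat structure of
the locus is central: at the maize *pl1* locus the repressed state is
associated with 24-nt RNA production and 5mC specifically at a 390 bp
unique subregion (USR) embedded in each unit of a penta-repeat (five
identical 2092 bp tandem copies) downstream of the gene. A read derived
from any repeat unit matches all five; the only way to quantify the region
with a zero-mismatch, unique-only mapping policy is to collapse the array
to a single unit first. Everything in this package flows from taking that
collapse seriously.

## Coordinates

All coordinates are 0-based, half-open internally. GFF3 I/O converts
to/from the 1-based closed convention on disk; BED and bedGraph writers use
0-based half-open as the formats require. Strands are `+`, `-`, `.`.

## Tandem arrays and the collapsed reference

`detect_tandem_arrays()` finds maximal runs of *perfect* direct repeats:
positions where `s[i] == s[i + p]` over a span of at least
`p * (min_copies - 1)`. Candidate periods are seeded from distances between
duplicated k-mers (k = min(12, `min_unit`), distances between occurrences
up to eight apart in rank), so only periods with textual support are
verified; verification is a vectorized shift comparison, which keeps a
192 kb haplotype under a second or two on one CPU. Numerical choices:

* **Primitive period.** When a region is explained by several unit
  lengths, the primitive (shortest) period is reported. With at least two
  copies, the primitive period divides any observed period
  (Fine–Wilf), so only divisors are checked. An array whose primitive
  period falls below `min_unit` is not reported at an inflated period —
  the caller asked for units of at least `min_unit`, and reporting a
  homopolymer as, say, a 4-mer repeat would be a misdescription.
* **Phase.** The unit boundary within an array is not observable from the
  sequence alone; the leftmost phase is reported (maximal run start).
* **Overlaps.** After primitive-period reduction, overlapping candidates
  are resolved greedily in favour of the longer span.
* **Perfect identity only.** Near-identical arrays (single SNPs between
  units) are representable in annotations but are out of scope for
  detection; the studied array is identical across units.

`collapse_repeats()` retains one unit per array; the collapsed length
equals the full length minus `(copies - 1) * unit` per array.
`lift_to_full()` maps a collapsed interval to one interval per repeat copy
(or exactly one outside arrays) and refuses intervals straddling an array
boundary rather than guessing; `lift_to_collapsed()` folds any full-space
position back. The test suite round-trips every collapsed position and
checks that the lifted position multiset reconstitutes the full sequence
length.

`repetitive_index()` counts exact occurrences of every query window
(default 24 nt, the length of the siRNAs of interest) across a background,
on either strand — reverse-complement occurrences count because mapping is
strand-blind. Windows containing `N` are flagged and given count 0.

## Exact-match read placement

The mapper reproduces the *contract* of zero-mismatch, suppress-multimapper
alignment (no mismatches, report a placement only when exactly one exists),
not any particular aligner. Occurrences are counted over both strands of
all references; 0 → `unmapped`, 1 → `unique` (with placement),
≥ 2 → `multi` (no placement). A perfectly palindromic read matching one
locus on both strands counts twice and is therefore `multi` — that rule is
declared, not inferred from any tool's behaviour. Reads containing `N`
never match. Internally the index holds a per-read-width hash of
forward-strand reference windows (built lazily, cached), so classifying
many libraries against the same small references costs one lookup per
distinct read; an optional `mode = "all"` enumerates every placement for
all-reads profiles.

`two_pass_filter()` implements the published cascade: classify against a
background genome, discard multi-mappers, classify survivors against the
target (the collapsed haplotype), keep unique target placements. A
per-stage accounting table is attached so every read's fate is auditable.

## 4C tag analysis

Proper amplicons read
`forward primer – DpnII site – interacting fragment – (NlaIII – reverse
primer)`. The parser applies four stages, each recording a single rejection
reason:

1. **Anchor** — the read must contain the last 3 primer nt plus the DpnII
   site (`CTCGATC`) within Hamming distance 1 (k = 7, mink = 7).
2. **Left trim** — everything through the 3′ 16 nt of the forward primer
   is removed (k = 16, mink = 12, hdist = 2). The DpnII site is *retained*
   at the fragment 5′ end: DpnII cuts 5′ of GATC, so the site is part of
   the captured genomic fragment and is needed for exact placement. A
   49 bp read whose primer was not recognized stays longer than the 28 nt
   cap and is rejected.
3. **Right trim** — the NlaIII site plus reverse-primer start
   (`CATGAGCTATGA`, k = 12, mink = 7, hdist = 1) is removed if present
   (long fragments need not contain it); fragments shorter than 8 nt are
   rejected as primer dimers.
4. **Quality** — trailing bases under Q20 are trimmed, then reads with
   mean quality below 20 or length under 8 are rejected.

The adapter-matching semantics shared by stages 1–3 (and by the sRNA
trimmer) are implemented directly from the parameter definitions: a match
is any window of length k — or, flush with the relevant read end, any
adapter prefix/suffix of length ≥ mink — within the stated Hamming
distance.

Unique placements collapse to the strand-aware 5′-most coordinate (plus:
interval start; minus: interval end − 1). Positions within 2 kb of the
bait are excluded; the published rule says "2 kb on either side of the
bait region" without fixing the anchor point, so the exclusion is centred
on the configured bait position (intended as the bait-fragment midpoint).
Counts are normalized to rpm over the retained tags (they sum to 10^6 by
construction) and ranked by descending rpm with competition ranking (ties
share the better rank; the next rank skips) — deterministic and
conventional. Binning tiles half-open windows from position 0 and sums
member rpm, so binning conserves totals exactly.

## Small-RNA pipeline

Preprocessing removes the 3′ adapter under the shared k/mink/hdist
contract (defaults k = 18, mink = 11, hdist = 1), then applies the library
protocol: for UMI-bearing libraries (4 random nt flanking the insert),
deduplication on the full trimmed sequence comes *first*, then 4 nt are
stripped from each end; the final insert filter keeps 18–30 nt. Reads with
any exact placement on an rRNA/tRNA reference are removed; the surviving
"clean" count is the library's rpm denominator.

Cluster calling is a declared merge-then-threshold procedure: the union of
uniquely-mapped read intervals across the defining libraries, merged
whenever the gap is strictly less than `pad` (default 50 nt, to avoid
fusing independent loci at depth), thresholded at
`ceiling(mincov_rpm * sum(clean_totals) / 1e6)` reads. The coverage floor
is recomputed from the defining libraries rather than hard-coded — the
published floor of 152 reads is exactly 0.5 rpm of its libraries'
combined depth, and that is the invariant worth keeping. The semantics may
differ in corner cases from any specific cluster caller's internals; it is
oracle-tested against an independent merge loop.

Per-cluster quantification counts reads overlapping a cluster by at least
1 bp (the simplest defensible rule, declared), converts to rpm per
library, and tests group differences with a two-sided two-sample t-test on
rpm values — Welch by default (unequal variances are the realistic case;
the pooled variant is available). No multiple-testing correction is
applied by default, matching the practice of reporting raw p over ~30
clusters; Bonferroni is available. Zero variance in both groups with equal
means yields p = 1 by convention.

Profiles: `collapse_5prime_profile()` bins strand-aware 5′ coordinates in
10 nt windows, per strand and read length, reporting mean rpm across
libraries. `size_class_profile()` gives per-length percentages (18–30 nt).
`normalize_by_21mer()` rescales a mutant profile by
`pct21(control) / pct21(mutant)` — 21-mer levels are unaffected by the
RdDM mutants of interest, so they anchor cross-genotype comparisons; the
residual fraction per length is the normalized mutant percentage over the
control percentage. The 21-mer invariance is an assumption encoded as a
normalization, not verified biologically. Genome-wide residuals are
computed on all clean reads by default (computing them on uniquely-mapped
reads instead is a one-line change and both are exercised in tests).

## Methylation amplicon calling

Contexts are assigned from the two bases 3′ of each cytosine on its
strand: CG, CHG, CHH; terminal cytosines lacking flank are ambiguous and
excluded from denominators. Clones are anchored ungapped against the
reference interval — Sanger clones of a ~123 bp amplicon either align
end-to-end or carry an indel, in which case they are rejected rather than
realigned (a cap on non-cytosine mismatches guards against misassigned
clones). At each reference cytosine, clone C → methylated (conversion
protected), clone T → unmethylated (deaminated), anything else ambiguous.
The default analysis strand is the amplified top strand; both strands are
supported. Conversion efficiency is the fraction of control-reference
cytosines read as T in unmethylated (lambda-style) control clones;
libraries under 0.98 are flagged.

## ΔΔCt quantification

Technical replicates are averaged on the Ct scale (arithmetic mean, as is
standard); per sample, ΔCt = Ct(target) − Ct(reference);
ΔΔCt subtracts the calibrator group's mean ΔCt; fold = 2^−ΔΔCt with
amplification efficiency fixed at 2 (efficiency-corrected modes are out of
scope). Group summaries report mean fold and s.e.m. on the linear scale,
as conventionally plotted; the two-group test runs on per-sample folds by
default, with a ΔCt-scale variant available (which of the two the
original analyses used is not stated; both are computed). Shift invariance
(adding a constant to every Ct) and calibrator self-fold (geometric mean
1) are tested properties. MNase-qPCR accessibility uses identical
arithmetic per tiled amplicon.

One statistical caveat worth stating plainly: the s.e.m. of per-sample
folds understates the uncertainty of the mean fold, because every fold
shares the calibrator-mean estimate and the fold scale is lognormal. A
naive "truth within 2 s.e.m." check covers only ~75% of repeated
simulations at Ct noise sd 0.2 and n = 3; a t-based interval on the ΔΔCt
(log2) scale is correctly calibrated (~95%), and that is what the test
suite asserts. The reported s.e.m. remains the plotted convention.

## The synthetic-data generator

`sim_config()` fixes the study conditions; the generator is not a tuning
dial. Defaults: a 50 kb haplotype carrying one perfect 2092 bp × 5 array
beginning at 20 kb; a 390 bp USR at offset 800 within each unit, flanked
by a 200 bp TE shared with an 8 kb decoy background (so its reads
multi-map at the genome pass) and a 180 bp array-private TE; a bait with a
DpnII site at 5 kb; a planted DpnII site inside the USR whose following
20 nt are free of either cutter so simulated 4C amplicons parse and map
losslessly; 10^5 reads per sequencing library; 30 sRNA source loci (one
being the USR, one immediately upstream of it, 28 elsewhere). Effect sizes
encode the reported genotype contrasts: repressed-vs-active USR sRNA folds
of 9.9 (cob) and 4.4 (seedling); 24-mer shares of 0.80 at generic loci,
0.79 at the USR (0.73 in the chromatin-remodeler mutant, which also
halves USR output — a 48% reduction — and boosts the adjacent private TE
15.8-fold); genome-wide 24-mer retention of 8% and 48% in the two
polymerase-pathway mutants; methylation rates 0.88 / 0.60 / 0.07
(CG/CHG/CHH) in repressed and heterozygous states versus near zero in the
active state (0.60 sits mid-range of the reported 55–70% CHG spread); a
true 15-fold USR RNA excess with Ct noise sd 0.2 over triplicates; 2-fold
MNase protection at the two central USR amplicons. A configurable
active-state emission fraction supports the strict genotype model (USR
emission only in the repressed state) used for end-to-end contrast tests.
Everything is reproducible byte-for-byte from the seed (R's integer-state
Mersenne Twister; each simulator draws from a fixed offset of the
configured seed).

What the generator deliberately does not emulate: sequencing error
(optional and off — with exact matching, erroneous reads simply become
unmapped, and that interaction is by design), base-quality profiles beyond
a constant high Q, realistic chimeric 4C ligation noise beyond
anchor-free decoys, PCR duplication structure beyond what UMI collisions
induce, and biological variability beyond multinomial sampling. Passing
tests therefore demonstrate the pipelines' correctness and calibration on
clean data at desk scale, not performance on real libraries two orders of
magnitude deeper.

## Problem sizes and test design

The test suite and the acceptance script run the full pipelines at
1 × 10^5 reads per library for the cob contrast and mutant panels (the
generator default) and 5 × 10^4 for some secondary panels; oracle
equivalence checks use up to 5 kb references with 1000 reads (mapper),
10 kb with 5000 reads (cluster caller), 1 kb (context classifier), and a
fixed toy Ct table at 10^-9 (ΔΔCt). Stochastic recovery checks use
tolerances derived from the data's own sampling error (2–3 × the
log-scale standard error of the measured contrast, the wider factor where
several contrasts are asserted jointly) or exact binomial bounds widened
to 3σ when six context/clone-count combinations are tested
simultaneously — per-assertion 95% bounds would fail about a quarter of
the time by multiplicity alone, which would test the random seed rather
than the method.

## Known limitations

* Tandem detection is exact-identity only; a single SNP splits an array.
* The mapper is exact-match by design; it is not a general aligner and
  has no gapped or mismatch-tolerant mode.
* Cluster-calling semantics are declared (merge-then-threshold) and may
  differ from specific published callers at pathological depths.
* Methylation calling assumes ungapped, full-length clones; partial or
  indel-bearing clones are rejected, not rescued.
* ΔΔCt assumes amplification efficiency 2.0 for all amplicons.
* The simulator's truth tables describe emission, not every stochastic
  loss along the pipeline (UMI collisions in deduplication are possible,
  if rare at the default depths).
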