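---
title: "Models and methods: LTR retrotransposon annotation and mobilome activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: LTR retrotransposon annotation and mobilome activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind each stage of the pipeline, what the synthetic-data
generator does and does not emulate, and the design decisions taken where
the design was genuinely open. It states no empirical result that the test
suite does not itself compute.

## The biological problem

LTR retrotransposons (LTR-RTs) replicate copy-and-paste through an RNA
intermediate. An intact copy consists of two long terminal repeats (LTRs)
flanking an internal region that encodes the GAG, protease (PR), integrase
(INT), reverse transcriptase (RT) and RNase H (RH) domains; Copia and
Gypsy superfamilies differ in the order of INT relative to RT/RH.
Integration duplicates a 2–20 bp target site (TSD) on both sides, and the
element almost always starts with `TG` and ends with `CA`. Because the two
LTRs are identical at integration, their subsequent divergence clocks the
insertion. Mobilization leaves two further traces: extrachromosomal
circular DNA (eccDNA) — either a full linear copy circularized by
non-homologous end joining (a *two-LTR circle*, whose LTR–LTR junction
typically carries a small indel, the NHEJ hallmark) or a one-LTR circle
from recombination between the two LTRs — and, when reintegration
succeeds, new insertion sites that are absent from the reference genome.

## Structural mining

`find_ltr_candidates()` reimplements the standard structural decision
surface: candidates are seeded by maximal exact repeats of at least
`seed_len` = 80 bp whose start distance lies in [3000, 15 000] bp, extended
gaplessly along the seed diagonal (X-drop, match +1 / mismatch −3, drop
10), boundary-adjusted to terminal-motif occurrences present in both
repeat copies within 60 bp of the extension edges, and validated for LTR
length (100–4000 bp), LTR-pair identity (≥ 0.85) and an identical flanking
TSD. `min_ltr_len` = 100 and `max_dist` = 15 000 are the conventional
defaults of structural LTR detectors (the source protocol lists only seed,
max LTR length, min distance, TSD range and motif and leaves the rest at
defaults); both are exposed as parameters.

Boundary selection ranks each (5′ start, 3′ end) motif combination by a
composite score: pair-alignment score (`ltr_len − 4·mismatches`) plus TSD
support (`+4` per duplicated base, `−8` per base of displacement from
adjacency, `−2` per base of distance from the extension edges). The TSD
search itself is adjacency-first: smallest displacement, longest
duplication within it. Rationale: the integration-site duplication pins
the true boundary, while the pair score vetoes extensions into flanking
sequence; chance duplications can only displace a boundary if they beat
the true adjacent TSD by ≥ 3 bp *and* pay the displacement penalty.

Two caveats are intrinsic and documented rather than solved. First,
"distance" means distance between LTR *start* positions (the cited
detector's semantics). Second, a genome can contain *structurally
ambiguous* boundaries: if the flank happens to extend the LTR repeat on
its diagonal, or the sequence beside the TSD duplicates an element
terminus, two parses are equally valid and no deterministic rule can
prefer the "true" one — the two ambiguity classes are mirror images, so
any fixed ranking resolves one and breaks the other. The generator
therefore enforces *boundary identifiability* (below); on real genomes a
small fraction of boundary calls is expected to be off by a few bases for
this reason. Nested insertions are not resolved; inner elements may shadow
outer ones. The strand of a structural call is reported as `+`: the TG…CA
motif is its own reverse complement, so detection is strand-symmetric (the
test suite checks that reverse-complementing the genome mirrors every
call).

Solo LTRs — relics of intra-element recombination — are found by
seed-and-extend similarity search with the classified copies' LTRs as
queries, kept at ≥ 80 % identity and ≥ 90 % query coverage, minus any hit
overlapping an intact copy by ≥ 1 bp. `solo_intact_ratio()` reports
missing (not infinite) ratios for groups without intact copies.

## Classification

*Lineage/superfamily.* `detect_domains()` translates each copy in six
frames and aligns a lineage-tagged peptide reference set (header contract
`LINEAGE#DOMAIN#id`) locally under BLOSUM62 (gap open 10, extend 0.5),
keeping the best hit per domain type above a threshold defaulting to 60 %
of the self-score of the shortest reference peptide. An exact 10-aa word
prefilter bounds the search; domains diverged beyond any intact 10-mer are
not recovered — the usual detection floor of seeded searches. A subfamily
is assigned the majority best-hit lineage across its members, ties going
to "unclassified" (reproducibility over coverage); superfamily follows
from the fixed lineage table (nine Copia lineages Ale…Tork, six Gypsy
lineages Athila…Tekay).

*Subfamilies.* `cluster_subfamilies()` links two copies when their local
alignment reaches 60 % identity over ≥ 70 % of the longer sequence
(conservative; a switch selects the shorter-sequence convention) and takes
single-linkage components. The alignment scoring (match 2, mismatch −2,
gap 10/2) is chosen so the expected score drift is positive (+0.4/column)
at the 60 % identity floor but negative (−1/column) in unrelated sequence;
a more permissive mismatch penalty lets random DNA accumulate long gapped
pseudo-alignments above 60 % apparent identity, which would connect
everything. Labels `sNNNN` are assigned by descending component size, then
lexicographically smallest member id, making the partition input-order
invariant. The test suite proves equality with a brute-force thresholded
pair graph + BFS oracle over randomized families.

*Families.* *rt*-domain nucleotide sequences of each lineage are aligned
with MAFFT (`--auto`; the standard tool for this step, shelled out rather
than reimplemented), columns below 90 % occupancy are discarded, pairwise
K80 distances feed a neighbor-joining tree, and support is the percentage
of column-resampling bootstrap replicates containing each internal
bipartition. The published protocol built ML trees (GTR+Γ); the family
rule consumes only support and branch length, both defined for NJ, so NJ
on K80 is used deliberately — cheaper, deterministic, and sufficient for
the cut. Families are the connected components after cutting every
internal edge with support > 70 and length ≥ 0.3 substitutions/site. This
"cut-edge components" formulation decides an open design point (what to do
when qualifying clades nest): it is equivalent to taking maximal
qualifying clades in the unnested case, and well-defined on unrooted
trees; a tree with no qualifying edge is a single family. Copies without
an *rt* domain form the artificial per-lineage family `f0`. Saturated
pairs (undefined K80) are routed to `f0` with a warning rather than
clamped.

## Insertion dating

`k80_distance()` globally aligns the LTR pair (affine gaps), drops gap
columns from the denominators (K80 is defined on substitutions; the
protocol is silent on gaps), computes transition and transversion
proportions P and Q, and applies the closed form
`K = −½ ln(1−2P−Q) − ¼ ln(1−2Q)`; non-positive log arguments are reported
missing and excluded from means. `estimate_age()` is `T = K/(2r)` in Myr
with the standard plant clock r = 1.3 × 10⁻⁸ site⁻¹ yr⁻¹. Gamma
correction within K80 is not applied (unstated in the protocol; plain K80
implemented). Age histograms use half-open 0.1-Myr bins.

Genomic context: distance to the nearest gene is 0 for overlapping
copies; copies > 1 kb from the closest gene are intergenic; distances of
1–10 kb fall into 1-kb bins (`ceiling(d/1000)`). Distribution comparisons
use the χ² goodness-of-fit of one group's binned counts against the other
group's proportions plus a two-sample KS test on the raw distances — both
two-sided, raw P values, no multiple-testing correction (matching how such
comparisons are conventionally reported).

## eccDNA profiling and junction detection

Reads pairs with either mate mapping to organellar references are removed
first. The minimal mapper (`map_reads()`) seeds exact 21-mers on both
strands, verifies candidates gaplessly and reports the highest-scoring
contiguous core (match +1 / mismatch −4) with soft-clipped flanks;
substitutions are the simulated error model, and indels surface as clips
resolved downstream by affine-gap realignment. Ties break to the lowest
reference id, then position; `n_best` counts equally good placements for
uniqueness filtering. SAM import is provided for externally mapped reads.

RPKM is `count · 10⁹ / (reference length · total mapped)`; candidate
subfamilies are retained at > 500 mapped reads and > 50 % database-hit
fraction — thresholds calibrated to a 500 000-read comparative sample in
the source protocol, exposed as parameters because how to scale them with
library size is unstated. Pairwise enrichment uses the 2×2 χ² without
continuity correction, switching to (seeded) Monte-Carlo simulation when
an expected cell is below 5.

Junction detection distinguishes the two circle topologies. The two-LTR
junction — element 3′ end joined to element 5′ start — occurs nowhere in
the linear element, so any read spanning it with ≥ 15 bp anchors on both
sides is circle evidence. The one-LTR circle has *no locally unique
junction*: both of its LTR/internal boundaries occur verbatim in the
linear element. Its topology reference is therefore internal-end + one
full LTR + internal-start, and evidence requires anchors in the internal
arms on both sides — the read must bridge the entire LTR, which no
linear-element read can do. This is the package's resolution of a real
identifiability gap; it implies one-LTR circles are only detectable by
read-level evidence when the LTR is shorter than the read minus two
anchors (bridgeable by PE150 reads for LTRs ≤ ~120 bp; longer-LTR one-LTR
circles need fragment-length or assembly evidence, which is out of
scope). The junction indel (NHEJ hallmark) is the net inserted minus
deleted bases within ± (max_indel + 2) bp of the circularization point in
the affine-gap realignment; `min_anchor` = 15 and `max_indel` = 20 are
conventions ("small indels" is all the source states) and both are
parameters. Duplicate read sequences are collapsed before counting to
damp rolling-circle amplification bias (off-switch provided).

## Insertion calling and the validation harness

`call_windows()` partitions the genome into fixed 10-kb windows (window
size follows the cited rice implementation; the protocol itself does not
print one) and marks a window as a candidate for subfamily S when ≥ 2
read pairs have one mate hitting S in the element library and the other
mapping *uniquely* into the window. Multi-mapping anchors are dropped, so
insertions into repetitive regions go unreported — matching the stated
limitation of the source pipeline. Reads shorter than 50 bp are discarded
(the protocol's MINLEN).

`refine_breakpoints()` collects soft-clipped reads in the window ± one
window whose clipped sequence matches an LTR terminus (≥ 80 % identity,
either orientation). Matching is shift-tolerant: chance agreement between
the terminus and the reference flank absorbs up to ~6 bp of the terminus
into the aligned core, so the matcher tries small shifts and corrects
each breakpoint by the detected shift — without this, clip clusters are
systematically displaced and TSD inference fails. Breakpoints are
single-linkage clustered (gap > 200 bp separates); the largest cluster
touching the window proper becomes the refined interval (min–max of
corrected clip positions), reported only when its span is ≤ 200 bp. When
left- and right-clip clusters are separated by 2–20 bp, that offset is
the inferred TSD. `compare_samples()` merges calls within 200 bp into
sites and labels them reference (overlapping an annotated copy),
shared-non-reference (≥ 2 samples) or private.

`mask_and_validate()` scores the caller against itself: reference
insertion sites are masked — default *excision* of the element plus one
TSD copy, restoring the pre-insertion allele exactly (an N-replacement
mode is provided, since "masked" is ambiguous) — and every read set is
run against both references. A false positive is a qualifying soft-clip
call at a still-occupied site on the unmasked genome; a false negative is
an emptied site with no soft-clip call. Rates are percentages of
`n_sites × n_samples` cells rounded to one decimal (R's round-half-even);
raw counts are always emitted so any rounding convention can be audited —
note that 2/36 prints as 5.6 % under this convention.

## The synthetic world

`build_genome()` states the world the tests run in: i.i.d. bases at GC
0.38 (an AT-rich plant genome), non-overlapping gene models (~2 kb every
~10 kb), elements planted with exact TSD duplication at well-separated
positions, coding domains reverse-translated from a deterministic
synthetic peptide set (labelled synthetic: it shares the *structure* of a
curated domain database, not real sequence), LTR pairs mutated to a
target K80 divergence with a 2:1 transition:transversion mix (solved for
the per-site substitution probability through the K80 closed form, each
site hit at most once), and PE150 read pairs from normal(400, 60) insert
fragments at per-base substitution error 10⁻³ (conventions for the
sequenced libraries; the source does not state error profiles). All
randomness flows from one explicit seed through a splittable derivation,
and the session RNG state is never touched.

Two generator properties deserve emphasis. First, *boundary
identifiability*: at each planting site up to four bases (TSD first/last,
one base on either side of the duplication) are deterministically
adjusted so the planted boundary is structurally unambiguous — without
this, ~6 % of planted elements in megabase fixtures acquire chance flank
configurations under which two boundary parses are equally valid and
exact-breakpoint recovery is undecidable in principle. A green miner test
therefore establishes exact recovery *of identifiable boundaries*; it
does not bound the boundary error on real genomes, where ambiguous flanks
occur. Second, the error model is substitutions only: no indel errors, no
quality-score structure, no nested elements. Green mapping and calling
tests establish correctness under that model, not robustness to indel-rich
platforms.

## Numerical conventions

Coordinates are 0-based half-open internally, converted at I/O boundaries
(GFF3 1-based inclusive, BED 0-based half-open). Deterministic tie-breaks
throughout: overlap resolution by (identity desc, length desc, leftmost);
subfamily labels by (size desc, smallest member id); family numbers by
(size desc, smallest member id); mapping ties by (reference id, position,
strand). Bootstrap and Monte-Carlo paths take explicit seeds. Saturated
distances, zero-denominator ratios and zero-variance correlations are
reported missing, never clamped or infinite.
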