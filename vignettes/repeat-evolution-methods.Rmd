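---
title: "Methods: reference-free repeat evolution from genome-skimming reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-free repeat evolution from genome-skimming reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`repeatscape` analyzes transposable-element (TE) evolution from
low-coverage shotgun reads, with no reference assembly: reads are
clustered into repeat families by sequence similarity, cluster sizes are
converted into Mb of genome occupancy, LTR-retrotransposon activity is
dated with a molecular clock, cluster sharing is compared across species,
TE insertions in gene-upstream windows are detected from annotations or
from read pairs, and TE-adjacent gene sets are tested for functional-term
enrichment.  A synthetic-genome simulator plants families with known
abundance, age, sharing and gene adjacency, so every stage can be scored
against ground truth.

# The similarity graph and repeat clusters

Two reads are connected when their best local alignment (match +1,
mismatch −1, gap −2) reaches **90% identity over at least 55% of the
shorter read**; identity counts matches over alignment columns, with gap
columns included.  Both orientations are tried and the higher-scoring one
kept; bases outside A/C/G/T never match, and reads with more than 10% N
are dropped up front.  Repeat clusters are the connected components of
this graph, numbered CL1, CL2, ... by decreasing size.  Components smaller
than `significant_fraction` of the input (default 10^-4^, the common
0.01%-of-reads convention for calling a cluster significant) are kept in a
remainder bucket rather than discarded, so reads always partition exactly
into components — which is what makes the occupancy arithmetic below
conserve the genome size identically.

Two choices here were genuinely open:

* **"55% of the sequence length"** is measured against the *shorter* read.
  With reads of equal length the choice is immaterial; with mixed lengths
  the shorter-read convention is the permissive one and is exposed as
  `min_overlap_fraction`.
* **Components, not communities.**  Hierarchical community splitting of
  lobed clusters is out of scope; connected components are the contract
  that the brute-force oracle can also compute exactly.

## The k-mer prefilter is lossless, not heuristic

All-vs-all alignment is quadratic, so candidate pairs are first screened
by shared strand-collapsed (canonical) 8-mers.  The screen is designed to
be a *superset* of the true edges: an alignment with `c` columns at 90%
identity has at most `floor(0.1 c)` non-match columns, so its longest
exact run has at least `ceil(0.9c / (0.1c + 1))` matches — at least 8 for
every `c`, and the *number* of exact 8-mer hits,
`sum(run_i - 7)` over runs, is at least 5 for every `c >= 55`.  The
default therefore requires 3 shared 8-mers (margin 2 against rare
duplicate k-mers inside a read) and cannot lose an edge when the shorter
read is ≥ 100 nt, while discarding ~99.6% of random read pairs.  For
read sets shorter than 100 nt, `min_shared_kmers = 1` restores the
unconditional guarantee.  A second exact bound skips the alignment
traceback whenever the score-only pass shows the pair cannot reach the
thresholds (a qualifying alignment scores at least `(3t − 2) · c₀` under
+1/−1/−2 scoring at identity threshold `t` and minimum columns `c₀`).

# Genome occupancy

Cluster sizes convert to genome space by

    occupancy_mb = cluster_read_length_mb × genome_size_mb / denominator_mb

The classical formulation divides by the total length of all *clustered*
reads, which forces repeat occupancies to sum to 100% of the genome —
inconsistent with the 60–75% genome proportions such analyses report.
`repeatscape` divides by the total length of **all analyzed reads**
(clustered and unclustered), so that summing over every component —
significant clusters plus remainder — reproduces the genome size exactly,
while the significant-cluster total yields the genome proportion
attributable to repeats.  The literal all-clusters denominator remains
available behind `literal_denominator = TRUE`.

# Molecular-clock dating

For each LTR cluster and species, reads are assembled into a consensus
contig (greedy overlap-layout in rounds: seed with the longest read,
batch-align all pending reads per round, place every read that overlaps
the contig by ≥ 30 nt at ≥ 90% identity, majority-vote the columns).  Up
to 400 reads are used, giving ~25× element depth for a 1.5 kb element at
100 nt reads — depth ≥ 10 is what keeps majority-vote consensus error well
below the divergence being measured.  The LTR segment is then located by
local alignment against LTR exemplars at **85% identity over ≥ 80 nt**,
and the cluster's reads are mapped back to that consensus LTR (span ≥ 50
columns at ≥ 80% identity; the identity floor exists because thresholdless
local alignment lets unrelated reads accrete ~60–65%-identity gapped
alignments that would contaminate the distribution, while 80% identity
still admits any divergence younger than ~15 My at the default clock).

Divergence converts to time through the grass TE substitution rate
**r = 1.3 × 10⁻⁸ substitutions per site per year**, with two conventions:

* **consensus mode** (`age = d / r`): the consensus approximates the
  ancestral state, so each read's divergence accrued along one lineage;
* **pair mode** (`age = d / 2r`): two sister sequences — the two LTRs of
  one element, identical at insertion — diverge along two lineages.

`identity_to_age()` exposes both; `date_element_by_ltr_pair()` is
intrinsically pair-mode.

## Peak versus pooled identity

Whether "peak activity" should be the histogram mode, the mean, or a
smoothed peak is an open methodological question.  `peak_activity()`
implements the modal 1%-bin midpoint (ties toward higher identity), which
matches how activity histograms are read.  As a *point estimator of age*,
however, the modal bin is lattice-limited: a 100 nt read carries an
integer number of mismatches, so identities concentrate on multiples of
1/span and the zero-mismatch class dominates the top bin for any family
younger than ~1.5 My, collapsing its apparent age to the top-bin midpoint
(~0.4 My at this clock).  `date_cluster()` therefore estimates age from
the **pooled identity** — total matches over total aligned columns across
mapped reads — which is the maximum-likelihood divergence for a
single-burst family, is continuous in age, and recovers planted bursts of
0.5–5 My within ±20% in the validation suite.  Both quantities are
reported side by side in the activity timeline; for multi-burst histories
(explicitly out of scope for deconvolution) the histogram remains the
honest display.

A constant `error_rate` may be subtracted from d to discount sequencing
error (default 0).  No multiple-hit (Jukes–Cantor) correction is applied,
neither when planting mutations nor when dating: at r = 1.3 × 10⁻⁸ and
ages ≤ 10 My the per-site substitution probability is ≤ 0.13 and the
multiple-hit discrepancy is below 0.1% divergence, smaller than the
sampling noise at these read depths.

# Synthetic genomes with planted truth

`simulate_genome()` lays out one chromosome from placement units —
TE copies, genes, and TE-upstream-of-gene composites — separated by
random background spacers of at least `min_spacer` bp.  Each TE copy is
the family consensus (5′LTR–internal–3′LTR) with every site independently
substituted with probability `min(r · t, 0.75)` for its age `t` drawn from
a truncated normal; because all sites mutate independently, a copy
diverges from the consensus at rate `r·t` while its two LTRs diverge from
each other at `2·r·t` — the two dating conventions are thus planted, not
assumed.  Substitution-only decay (indels default to 0) keeps identity
arithmetic exactly invertible for the dating tests.  Coordinates are
0-based half-open internally and convert to 1-based GFF3 on write; genes
are non-overlapping with uniform strands, and "upstream" is 5′ of the
gene start on the gene's own strand.  Reads are uniform-start,
random-strand, with per-base substitution errors and constant Q40
qualities (quality trimming is out of scope).  Every placement is recorded
in a truth ledger whose per-family interval lengths equal the realized
occupancy by construction.

What the simulator does **not** emulate: nested insertions, solo-LTR
recombinants, satellite arrays, GC/chromatin biases, and indel decay.
Passing recovery tests therefore demonstrates correctness of the
estimators under the stated generative model, not robustness to every
property of real genomes.

# Study designs bundled with the package

The demo design (`demo_config()`) uses three 0.7 Mb species, each ~60%
repeat-derived — echoing the repeat content of grass genomes — via two
shared families (gypsy at 1.0 My, copia at 2.0 My, 0.15 Mb each) and one
private family per species (0.12 Mb), with 20 genes, 0.5× coverage of
100 nt reads, and 1500 reads per species pooled for the comparative
stage.  Genome sizes are scaled down ~4000× from real grasses so a full
multi-species run completes in about two minutes; read depth over each
repeat family (hundreds of reads per element) is kept in the regime where
cluster connectivity and abundance sampling error (~5% relative) behave
as they would at scale.  A fourth, repeat-sparse species carries the
read-pair proximity design: 6 kb minimum spacers keep TE-free genes
genuinely isolated, and planted upstream distances are drawn within
1–300 bp because mate-pair evidence with an 800 nt insert cannot span
farther — read-pair proximity detection is intrinsically limited to the
insert range.

The validation suite additionally uses: a four-family burst design at
0.5/1/2/5 My for clock recovery; random interval fixtures checked against
an exhaustive all-pairs scan for the upstream-window logic; enumeration of
all C(N, n) draws for the hypergeometric tail at N ≤ 12; and a 1000-rep
null simulation confirming BH control (observed per-term rejection rate
≤ 6% at q < 0.05).

# Gene proximity and enrichment

Reference mode takes the strand-aware window `[start − 5000, start)` (+
strand) or `[end, end + 5000)` (− strand); a TE hits when its interval
overlaps the window at a gene-ward gap of at least 1 bp (overlapping or
abutting elements are excluded), binned per kb.  Read-pair mode follows
the BWA-aln parameter contract (12 nt seed with ≤ 2 mismatches, ≤ 4 total
edits, ≤ 3 gap opens, ≤ 3 gap extensions; penalties 2/6/3) as a
seed-and-extend scoring contract — best-penalty target wins and mates with
equal-best targets of different classes are discarded as ambiguous, rather
than replicating any particular aligner's tie-breaking.  A pair is
TE-near-gene evidence when one mate's best target is a TE contig and the
other's is a gene.

Enrichment is a one-sided hypergeometric test over a flat gene-to-term
table (no GO DAG propagation), with Benjamini–Hochberg FDR via
`stats::p.adjust` and the background fixed to the gene universe used for
proximity — not the whole genome.  E-value thresholds of database search
tools are replaced throughout by (identity, length) thresholds — 80%/50 nt
for read matching, 85%/80 nt for LTR extraction — which are deterministic
and independent of database size at this scale.

# Numerical conventions and degenerate inputs

* Identity is always matches / alignment columns, gaps counted.
* Histogram bins are `[k·w, (k+1)·w)` with identity 1 assigned to the top
  bin; modal ties resolve toward higher identity (younger).
* Plurality ties in cluster annotation resolve by higher mean identity,
  then lexicographic name; majority ties in consensus columns resolve to
  the alphabetically first base.
* Clusters with fewer than 3 reads per species refuse consensus assembly;
  distributions with fewer than 5 identities refuse peak estimation; LTR
  pairs aligning below 50% identity are rejected as implausible — all are
  flagged, never silently dropped.
* Empty inputs, desynchronized mate files, infeasible genome profiles and
  malformed configs raise typed errors carrying every detected problem.

# Determinism

Every stochastic step takes an explicit seed; the pipeline derives one
sub-stream per stage from the master seed, and no output carries a
timestamp, so a rerun with the same configuration and seed is
byte-identical — verified file-by-file in the test suite.

# Known limitations

Community structure inside lobed clusters is not split; paired-end
information is unused during clustering; dating assumes a single
amplification burst per cluster × species (no mixture deconvolution); the
read mapper is a scoring contract, not a full aligner with mapping
qualities; and enrichment treats terms as flat sets.  These mirror the
package's non-goals and keep every retained behavior testable against an
independent oracle.
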