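---
title: "Assigning archival specimens to genetic lineages by barcode fishing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning archival specimens to genetic lineages by barcode fishing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Museum type specimens fix which population carries a scientific name, but
many are a century old and their DNA is heavily fragmented. When a nominal
species turns out to contain several deep genetic lineages, the name can
only be allocated by sequencing the name-bearing type and placing it among
the candidate lineages. Target-enrichment ("barcode fishing") makes this
practical: short mitochondrial barcode fragments (16S, cox1, cyt-b) are
captured from the archival extract, sequenced as short single-end reads,
and reconstructed against a reference panel of the candidate lineages.

`barcodefish` implements the downstream analysis of that design as a
tested, reusable pipeline:

1. **fishing** — quality/adapter trimming, then retention of reads whose
   best local-alignment identity against any panel reference reaches a
   similarity threshold (default 90%), each read assigned to the locus of
   its best reference;
2. **consensus** — semi-global placement of retained reads on a per-locus
   reference and a strict-majority, minimum-depth consensus call in
   reference coordinates, with per-position coverage and
   recovery/missing-run statistics;
3. **assignment** — lineage-diagnostic alignment columns (fixed within
   each candidate group, different between them), scored against the
   partial consensus;
4. **placement** — TN93 distances, neighbor-joining and nonparametric
   bootstrap supports for the consensus among the panel sequences;
5. **traits** — the morphometric ratio/range diagnostics and
   minimum-convex-polygon range area that accompany such a taxonomic
   treatment.

Because raw archival read sets are rarely deposited, the package ships a
synthetic archival-read generator so that every stage — and the pipeline
end to end — is testable without any download.

## The synthetic archival specimen

`sim_config()` describes the scenario the package targets, and its
defaults are the study conditions used throughout the tests:

| parameter | default | meaning |
|---|---|---|
| `loci` | 16S, 501 nt | one barcode locus of typical fragment length |
| `n_lineages`, `members_per_lineage` | 2, 5 | two candidate lineages, five references each |
| `between_divergence` | 0.03 | substitutions/site ancestor→founder, so lineages sit ~6% apart |
| `within_diversity` | 0.005 | substitutions/site founder→member |
| `read_length` | 75 | single-end read length |
| `fragment_mean`, `fragment_sd` | 60, 15 | normal fragment lengths, truncated to ≥ 20 nt |
| `n_reads` | 170 | ≈ 20× mean depth on a 501 nt locus with ~60 nt fragments |
| `error_rate` | 0.002 | uniform per-base sequencing error |
| `deam_rate`, `deam_decay` | 0.2, 3 | C→T (5′) / G→A (3′) probability `0.2·exp(−i/3)` at distance `i` from the fragment end |
| `contam_fraction` | 0.10 | reads drawn from off-target contaminants |
| `coverage_dropout` | none | reference intervals that yield no fragments |

Lineage simulation uses a uniform (Jukes–Cantor-style) substitution
process: it is the simplest process sufficient to test assignment, and the
TN93 machinery is validated separately against its closed form. Two
founders independently mutated at rate *d* from a common ancestor differ
per site with probability `2d(1−d) + (2/3)d²`; the test suite checks the
simulator against this expectation by Monte Carlo. With `d = 0.03` the
expected uncorrected distance between lineages is ≈ 5.9%, matching the
5–7% range typical of deeply diverged mitochondrial frog lineages.

Fragments are sampled uniformly outside the configured dropout intervals,
which reproduces the long interior stretches of missing consensus that
real archival captures show. Damage is substitution-only (no indel damage
model, no formalin crosslinks) and qualities are constant Q37, because
trimming behaviour is exercised with hand-built reads instead. Reads are
emitted forward-strand by default; `revcomp_fraction = 0.5` exercises the
strand handling of the fishing and placement stages. No PCR-duplicate
model is included: the pipeline deliberately keeps clonal reads, as a
majority-based assembly wants all observations.

What passing these tests does *not* show: real archival damage is not
uniform along the molecule and correlates with fragment length; real
contamination is phylogenetically structured (human, microbial, congeneric
cross-capture) rather than random sequence; and real base-quality profiles
decay along the read. The generator's parameters are tunable, not
calibrated to any particular specimen.

## Numerical and design choices

**Identity metric.** "Similarity to the references" is implemented as
matches / alignment columns of the best local alignment (match +1,
mismatch −1, gap open −2, gap extend −1), both strands tried; mismatch and
gap columns count in the denominator, and ambiguous (N) positions never
count as matches. Alignments spanning fewer than `min_aligned_length`
(default 30) columns are treated as no hit, which prevents short spurious
perfect matches from passing the threshold. Published descriptions of
read-fishing scripts rarely pin down this metric; retention counts from
other implementations are therefore comparable only approximately.

**Trimming.** The 3′ adapter is removed at the longest read-suffix /
adapter-prefix overlap of ≥ 8 nt with at most one mismatch per 10 nt.
Quality trimming cuts at the first sliding 5 nt window whose mean phred
drops below 20, with the cut landing on the first sub-threshold base in
that window — so an exactly-6-base bad tail loses exactly 6 bases.

**Consensus.** Reads are placed with a semi-global alignment (read fully
aligned, reference local). Read insertions relative to the reference are
dropped so the consensus lives in reference coordinates and the reported
alignment lengths equal the reference length; reference positions deleted
in the read are recorded and a deletion can win a column's majority (it is
then a recovered position). A column is called only when coverage reaches
`min_depth` (default 3) and one state has a strict majority
(`> majority_fraction`, default 0.5); exact ties give N, unless the
optional IUPAC mode encodes two-base ties. The majority-based assemblers
used in practice do not publish their thresholds; depth 3 balances
usability of the low-coverage tail of archival captures (single-figure
depths) against error suppression, and both knobs are exposed.

**Diagnostic sites.** A column is diagnostic iff every focal group is
monomorphic at it after ignoring missing characters (N/?/-) and the group
states are pairwise distinct. Missingness is ignored rather than treated
as a fifth state because the query is expected to be partial: the point is
to score only recoverable positions. Fixity is assessed over the supplied
panel — a panel that under-samples a lineage's range can therefore
overstate diagnosability, which is a property of the data, not the
algorithm. The verdict requires a strict majority of agreeing sites;
equality is reported as "ambiguous" rather than forced. The same
machinery runs at phylogroup level, which is how a query can "agree with
lineage members outside its nearest phylogroup".

**Distances and trees.** TN93 is computed from the pooled base
frequencies of each pair under pairwise deletion; saturated pairs (any
non-positive logarithm argument) are flagged undefined (`NaN`) rather than
silently clamped, and `nj_tree()` refuses matrices containing them, naming
the pair. The gamma-shape parameter is user-supplied; plain TN93 is the
default since shape estimates are rarely reported alongside published
trees. Neighbor joining replaces full maximum-likelihood search here
deliberately: the placement question — which lineage's clade contains the
query — is topological, and NJ on TN93 distances answers it at a fraction
of the cost; the package makes no attempt at ML optimisation or model
selection. Negative NJ branch lengths are clamped to zero with the deficit
reported. Bootstrap supports are percentages of column-resampled
replicates containing the same leaf bipartition; replicates with undefined
distances are skipped and a warning is raised if more than 10% are.

**Range polygon.** The minimum convex polygon of occurrence localities is
the planar convex hull of the decimal-degree coordinates, with its area
evaluated on a sphere of radius 6371.0088 km (via `geosphere` with zero
flattening) and rounded to 3 significant figures — consistent with the
"approximate area" such assessments quote. Published extent-of-occurrence
figures typically draw on more localities than a taxonomic treatment
prints,
so the bundled eight-locality hull is validated for order of magnitude
(10⁴ km²), not to a printed value.

**Rounding.** Ratio diagnostics round half away from zero
(98.07 → 98, 66.67 → 67), the convention consistent with the printed
values they reproduce. Subadults are excluded from adult size ranges
unless requested; holotype/paratype status implies adult unless a
subadult flag is present.

**Seeds.** Every stochastic step takes a seed and restores the caller's
RNG state, so a single pipeline seed fans out deterministically: identical
configuration and seed give byte-identical FASTQ, truth JSON and report
JSON (wall-clock aside).

## Problem sizes used by the tests

The test suite and the acceptance script run entirely on synthetic data at
desk scale: panels of 10 reference sequences on a 501 nt locus, 170 reads
per simulated specimen (~20× depth), 20 replicate specimens for the
recovery rate, 100-500 bootstrap replicates, 100-250 Monte-Carlo
replicates for the simulator calibration checks, and a 100-read set for
the exhaustive dynamic-programming cross-validation of the fishing stage.
These sizes were chosen so each check isolates one property at comfortable
statistical resolution.

## Known limitations

- No probabilistic, damage-aware alignment or base recalibration: a
  deaminated terminal C→T is evidence like any other mismatch. At the
  default damage rates the majority vote absorbs this, but single-read
  columns can carry damage into the consensus (they are masked by
  `min_depth` ≥ 3 unless coverage is marginal).
- Paired-end data, indel-rich loci and de-novo assembly are out of scope.
- The assignment model is a count of fixed differences, not a likelihood;
  it reports "ambiguous" rather than a posterior when evidence conflicts.
- GenBank access is not built in: external validation against deposited
  consensus sequences is done by handing the downloaded FASTA to
  `score_query()`/`bootstrap_tree()` like any other query.
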