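# barcodefish

Assigning degraded archival-DNA specimens — typically century-old museum
types — to candidate genetic lineages from short sequencing reads and a
panel of mitochondrial barcode references (16S, cox1, cyt-b).

When a nominal species is found to contain several deep lineages, the
scientific name follows the name-bearing type specimen. Target-enrichment
("barcode fishing") recovers short barcode fragments from the type's
degraded extract; this package implements the downstream analysis as a
tested pipeline:

- **fishing** — quality/adapter trimming, then retention of every read
  whose best local-alignment identity to any panel reference reaches a
  similarity threshold (default 90%); identity is
  *matches / alignment columns* of the best local alignment
  (match +1, mismatch −1, gap open −2, gap extend −1), both strands tried;
- **consensus** — semi-global placement of retained reads on a per-locus
  reference and a strict-majority call per column (depth ≥ 3 by default;
  ties and thin columns give N), with per-position coverage, recovery
  counts and missing-run statistics in reference coordinates;
- **assignment** — *lineage-diagnostic positions*: alignment columns
  monomorphic within each candidate lineage and different between them,
  scored against the partial consensus; the verdict is the lineage with a
  strict majority of agreeing sites;
- **placement** — Tamura–Nei (TN93, optionally +Γ) distances under
  pairwise deletion, neighbor-joining, and nonparametric bootstrap
  supports; plus uncorrected (p) distance ranges between groups;
- **simulation** — a synthetic archival-read generator (short fragments,
  75 nt single-end reads, terminal C→T/G→A deamination, sequencing error,
  contamination, coverage dropout) so every stage is testable offline;
- **traits** — morphometric ratio/range diagnostics from a specimen
  measurement table and minimum-convex-polygon range areas on the sphere.

Everything is tibble-in/tibble-out and pipe-friendly; result objects have
broom-style `tidy()`/`glance()` methods and ggplot2 `autoplot()`s.

## Worked example

Simulate an archival specimen from a two-lineage complex (~6% divergent,
five reference individuals per lineage), withhold one lineage-1 individual
as the "type", degrade it to 75 nt reads with deamination, error and 10%
contamination, and run the pipeline:

```r
library(barcodefish)

cfg <- sim_config(seed = 7, members_per_lineage = 6,
                  coverage_dropout = list(c(150, 230)))
sim <- simulate_lineages(cfg)
panel <- sim$panel[sim$panel$id != "16S_L1_m6", ]   # 11-sequence panel
query <- sim$panel[sim$panel$id == "16S_L1_m6", ]   # withheld individual
set.seed(99)
contam <- tibble::tibble(id = "contam",
  seq = paste(sample(c("A","C","G","T"), 600, TRUE), collapse = ""))
reads <- degrade_and_read(query, cfg, contaminants = contam)$reads

report <- run_pipeline(reads, panel, bootstrap_replicates = 200, seed = 1)
cat(render_report(report))
```

which prints:

```
# Barcode-fishing run report

## Read accounting

- total input reads: 170
- removed by trimming: 0
- retained at similarity threshold: 152
  - 16S: 152

## Consensus recovery

- 16S: 395 of 501 nt recovered (3 missing run(s), max coverage 38)

## Diagnostic-site assignment

- 16S (lineage level): 20 informative of 27 sites (0 off-pattern);
  agreements L1: 20, L2: 0; verdict **L1**

## Combined verdict: **L1**

- between-group uncorrected distance range: 5.4% to 7.0% (30 pairs)
```

Reading it: of 170 reads, 152 passed the 90% similarity filter (the
contaminant reads did not); the majority consensus recovered 395 of the
501 reference positions, the gaps being the configured dropout interval
plus sampling holes; all 20 diagnostic positions at which the partial
consensus has a call agree with lineage L1 and none with L2, so the
specimen is assigned to L1 — its true origin. The accompanying NJ tree
places `query_16S` inside the L1 clade with 100% bootstrap support for
the L1/L2 split. `tidy(report$objects[["16S"]]$assignment)` gives the
per-site table behind the verdict, and
`autoplot(report$objects[["16S"]]$consensus)` the coverage profile.

The traits module reproduces printed morphometric diagnostics from the
bundled specimen table, e.g. the foot/tibia ratio of holotype
ZSM 2078/2007:

```r
m <- load_measurements(system.file("extdata",
  "mantidactylus_measurements.tsv", package = "barcodefish"))
hol <- m[m$catalogue == "ZSM 2078/2007", ]
ratio_percent(hol$FOL, hol$TIBL)   # 98
ratio_percent(hol$TD, hol$ED)      # 67
group_range(m, "SVL", species = "Mantidactylus ambony", sex = "M")
#   min   max     n
#  30.8  32.5     3
```

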