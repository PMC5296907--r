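# nomefoot

Single-molecule nucleosome and footprint analysis for NOMe-seq amplicon
data.

NOMe-seq treats nuclei with the GpC methyltransferase M.CviPI, which
methylates cytosines in GpC dinucleotides that are not protected by a
nucleosome or a tightly bound protein; bisulfite sequencing then reads that
mark — together with endogenous CpG methylation — on every individual
molecule. `nomefoot` is for researchers analysing such footprinting data at
promoter-scale amplicons (the setting where pol III promoter architecture —
tRNAs, U6, vault RNAs — was dissected molecule by molecule): it turns
bisulfite-converted molecules into per-site accessibility states, calls
nucleosomes and sub-nucleosomal protein footprints on each molecule,
aggregates strand-aware anchored accessibility metaplots, detects
nucleosome-depleted regions (NDRs) and positioned-nucleosome centers,
contrasts native against salt-washed chromatin to separate protein
footprints from histones, and classifies promoter activity from ChIP
evidence. A fully parameterised simulator with ground truth makes every
stage testable without external data.

## The rules at the core

For each molecule, per-site states over informative cytosines
(GCH = accessibility channel; HCG = endogenous channel, or a second
accessibility channel in dual M.CviPI + M.SssI mode; GCG excluded as
ambiguous) are segmented into maximal protected runs. With the protected
span measured between the nearest flanking accessible sites:

* span ≥ 146 bp → **nucleosome** (one histone-core wrap of DNA),
* 25 bp < span < 146 bp within ±150 bp of the TSS or TTS → **footprint**,
* ≥ 2 protected sites per run, and isolated accessible sites inside runs are
  treated as missing — both guards calibrated to the assay's ~0.9%
  bisulfite inconversion noise floor.

Aggregate percent accessibility at offset *x* is
`100 · accessible / (accessible + protected)` pooled over all reads covering
*x*; the NDR is the maximal anchor-containing interval ≥ 0.6·max, and
nucleosome centers are prominence-filtered troughs refined to
valley-floor centroids.

## Worked example

Simulate six tRNA-like promoter loci (dyads at −150/+220 bp, occupancy 0.8,
a salt-resistant TFIIIB-like footprint at [−45, −5) and a salt-labile
polymerase-like footprint at [5, 55), enzyme efficiency 0.95, 0.9%
inconversion), run the whole pipeline, and inspect the summary:

```r
library(nomefoot)
cfg <- run_config(seed = 1, n_loci = 6, n_molecules = 60)
s <- run_pipeline(cfg, "demo_out")

s$troughs
#>       center raw_offset     value prominence
#> 1 -151.66667       -145 20.000000   52.22222
#> 2  -25.00000        -25  9.259259   86.45503
#> 3   26.13636         15  9.861111   14.18651
#> 4  215.52632        195 19.523810   74.69841

s$ndr$found        # FALSE
s$ndr_salt         # start 0, end 150
s$salt_flagged
#>   start end n_bins mean_delta max_delta
#> 1     0  60      6   82.63426  88.88889

sapply(s$occupancy, function(o) o$fraction)
#> 0.7694444 0.7833333
```

Reading the numbers: the trough table recovers all four protection features
of the simulated architecture — the −1 nucleosome near −152, the +1
nucleosome near +216 (both within the jitter of the true −150/+220 dyads),
and the two TSS-proximal footprints at −25 and +26, whose valleys are deep
(accessibility ~9%) because they are present in 90% of molecules. Because
those footprints sit at the anchor, the *native* profile has no NDR at the
TSS (`s$ndr$found` is FALSE) — the salt-washed profile, with the labile
footprint stripped, shows the open region from 0 to +150. The condition
comparison flags exactly one interval, [0, 60), the salt-labile footprint:
an accessibility gain of ~83 percentage points, while the salt-resistant
upstream footprint and both nucleosome regions are untouched. Per-dyad
occupancy recovered from single-molecule nucleosome calls is 0.77–0.78
against a simulated 0.8. With TSS footprints present, the troughs nearest
the NDR are the footprints themselves, so read `minus_one`/`plus_one`
together with the trough table (and the per-molecule calls BED) rather than
in isolation.

All artifacts (reference and read FASTA, per-molecule state TSV, calls BED,
per-condition profile TSVs, features and summary JSON with every threshold
echoed) are written to `demo_out/`. A thin command-line wrapper with
`simulate`, `call`, `regions`, `aggregate`, `compare`, `classify` and
`demo` subcommands lives at `inst/scripts/nomefoot-cli.R`.

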