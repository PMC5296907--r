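---
title: "Single-molecule nucleosome footprinting with nomefoot: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-molecule nucleosome footprinting with nomefoot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nomefoot)
```

## The assay and the measurement model

NOMe-seq probes chromatin accessibility with an exogenous GpC
methyltransferase (M.CviPI): cytosines in GpC dinucleotides that are not
protected by a nucleosome or a tightly bound protein are methylated, and
bisulfite sequencing then reads the methylation state of every cytosine on
every sequenced molecule. Because the exogenous GpC mark and the endogenous
CpG mark live in different trinucleotide contexts, one molecule yields two
coupled signals:

* **GCH** (GpC not followed by G) — the accessibility channel: methylated
  means the enzyme reached the site, i.e. the site was *accessible*;
  unmethylated means *protected*.
* **HCG** (CpG not preceded by G) — the endogenous methylation channel.
* **GCG** — the two contexts overlap; enzymatic and endogenous signal cannot
  be separated, so these sites are excluded from state calling (they are
  still chemically methylated in simulation, which is precisely why they are
  useless analytically).

In *dual* mode a CpG methyltransferase (M.SssI) is added so that HCG sites
also report accessibility, roughly doubling informative-site density. This
is only valid where the locus is endogenously unmethylated;
`check_dual_eligibility()` enforces a mean-HCG-methylation bound (default
0.10) and `apply_chemistry()` records a warning when a dual simulation is
configured on a methylated locus. For a monoallelically methylated locus the
per-molecule endogenous means are bimodal at 0 and 1 while the locus mean
sits near 0.5 — the eligibility check rejects it, as it must.

Bisulfite conversion is imperfect: an unmethylated cytosine survives
conversion with probability `inconversion_rate` (default 0.009, i.e. the
0.9% noise floor typical of the assay), and appears spuriously methylated —
on the accessibility channel, spuriously *accessible*. Every design choice
in the calling layer is shaped by this one number.

## Single-molecule region calling

On each molecule, maximal runs of protected sites are classified by the
length of the protected span, defined as the open interval between the
nearest flanking accessible sites (exclusive). This is the only span
definition that is exact at dense site spacing (flanks 147 bp apart bound a
146 bp span) and conservative at sparse spacing; where a run has no flank,
the span is truncated at the outermost informative site rather than
extrapolated.

* span ≥ 146 bp → **nucleosome** (one histone-core wrap);
* 25 bp < span < 146 bp, intersecting ±150 bp of the TSS or TTS →
  **footprint** (sub-nucleosomal bound protein);
* anything else → `unclassified_protected`.

The 146 and 26 bp bounds are the assay's published calling rules; the
±150 bp anchor window is a configurable choice (the rule is stated only as
"around the TSS or TTS").

Two guards address the noise floor symmetrically:

1. a run must contain at least two protected sites — a single protected site
   is within reach of enzyme inefficiency (default efficiency 0.95 leaves 5%
   of open sites unmethylated);
2. an isolated *accessible* site whose informative neighbours are both
   protected is treated as missing (`denoise = TRUE`). A nucleosome covers
   roughly 9–10 GpC sites at realistic spacing, so at a 0.9% inconversion
   rate about one molecule in eight would otherwise have its nucleosome run
   split into two sub-146 bp fragments and silently dropped; the resulting
   occupancy underestimate (~0.07 absolute at occupancy 0.8) would exceed
   the recovery tolerance this package holds itself to. Treating the
   singleton as missing (not protected) bridges the run without fabricating
   protection evidence.

Occupancy over a window counts a molecule as occupied when a called
nucleosome overlaps at least half the window, yielding the "k of n molecules
occupied" readout of single-molecule maps.

## Aggregate profiles

`build_metaplot()` pools site-observations across molecules and loci —
read-level pooling, not per-locus averaging — into signed-offset bins
(default 10 bp) anchored at the TSS or TTS, negating offsets on minus-strand
loci. Percent accessibility per bin is `100 * accessible / (accessible +
protected)`; missing observations are tracked but excluded from the ratio.
TTS anchoring is a separate aggregation pass, not a rescaling of the TSS
profile, because gene lengths differ.

Smoothing (default 20 bp) is a centred running mean in which each bin
contributes by the length of its overlap with the window times its
coverage — equivalently, the pooled accessible fraction over the window.
This gives exact closed-form behaviour at the edges of a window (an impulse
of height *h* becomes a plateau of *h*·bin/window) and degrades gracefully
where coverage is uneven.

The NDR is the maximal contiguous interval containing the anchor where the
smoothed profile stays at or above θ·max (θ = 0.6, maximum taken within
±1 kb). Two degenerate cases are handled explicitly: if the anchor bin is
below threshold there is *no* NDR (an empty result, not an error), and an
absolute floor of 25 percentage points prevents a uniformly closed profile
from "containing" a vacuous NDR.

Nucleosome centers are troughs of the smoothed profile with prominence of at
least 5 points. A well-positioned nucleosome produces a *flat-bottomed*
valley roughly `146 − 4·jitter_sd` bp wide, so the location of the raw
minimum within the floor is noise, not signal; each trough is therefore
refined to the coverage-weighted centroid of its valley floor (bins within
2 points of the minimum). The −1/+1 nucleosomes are the troughs nearest the
NDR on each side, and the phasing period is the median spacing of successive
troughs per side.

`compare_conditions()` flags intervals where the salt-washed profile gains
at least 10 points over the native profile across at least two consecutive
*defined* bins. A 400 mM NaCl wash removes chromatin-associated proteins but
not histones, so gains localise to protein footprints while nucleosomal
spans stay put; bins without defined values (coverage gaps between sparse
sites) carry no evidence either way and neither break nor extend a run.

## What the simulator emulates, and what it does not

`simulate_molecules()` + `apply_chemistry()` emulate the physical steps:
per-molecule nucleosome occupancy (independent Bernoulli per dyad) with
truncated-normal dyad jitter, sub-nucleosomal footprints with per-molecule
presence, enzymatic labelling of unprotected target cytosines with
efficiency 0.95, endogenous CpG methylation (scalar rate or
allele-structured patterns), bisulfite conversion with a 0.9% failure rate,
and full-length clone-style amplicon reads on either strand of the amplicon.
A salt-washed condition removes exactly the footprints flagged salt-labile.

Defaults are meant as realistic study conditions, chosen once: GpC spacing
16 bp (the expected dinucleotide frequency), nucleosomal protection
dyad ± 73 bp, dyads at −150/+220 with occupancy 0.8 and 20 bp jitter for the
tRNA-like architecture, and a TSS-proximal footprint pair — an upstream
salt-resistant 40 bp footprint at [−45, −5) (TFIIIB-like) and a downstream
salt-labile 50 bp footprint at [5, 55) (polymerase-like) — each present in
90% of molecules. Motif placement is jittered within the spacing grid so
site phases decorrelate across loci, as they do in real sequence.

One modelling choice deserves emphasis. The configured `ndr` interval acts
as a remodeler-enforced clearing: nucleosomal protection is clipped out of
it, while footprints inside it are untouched. Without this, a −1 dyad at
−150 with 146 bp protection necessarily ends at −77 and no architecture
could simultaneously exhibit the canonical dyad positions and an NDR
spanning [−100, +200). The biological reading is that remodelers hold the
NDR open against nucleosome encroachment; the analytical consequence is
that NDR-clipped nucleosomes protect less than 146 bp and are deliberately
*not* called as nucleosomes on single molecules — occupancy questions
should be asked of architectures without clipping (or of windows away from
the NDR).

The simulator does **not** model sequencer errors, PCR duplicates, short
reads or alignment artifacts, variable fragment boundaries, CpG-density
biology (motifs are planted, not evolved), or linker-specific sequence
preferences. Passing tests therefore demonstrate correctness of the
measurement and calling logic under the assay's dominant noise sources —
enzyme inefficiency and bisulfite inconversion — not robustness to
alignment-era artifacts, which are out of scope for amplicon data.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere; anchored offsets are signed
  with 0 at the anchor base. Minus-strand context sites are recorded at the
  plus-strand position of the paired G.
* Dyad jitter uses rejection sampling into the admissible range (protection
  fully inside the reference), with a clamp as a last resort.
* Trough ties are broken leftmost; trough prominence is the smaller of the
  maximal rises to the nearest lower point (or edge) on each side.
* `smooth_profile()` refuses windows narrower than a bin;
  `compare_conditions()` refuses mismatched binnings; occupancy over zero
  molecules, eligibility without HCG sites, z-scores of constant tracks and
  impossible site spacings are explicit errors.
* Reads of the wrong length are an error (amplicon reads are full-length by
  construction); a read with zero informative sites is returned all-missing
  with a warning, not dropped silently.
* All randomness flows through per-call seeds; fixed seeds give bit-identical
  outputs, including across the end-to-end pipeline.

## Problem sizes used in the checks

The package's own acceptance checks run at desk scale, chosen to make the
statistical tolerances meaningful: threshold exactness on constructed dense
molecules (spans 140–150 and 10–40 bp); the inconversion floor on ≥10^5
protected cytosines (3 binomial SEs); brute-force oracle agreement on 1,000
random molecules of ≤30 sites; architecture recovery on 50 loci × 500
molecules (troughs within ±20 bp, NDR bounds within ±1 bin, single-dyad
occupancy within ±0.08); and salt-differential specificity across 100
replicates of 10 loci × 60 molecules (≥95 must flag the labile footprint
and nothing else).

## Known limitations

ChIP-based activity classification uses a peak-overlap OR mean-z ≥ 1.64
rule; the exact criterion used for published genome-wide active/inactive
splits is not reproducible without the original external tracks, so those
counts (e.g. 203/225 active tRNAs) are outside what this package can or
tries to verify. Genome-scale bisulfite alignment and methylation calling
are likewise out of scope: inputs here are amplicon-style molecules already
in reference coordinates.
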