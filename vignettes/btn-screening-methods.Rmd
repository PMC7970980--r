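---
title: "Screening mussels for transmissible cancer: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening mussels for transmissible cancer: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btnscreen)
library(dplyr)
```

## The problem

Bivalve transmissible neoplasia (BTN) is a clonally transmissible cancer
of mussels: living cancer cells pass between individuals through the
water column and proliferate in the hemolymph as aneuploid,
hemocyte-like cells (disseminated neoplasia, DN). Because the cancer is
a clone descended from a long-dead "patient zero", its genotype differs
from its current host's and is shared across infected individuals. Those
two facts drive the whole diagnostic chain this package implements:

1. **Flow cytometry** of hemolymph flags specimens with an extra
   population of aneuploid cells (DN-suggested).
2. **Molecular cloning** of PCR products from paired tissues (hemolymph
   vs foot) yields per-tissue allele sets with frequencies.
3. **Chimerism detection** identifies "extra" alleles enriched in the
   hemolymph relative to the same animal's foot.
4. **BTN calling** requires two kinds of evidence: chimerism, and
   identity of the extra alleles across diseased individuals (the shared
   cancer genotype).
5. **Lineage assignment** places the cancer alleles against a BTN1/BTN2
   reference panel by p-distance, supports a haplotype network view, and
   scans cancer control-region alleles for the recombinant
   F-mtDNA/M-mtDNA structure characteristic of BTN2.

Every stage consumes and produces tibbles, so the chain composes with
ordinary dplyr verbs.

## The synthetic cohort generator

No raw study data ship with the package; `generate_cohort()` builds
cohorts with the structure the analysis assumes, so every stage is
testable end to end and the truth of every latent variable is known.

* **Loci.** EF1a (nuclear, 450 bp), COI (630 bp), the mitochondrial
  control region CR (622 bp) and 16S (500 bp). Alignment is taken as
  given: substitutions only, no indels.
* **Hosts.** Each specimen draws alleles as Poisson-mutated copies of a
  locus ancestor (expected pairwise difference `host_divergence`,
  default 6 substitutions — within-population mtDNA diversity of
  roughly 0.3–1.5% over these fragment lengths). Somatic mitochondrial
  loci are homoplasmic, matching healthy control animals.
* **DUI.** Sexes are assigned 1:1. Under doubly uniparental inheritance
  females are homoplasmic for F-mtDNA everywhere; males additionally
  carry M-mtDNA in the gonad, which is sampled with the mantle. The
  generator models the M genome at 16S only — the locus the
  mitochondrial sexing method reads — and keeps CR/COI F-type in
  somatic tissues; M-mtDNA is placed ~10% away from F-mtDNA.
* **The cancer clone.** One diploid nuclear genotype with two EF1a
  alleles exactly 21 substitutions apart (the observed heterozygosity of
  the BTN2 clone), and by default two mitochondrial haplotypes whose COI
  alleles differ by 6 substitutions and whose control regions are
  recombinant: an F backbone with an M-derived segment spliced into the
  configured 0-based half-open interval (default `[200, 400)`). Each
  infected specimen is homoplasmic for one haplotype.
* **Infection.** `floor(prevalence * n)` specimens are infected.
  Neoplastic cells are modeled as one cancer genome equivalent per cell,
  so the cancer allele weight in a tissue equals the cell fraction `p`
  (the relative DNA dosage of aneuploid cells in PCR templates is
  unknown; this is a flagged simplification). Hemolymph mixes at `p`
  drawn from `[0.12, 0.98]` — the span reported for diseased mussels —
  or from an explicit vector; the foot mixes at `foot_infiltration`,
  default 0 because no cancer mitochondrial signal was seen in foot
  tissue of diseased animals; the mantle is untouched.
* **Cloning noise.** `simulate_cloning()` draws colonies multinomially
  (16 per experiment by convention) and converts each to a PCR/cloning
  artifact with probability `artifact_rate` (default 0.05), replacing it
  with a 1–2-substitution mutant forced unique across the experiment so
  the singleton-exclusion rule is well-posed.
* **Flow events.** A truncated-normal mixture: diploid at the diploid
  mean, tetraploid (normal proliferating cells, 2% of the healthy
  compartment) at twice that, aneuploid at `relative_ploidy/2` times it,
  all with CV 0.05, 10,000 events per specimen.

What the generator does **not** emulate: S-phase bridges between the 2n
and 4n peaks, debris and doublets (event lists are assumed pre-gated),
indel variation and alignment error, a third peak of proliferating
neoplastic cells, and PCR amplification bias between templates. Passing
tests therefore demonstrate the logic of the inference chain under its
stated assumptions, not robustness to every artifact of real
cytometry or Sanger data.

## Flow-cytometry classification

`diagnose_ploidy()` bins intensities (256 equal-width bins over
`[0, max]`), smooths with a 5-bin moving average, and takes local maxima
as candidate peaks. Two guards make the candidate set robust at 10,000
events: a candidate must stand at least `min_fraction` (default 0.01) of
the tallest mode high, and at least half of its height must be its own
topographic prominence, which removes shot-noise ripples on the tails of
real peaks. Each peak is gated at ±3σ̂ with σ̂ from the full width at
half maximum (the walk is confined so it cannot pass through a taller
neighbour); its fraction is the share of all events inside the gate, and
peaks closer than 5% in mean are merged.

The diploid anchor is the **lowest-mean** peak holding at least
`diploid_anchor_fraction` of events (default 0.01): in heavy disease the
2n peak is a small minority (down to ~2% at a 98% neoplastic fraction),
so anchoring on the largest peak would be wrong, and the noise guards
above make a low floor safe. Relative ploidy is `2 × mean/mean(2n)`.

A peak is **tetraploid** (normal proliferating cells) only when it is
within ±0.3 n of 4.0 **and** holds under 5% of events; a large near-4n
population is treated as aneuploid disease evidence. This keeps genuine
aneuploid populations at the band edge (3.7 n occurs in real cases) from
being written off as tetraploid, at the documented cost that the
"ambiguous-proliferative" status is only reachable from hand-supplied
peak tables. The specimen is `dn_suggested` when any aneuploid peak
reaches `min_aneuploid_fraction` (default 0.05; the lowest reported real
case is 12%), `healthy` otherwise.

```{r flow}
set.seed(7)
ev <- simulate_flow_events(0.44, relative_ploidy = 4.5)
diagnose_ploidy(ev)
```

## Allele calling

`call_alleles()` groups identical colony sequences. A sequence seen in
fewer than `min_colonies` (default 2) colonies is a presumed
PCR/cloning artifact and excluded — **unless** the identical sequence
recurs in another cloning experiment of the study (another tissue or
individual), in which case it is retained with status `rare`. This
rescue rule is the only reading consistent with the packaged worked
example, where several count-1 sequences are retained precisely because
they dominate another tissue; it is switchable (`rescue = FALSE`).
Frequencies are computed over the retained ("major-sequence") colonies
only.

`merge_homopolymer_variants()` optionally folds allele pairs differing
by a single substitution inside or adjacent to a homopolymer run of ≥6
bases into the higher-count allele — polymerase slippage generates
exactly this signature (the worked example's D/7 pair differs by one SNP
at the 5' end of a 9-bp poly-A run). `resolve_piggyback()` reconstructs
dominant and minority templates from overlapping chromatogram peaks and
attributes the dominant hemolymph sequence to the cancer only when the
minority equals the animal's own foot allele; above 30% mixed sites the
assignment is refused as unreliable. Microsatellite profiles are
compared by height share (`compare_fragment_profiles()`), and the result
is always graded "inconclusive" — fragment sizes are shared across
unrelated individuals too.

## Chimerism and the two-evidence BTN call

`extra_alleles()` returns alleles strictly more frequent in hemolymph
than in foot (margin 0 by default, configurable to absorb cloning
noise; with 16 colonies per tissue, sampling noise alone makes controls
"chimeric" at some rate, which is why chimerism alone is never a cancer
call). `shared_cancer_alleles()` keeps extras recurring in at least
`min_support` diseased individuals — by default **all** of them, since
universality across cases is the evidence; with six or more cases the
default relaxes to a majority. In the pipeline the support pool is
restricted to DN-suggested individuals so a noisy control cannot raise
the bar. `call_btn()` is then positive iff the individual is chimeric
**and** its extras intersect the shared genotype at ≥1 locus; chimeric
individuals with only novel extras are annotated `possible-new-lineage`.

`mito_sex()` classifies a specimen male iff any mantle 16S allele is
M-type (within 0.05 p-distance of an M reference, or nearer the M than
the F panel when both are given).

## Lineage assignment, network, recombination

`assign_lineage()` is nearest-reference classification under the
uncorrected p-distance with pairwise deletion of gapped columns.
Distances, not likelihood trees, carry the package's conclusions: the
lineage identity of a cancer allele rests on identity/proximity to known
BTN alleles, which p-distances capture without a substitution-model
optimizer; ties are reported as `ambiguous` rather than broken, and
alleles beyond `novel_threshold` (default 0.03) from every reference are
flagged novel. The packaged reference panel is a synthetic stand-in
whose distances mirror the published ones; an accession manifest
placeholder documents where real identifiers would go.

`build_haplotype_network()` returns the union of **all** minimum
spanning trees (an edge is in some MST iff its endpoints are in
different components of the strictly-shorter-edge graph), so alternative
equally parsimonious connections survive, then expands k-step edges
through k−1 inferred median nodes. This is a minimum spanning network,
an approximation of TCS-style statistical parsimony; the 95% parsimony
connection limit is exposed as a plain `max_steps` cutoff rather than
computed from the parsimony probability formula. Tests verify the
construction against exhaustive spanning-tree enumeration on small
haplotype sets.

`scan_recombination()` slides a window (default 50 bp, step 10) along a
(query, parent A, parent B) alignment, assigns each window to the parent
the query matches better, and brackets breakpoints between consecutive
decisively assigned windows with different winners — tie windows in
between widen the bracket rather than displacing it. Within a bracket
the cut maximizing the 2×2 chi-square of (left/right × matches-A/B) over
informative sites is chosen, and the reported breakpoint is the midpoint
between the two flanking informative sites — any true breakpoint in
that gap is observationally equivalent, so the expected error is about
half the mean informative-site spacing (≈10 bp at 5% parental
divergence). Only breakpoint positions are compared between alleles;
with 0–1 informative sites in a bracket the midpoint (or the single
site) is reported rather than nothing.

```{r recomb}
set.seed(3)
f <- random_sequence(622)
m <- mutate_sequence(f, 31)
scan_recombination(make_recombinant_cr(f, m, c(200, 400)), f, m,
                   window = 50)
```

## Numerical and design choices

* Coordinates for intervals (recombination breakpoints, CR segments)
  are 0-based half-open; per-site tables (chromatograms) are 1-based,
  following R convention. Sequences are plain character strings; `-`
  and `N` are treated as missing under pairwise deletion.
* All stochastic stages draw from seeds derived from the configuration
  seed, so `run_pipeline()` output is byte-identical across reruns; the
  output dialect is tab-separated UTF-8 with `.` for missing, chosen
  for bit-exact diffing.
* Frequencies in the packaged worked-example table follow the
  major-colony denominator; two experiments in the printed source used
  the total clone count instead and are stored with their unambiguous
  integer counts, letting either convention be reproduced. Printed
  values at exact halves were rounded inconsistently in the source
  (10/16 → 0.63 but 2/16 → 0.12), so round-trip checks agree to half a
  unit in the last printed place.
* Problem sizes in the test-suite simulations — 200-replicate recovery
  runs, 500-replicate flow specificity, 100 seeded recombinants,
  1000-specimen DUI checks — were chosen as the smallest sizes at which
  the binomial noise of the property being tested is well below its
  acceptance margin.

## Known limitations

* Flow classification is 1-D and assumes pre-gated singlet events; no
  cell-cycle modeling, compensation, or multi-channel analysis.
* The chimerism margin formalizes "dominated by", which the underlying
  method never quantified; at 16 colonies the margin-0 rule is noisy on
  purpose and the BTN call carries the specificity burden.
* Allele dosage is equated with cell fraction; aneuploidy-weighted DNA
  dosage is out of scope.
* The recombination scanner is a single max-chi-square method, not a
  method ensemble, and reports no significance value — it is built for
  comparing breakpoint positions between alleles, not for hypothesis
  testing.
* No maximum-likelihood trees, bootstrap supports, or model-corrected
  distances; and at the 16-colony scale a 0.08-frequency allele drops
  out of a single cloning experiment roughly two times in three
  (measured, not asserted, by the test suite), which is why
  cross-referencing experiments matters.
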