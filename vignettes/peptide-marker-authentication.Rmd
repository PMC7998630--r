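---
title: "Peptide-marker food authentication: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peptide-marker food authentication: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepmarker)
```

## The problem

Processed foods are routinely adulterated or mislabelled: a meat product may
contain an undeclared second species, a "vegan" spread an undeclared
oilseed. Bottom-up proteomics authenticates ingredients through *marker
peptides* — tryptic peptides whose sequence occurs in exactly one species —
because peptides survive cooking far better than intact proteins or DNA in
heavily processed matrices. `pepmarker` implements the computational side of
that workflow: derive candidate peptides from taxon-tagged protein
databases, keep the species-unique ones, match observed LC-MS feature masses
to the resulting panel, and turn presence/absence across a spiked dilution
series into species calls and protein-level limits of detection (LOD).

The package ships a transcription of a published hemp-in-meatball dilution
experiment (five meatball variants at 0, 0.9, 2.6, 4.2, and 7.4 % w/w hemp
cake, plus pure hemp cake) as an executable fixture, so the whole pipeline
can be exercised end to end without any raw mass-spectrometry data, which
for that study were never deposited.

## Digestion model

Trypsin cleaves C-terminal to lysine and arginine. Two conventions matter:

* **Proline block (Keil rule).** Cleavage is suppressed when the next
  residue is proline. The block is on by default because that is what the
  common search engines do, and the published markers are consistent with
  it: the sunflower peptide `SQQCSETEIQRPVSQCQR` has an internal `R` before
  `P` and is a clean zero-missed-cleavage product only under the block
  (without it, it counts one missed cleavage, still within bounds). The
  flag is exposed in `cleavage_rule()`.
* **Missed cleavages.** Up to two internal uncut sites are enumerated,
  matching routine search settings. `cleave()` generates every peptide
  bounded by cleavage sites for 0–2 missed cleavages; protein termini
  always count as boundaries, with no special semi-tryptic handling of the
  initiator methionine.

Peptide length is filtered to 6–50 residues by default (the published food
markers span 8–27); both bounds are parameters.

Masses are neutral monoisotopic: residue masses (embedded to six decimal
places) plus one water, plus +57.021464 Da per cysteine (fixed
carbamidomethylation) and +15.994915 Da per oxidised methionine (variable,
at most two sites per peptide by default — `modification_scheme()` exposes
both maps). The test suite checks every embedded mass against an
independent element-composition oracle to 1e-4 Da, and checks additivity
(`mass(AB) = mass(A) + mass(B) − water`) to 1e-9 Da.

## Uniqueness screening

The operative criterion for a marker is *exact occurrence*: a candidate is
species-unique if its sequence occurs in no protein of any other species in
the database. This is deterministic and needs no external aligner; original
studies typically confirm uniqueness with BLAST, but the decision they act
on is presence/absence of the exact peptide elsewhere. Two switches modify
the notion of "occurs":

* `collapse_IL` treats I and L as the same letter. Off by default (markers
  are published as distinct sequences), but mass spectrometry cannot
  distinguish the two residues — a documented caveat, not a solved problem.
* `match_mode` judges uniqueness against foreign *substrings* (default;
  conservative — the peptide is disqualified even where trypsin would never
  release it) or against foreign *digest products* only.

Same-species paralog hits (the same peptide in edestin 1 and edestin 2, say)
are recorded but do not break species-level uniqueness, which is the
headline criterion; protein-level ambiguity stays visible in the screening
output. Uniqueness is a property of the bare sequence: modification states
inherit it. Instead of a full multiple sequence alignment, the package
reports, per foreign species, the same-length window with minimal Hamming
distance (`nearest_homolog_report()`), which is the part of an alignment
figure the screening decision actually uses; gapped alignment is out of
scope.

## Matching and detection

Features are assumed deisotoped and decharged (neutral monoisotopic masses),
as produced by standard feature-finding software. `match_features()` applies
a relative window, 10 ppm by default, and assigns each feature at most once:
to the panel state with minimal |ppm error|, ties broken by lower
theoretical mass, then lexicographic sequence. The tie-break is arbitrary
but deterministic, which matters more. Fragment-level evidence (MS/MS
spectra, product-ion tolerances) and decoy-based FDR control are outside the
package's scope — it models the mass-matching layer only, and says so
rather than pretending otherwise.

A peptide is *detected* in a sample when it matches in at least `consensus`
replicates; the default is 1 because the published presence/absence table
reports triplicate consensus without replicate-level detail, and a majority
rule (2 of 3) is one argument away. Cell intensity is the per-replicate
summed matched intensity averaged over the sample's replicate count.
Protein rollups count detected panel peptides and, when parent sequences
are available, compute sequence coverage as the interval *union* of
detected peptide spans (overlaps are not double-counted). Retention time is
carried through the tables but unused by default; no published RT values
exist to calibrate a window against.

## Species calls, stable markers, LOD, trends

A species is called in a sample when at least `min_proteins` of its panel
proteins each show at least `min_peptides` detected peptides (defaults 1
and 1: one species-unique peptide is already species evidence; the hemp
albumin, with only two panel peptides, would be lost under a blanket
two-peptide rule). Heat-stable markers are the per-sample intersection of
detections across processing variants.

The LOD of a protein is the smallest *tested* spike concentration at which
the protein is detected — reported on the grid only, with no interpolation,
because that is how dilution-series LODs are stated. Detection that
disappears again at a higher concentration is flagged non-monotone rather
than silently accepted. On the study fixture this yields 0.9 % w/w for the
three edestin subunits and albumin and 4.2 % w/w for the 7S vicilin-like
protein. Whether "edestin LOD" should be judged per subunit or jointly is
not specified in the source study; the package computes per-protein values,
and a joint any-subunit variant is a one-line regrouping of the matrix (the
test suite exercises it).

`intensity_trend()` is ordinary least squares of total intensity on
concentration, with R² the squared Pearson correlation (defined as 0 for a
constant response). A zero point (0 % spike, zero intensity) is included by
default, mirroring calibration through a blank; raw-intensity fitting is
the default and a log-intensity fit is behind a flag, since the source
figure does not specify a transform. The study reports R² = 0.95 for its
edestin-1 trend line, but that value cannot be reconstructed from the
printed per-sample intensities by least squares with or without the zero
point (the fit inputs are under-specified); the package therefore asserts
oracle-equivalence of its own fit and the positive slope, not the printed
constant.

## The synthetic-data generator

`simulate_features()` draws feature tables with the statistical structure
the analysis assumes:

* latent intensity `scale × abundance(protein) × efficiency(peptide) ×
  concentration × exp(ε)`, `ε ~ N(0, σ²_log)` — linear in concentration
  (supporting the linear trend) with multiplicative log-normal noise;
* emission probability `plogis(steepness × (log I − log threshold))`, with
  `steepness = ∞` a hard cutoff — intensity-threshold dropout, which is
  what makes low-abundance proteins disappear at low spike levels;
* emitted masses perturbed by Gaussian ppm error; uniform-mass decoy
  features at a Poisson count per sample exercise false matching inside the
  ppm window;
* samples at zero concentration emit no marker features at all.

Everything is driven by one integer seed and is exactly reproducible.
`paper_pattern_dataset()` presets abundances (edestin 1/2/3 ≈ 5/5/4,
albumin 0.5, 7S vicilin-like 0.03, scale 1e7, threshold 1e6) so that the
noiseless hard-threshold detection pattern over the 0.9–7.4 % grid
reproduces the published protein-level pattern — storage proteins from
0.9 %, the 7S protein from 4.2 % — and edestin-1 intensities land on the
published order of magnitude (≈4e7 at 0.9 %).

What the generator does *not* emulate: chimeric and co-eluting features,
charge-state and isotope assignment errors, retention-time structure,
matrix-dependent ionisation suppression, and shared (non-unique) peptides
from homologous proteins. Passing tests on synthetic data therefore
demonstrate the correctness of the pipeline's logic under its stated model,
not performance on real chromatograms.

Parent "proteins" for the hemp and meat panels are synthetic
concatenations of the printed marker peptides (every marker ends in K/R and
none starts with proline, so each concatenation digests back into exactly
its markers). They are labelled synthetic wherever they appear and stand in
only for operations that need *a* parent sequence — digestion round-trips,
coverage spans, abundance bookkeeping — not for the real NCBI records,
which the package deliberately does not ship.

## Numerical and testing choices

* Coordinates are 0-based half-open internally; masses are validated on
  panel I/O to 1e-4 Da against recomputation.
* All tabular formats are TSV with fixed headers, decimal points, no
  thousands separators, so round-trips are exact in tests.
* Digestion is verified against a brute-force substring-enumeration oracle
  (200 random sequences up to length 40, missed cleavages 0–2, proline
  block on and off); least squares against the closed-form normal
  equations; masses against element compositions.
* The stochastic generator contracts are tested at fixed seeds: byte-level
  seed determinism; detection-frequency monotonicity in concentration at
  10 000 replicate draws with well-separated emission probabilities;
  noiseless LOD parameter recovery over 20 randomized abundance/threshold
  draws with the threshold placed at the log-scale midpoint between grid
  latents.
* For the noisy-LOD guarantee ("the estimate does not undercut the
  generator truth"), the test uses σ_log = 0.2, one peptide per protein,
  majority (2-of-3) consensus, and thresholds at the log-midpoint of the
  *wide* grid gaps (0.9→2.6, 4.2→7.4). This configuration is the honest
  form of the claim: with single-replicate consensus, or a threshold at the
  midpoint of the narrow 2.6→4.2 gap (only 0.24 natural-log units of
  margin, 1.2σ), log-normal noise pops a sub-threshold peptide over the
  line in a third of runs, and no implementation could satisfy the bound.
  The one-sided failure rate is checked over 100 simulated runs against a
  5 % ceiling.

## Known limitations

I/L ambiguity is carried as a flag, not resolved. Uniqueness is judged
against whatever database is supplied — an incomplete proteome (the rule,
not the exception, for oilseeds) inflates apparent uniqueness, which is an
argument for re-screening panels as databases grow, not a property the
package can fix. The LOD is a grid statistic: it cannot be more precise
than the dilution design. And the fixture detection matrix carries
zero intensities (the source prints protein-level intensities only), so
intensity-dependent operations on the fixture use the per-protein table
instead.
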