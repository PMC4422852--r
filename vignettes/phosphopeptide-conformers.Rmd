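---
title: "Linking phosphopeptide ECD fragmentation to gas-phase conformation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking phosphopeptide ECD fragmentation to gas-phase conformation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecdims)
```

## The model

Electron capture dissociation of a doubly protonated peptide ion cleaves
N–Cα bonds along the backbone, giving N-terminal *c*-type and C-terminal
*z*-type fragments. Because electron capture is largely nonspecific along
the chain, an unmodified peptide shows fragments from most cleavage
sites. The working model of this package is:

> A noncovalent contact between the phosphate group and a protonated
> basic site that survives electron capture prevents the two backbone
> halves from separating, so a bridge between residues $a$ and $b$
> suppresses every cleavage site $s$ with $a \le s < b$.

The nature of that contact depends on the protonation pattern of the
ion. With three basic sites protonated and the phosphate deprotonated
(net +2), a sub-4 Å phosphate–ammonium/guanidinium contact is a **salt
bridge**; with two sites protonated and a neutral phosphate it is an
**ionic hydrogen bond**. The package treats each pattern as a competing
hypothesis, converts the sub-threshold contacts of model conformers into
predicted suppressed-site sets, and scores each hypothesis by the
fraction of cleavage sites whose predicted observability (suppressed vs
observable) matches the measured coverage (zero vs nonzero assigned
fragments). The score is a formalisation of a comparison that is usually
made narratively; it is deliberately simple (unweighted sites, coverage
dichotomised at zero) so that its behaviour is transparent.

Assumptions worth keeping in mind: the bridge is assumed to survive the
electron-capture event; fragment intensities are not modelled, only
presence/absence; and conformers are treated as equally weighted when
combined (`union` or `majority` rules) because relative conformer
contributions to the ECD signal are not measurable here.

## Fragment masses and peak assignment

Ion conventions follow standard ECD nomenclature, built from
monoisotopic residue masses: $b_i = \sum_{1..i}$ residues,
$c = b + \mathrm{NH_3}$, $c^\bullet = c - \mathrm{H}$,
$y_j = \sum + \mathrm{H_2O}$, $z^\bullet = y - 16.018724$,
$z' = z^\bullet + \mathrm{H}$, and
$m/z = (\mathrm{neutral} - \mathrm{loss} + z \cdot 1.0072765)/z$.
Phosphorylation adds 79.966331 Da at its site and H$_3$PO$_4$
(97.976896 Da) is the built-in neutral loss; loss combinations exceeding
the fragment mass are dropped rather than emitted with nonsensical
negative masses. A useful internal identity — the neutral masses of
$c_i$ and $z^\bullet_{N-i}$ always sum to $M + 1.007825$ Da — is used as
a property test over every site.

Peak assignment is greedy one-peak-one-ion: all (peak, ion) pairs within
the ppm tolerance are ranked by $|\mathrm{ppm}|$, exact ties broken by
ion-type precedence $c > c^\bullet > z^\bullet > z' > y > b > a$, and
accepted so that no peak or ion is used twice. The default tolerance is
5 ppm, appropriate for FT-ICR data; it is an argument everywhere.
Relative abundance divides each assigned intensity by the total assigned
intensity *including the charge-reduced species*, matching how such
tables are reported.

Cleavage sites are 1-based, site $s$ lying between residues $s$ and
$s+1$; a $z_j$ ion covers site $N-j$. "No fragments between residues
$a$ and $b$" therefore means zero counts at sites $a..b-1$, which is
exactly the set a bridge between $a$ and $b$ would suppress.

## The bundled reference tables

`reference_abundances()` carries the published relative fragment-ion
abundances of the six-peptide APLSFRGSLPKSYVK series and
`reference_ccs()` the measured CCS values with their random-coil
trendline deviations. The abundance table as typeset does not mark empty
cells explicitly in all renderings, so the transcription was pinned down
using the accompanying fragment summaries: the Arg-6 phosphopeptides show
no fragments between the phosphoserine and the flanking basic residues
(sites 4–10 for pS4, 6–11 for pS12), the Leu-6 analogues fragment through
those regions, the z11 ion of L6pS4 is about three-fold that of L6pS12,
the charge-reduced species is always larger for a phosphopeptide than for
its unmodified analogue, and the phosphate-loss precursor of R6pS12 is
about half that of the other phosphopeptides. All of these constraints
are satisfied simultaneously by the shipped table; the handful of minor
single-cell rows not pinned by any constraint (y9, y10, parts of
z13/c6–c10) were assigned to the peptides with full-sequence coverage,
where they affect no gap statistic.

The CCS comparison "to the unmodified peptide" is computed as the
*difference of trendline deviations* (modified minus unmodified), not as
a direct percent difference of raw CCS. The direct form does not
reproduce the published column, whereas the deviation difference
reproduces all four values (−7.6, −6.4, −3.8, +1.4 %); this definition is
therefore adopted.

## TWIMS calibration

Calibration follows the established corrected power-law protocol:
drift times are corrected for mass-dependent post-mobility flight
($t'_d = t_d - c\sqrt{m/z}/1000$, with $c$ the instrument's EDC delay
coefficient, a required input since it is never published), literature
CCS values are reduced by charge and reduced mass
($\Omega' = \Omega / (z\sqrt{1/m + 1/m_g})$, nitrogen gas mass
28.00615 Da by default), and $\ln \Omega'$ is regressed on $\ln t'_d$.
At least three calibrants are required; the fit is exact on noiseless
synthetic calibrants and, with 1 % log-normal drift-time noise and
$n = 20$, recovers the exponent well within ±0.05 (checked over several
fixed seeds). The random-coil trendline is likewise a log-log regression
of CCS on mass; the published deviations are used directly as inputs
because the specific calibrant subset behind the published trendline is
not available.

Arrival-time profiles are reduced to conformer peaks by local-maximum
detection with two knobs: a height floor (default 10 % of the global
maximum) and a minimum peak spacing (default 5 CCS units; of two closer
maxima the taller wins). Peaks closer than the spacing merge into one
report — the documented behaviour, not an error.

## Projection-approximation CCS

The package estimates CCS as the orientation-averaged projected area of
the union of atomic collision disks (atom van der Waals radius + probe
radius; H 1.20, C 1.70, N 1.55, O 1.52, P/S 1.80 Å, probe 1.0 Å for
helium or 1.8 Å for nitrogen). Orientations are seeded uniform random
rotations (quaternion sampling); each projected area is estimated by
uniform dart throwing over the projected bounding box. Defaults are 300
orientations × 512 darts, which puts the Monte-Carlo standard error near
0.1–0.5 % for peptide-sized structures; the quoted `mc_stderr` is the
standard error over orientations and shrinks as
$1/\sqrt{n_\mathrm{orientations}}$.

The projection approximation is a deliberate, documented simplification
relative to trajectory-method CCS (which requires Lennard-Jones
parameters and long integrations). It is used here for *relative*
ensemble filtering, where a systematic offset cancels; an optional
multiplicative `scale` argument lets users emulate a known
projection-to-trajectory offset. Absolute agreement with published
experimental CCS values is not claimed — those values enter the pipeline
as inputs, not predictions. Accuracy is verified against an analytic
single-disk area and a deterministic two-disk quadrature oracle (< 1 %).

## Ensemble filtering, clustering, contacts

Filtering retains conformers within ±3 % of the target CCS (inclusive
bounds — a structure at exactly 1.03× the target is kept). Clustering
superposes every structure onto the first retained structure (Kabsch
least squares via `bio3d::fit.xyz`), flattens the coordinates and runs
seeded k-means (Lloyd, up to 500 iterations, 5 starts). Populations are
percentages *of the filtered ensemble*; each cluster's representative is
its member nearest the cluster mean. Because superposition removes rigid
motion, clusters separate by *shape* — two conformers differing only by
a rotation belong together by construction. `k` is a user choice: the
cluster count is not something the data fix here, and only the most
populated clusters are usually carried forward.

Charged groups resolve to heavy atoms only: ammonium to NZ, guanidinium
to NE/NH1/NH2, the N-terminal amine to the backbone N of residue 1, and
the phosphate to its three terminal oxygens (O1P/O2P/O3P) regardless of
protonation state. Hydrogens are excluded deliberately — their placement
is a modelling artefact, and using heavy atoms makes the distance
criterion robust to how structures were protonated. Whether published
distance analyses measured to the guanidinium carbon or nitrogens is not
knowable; the heavy-nitrogen choice is documented rather than inferred.
The 4 Å criterion is a strict inequality (3.99 Å is a contact, 4.00 Å is
not) and the same cutoff is used for salt bridges and (ionic) hydrogen
bonds, keeping the published consistency choice. A sub-threshold contact
with a *non*-protonated lysine is labelled a plain `hydrogen_bond` and is
excluded by default from the suppressing classes, since a neutral contact
is unlikely to survive electron capture.

## The synthetic generators

The generators exist so every pipeline stage can be tested against
planted ground truth:

* `gen_conformers()` builds coarse-grained pseudo-peptides: a jittered
  Cα trace plus exactly the charged pseudo-atoms the distance analysis
  reads. Contact specs are satisfied *exactly* (root-solving the anchor
  position so the minimum heavy-atom distance equals the target), all
  unspecified phosphate–basic distances are ≥ 6 Å, and a per-structure
  size factor (applied to the backbone only, so planted distances are
  untouched) produces a CCS spread when needed. Present contacts must be
  planted below 4 Å and absent ones at ≥ 6 Å, keeping a clear margin
  around the threshold.
* `gen_calibrants()` inverts the calibration power law from sampled
  masses/charges and a smooth mass–CCS trend, then adds log-normal
  drift-time noise.
* `gen_peaklist()` realises an abundance table at exact theoretical m/z,
  assigns any remainder below 100 % to the charge-reduced species, and
  can add decoy peaks kept ≥ 5 ppm from every theoretical ion.
* `gen_atd()` sums Gaussian conformer peaks on a CCS grid.

Everything is deterministic per seed, and the generators restore the
caller's RNG state.

What the generators do **not** emulate matters for interpreting green
tests: there is no force field, no conformational energetics, no isotope
structure, no peak-shape or centroiding noise, and the coarse-grained
side chains are single pseudo-atoms. Passing tests therefore demonstrate
that the *analysis* (assignment, calibration arithmetic, filtering,
clustering, distance classification, scoring) is correct on inputs whose
truth is known — not that force-field conformer ensembles of real
phosphopeptides would be reproduced. Published cluster populations and
absolute experimental CCS values depend on molecular-dynamics
trajectories that are out of scope here.

## Numerical choices and problem sizes

Tolerances: peptide masses are checked to 1e-6 Da; noiseless round trips
(calibration, abundance recovery) to 1e-9 relative; superposition of
rigidly moved copies to 1e-6 Å. k-means ties and init are controlled by
an explicit seed; equal cluster populations are ordered by cluster id.
Degenerate inputs are defined, not accidental: an empty filtered set
warns rather than errors, `k = 1` clusters trivially, `n = k` gives
singletons, unmatched peaks pass through unassigned, and an all-zero
intensity set is an error.

The test suite and the acceptance script run at deliberately desk-scale
sizes — ensembles of 3–12 structures, 20 calibrants, 300×512 to 400×2048
Monte-Carlo samples, 1000-point filter clouds — chosen so the full chain
(including the end-to-end hypothesis ranking) verifies in seconds while
keeping every statistical margin comfortable.
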