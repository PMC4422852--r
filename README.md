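# ecdims

Rationalizing the electron capture dissociation (ECD) behaviour of
phosphopeptides from their gas-phase conformation.

## The problem

ECD of a doubly protonated peptide normally cleaves the backbone N–Cα
bonds throughout the sequence, producing *c* and *z* fragments that retain
labile modifications such as phosphorylation. For some phosphopeptides,
however, whole stretches of the sequence yield **no** fragments: a
noncovalent contact between the phosphate group and a protonated basic
side chain (Arg, Lys or the N-terminus) can hold the two halves of a
cleaved backbone together, so no separated fragment is ever detected from
any cleavage site lying *between* the bridged residues. Whether that
contact is a **salt bridge** (deprotonated phosphate against a protonated
side chain) or an **ionic hydrogen bond** (neutral phosphate) cannot be
read off the spectrum alone — but it can be inferred by combining:

1. the observed ECD cleavage-site coverage and its gaps,
2. traveling wave ion mobility (TWIMS) collision cross sections (CCS),
3. model conformer ensembles filtered to the experimental CCS and
   analysed for charged-group distances under competing protonation
   hypotheses.

`ecdims` implements that whole chain for peptides such as the
APLSFRGSLPKSYVK series (Arg-6 or Leu-6; phosphoserine at position 4
or 12).

## The core quantities

* **Fragment annotation.** Theoretical *c*/*c•*/*z•*/*z′* (plus *a*, *b*,
  *y* and precursor-derived) ions with standard monoisotopic mass
  conventions (`c = b + NH3`, `z• = y − 16.018724`, `z′ = z• + H`);
  m/z `= (neutral − loss + z·1.0072765)/z`. Relative abundance of a
  fragment is `100 · I / Σ I` over all assigned species including the
  charge-reduced `[M+2H]+•`.
* **TWIMS calibration.** Corrected drift time
  `t′d = td − c·√(m/z)/1000`, reduced CCS
  `Ω′ = Ω / (z·√(1/m + 1/m_gas))`, power law `Ω′ = A·(t′d)^X` fitted in
  log-log space; deviations from a random-coil `ln(CCS) ~ ln(mass)`
  trendline (`ΔCCS_rc`, %), and the modified-minus-unmodified deviation
  difference (`ΔCCS_unmod`).
* **Projection-approximation CCS.** Orientation-averaged projected area
  of the union of atomic collision disks (vdW radius + probe radius),
  Monte Carlo over seeded uniform rotations with dart-throwing per
  orientation.
* **Ensemble analysis.** ±3 % CCS-window filtering, Kabsch superposition,
  seeded k-means clustering with population percentages and
  centroid-nearest representatives.
* **Contact classification.** Minimum heavy-atom distance between the
  phosphate oxygens and each basic site; a contact `< 4 Å` is a salt
  bridge (phosphate −1, partner +1), an ionic hydrogen bond
  (phosphate 0, partner +1) or a plain hydrogen bond (partner neutral).
* **Hypothesis scoring.** Each sub-4 Å bridge between residues *a* and
  *b* suppresses cleavage sites `a ≤ s < b`; a hypothesis scores the
  fraction of sites whose predicted observability matches the measured
  coverage.

## Worked example

```r
library(ecdims)

# published ECD abundances of APLpSFRGSLPKSYVK realised as a peak list,
# assigned, and mapped onto cleavage sites
rs <- reference_spectrum("R6pS4")
rs$coverage
#> Cleavage-site coverage (14 sites):
#>   0 1 4 0 0 0 0 0 0 0 2 2 1 1
#>   gap: sites 1..1 uncovered
#>   gap: sites 4..10 uncovered
gap_between(rs$coverage, 4, 11)$n_fragments
#> [1] 0        # nothing separates pS4 from K11

# synthetic conformers planted with a 3.5 A pS4-K11 contact, classified
# under the deprotonated-phosphate (salt-bridge) hypothesis
ens <- gen_conformers("APLpSFRGSLPKSYVK", n = 3,
                      contacts = contact_spec(4, 11, 3.5), seed = 1)
pat <- protonation_pattern("R6+,K11+,K15+,POx-",
  data.frame(index = c(6L, 11L, 15L),
             kind = c("arg_guanidinium", "lys_ammonium", "lys_ammonium")),
  phosphate_state = -1L, phosphosite = 4L)
contact_grid(interaction_table(ens, pat))
#>           R6  K11 K15
#> conf_0001 "N" "Y" "N"
#> conf_0002 "N" "Y" "N"
#> conf_0003 "N" "Y" "N"

# does the hypothesis explain the observed gap?
score_agreement(predict_suppression(interaction_table(ens, pat), 15),
                rs$coverage)
#> Hypothesis 'R6+,K11+,K15+,POx-': 13/14 sites agree (score 0.929)
```

The pS4–K11 salt-bridge hypothesis predicts suppression of exactly sites
4–10 and agrees at 13 of 14 sites (site 1 yields no fragments for reasons
unrelated to bridging), while a no-interaction, neutral-phosphate
hypothesis agrees at only 6 of 14 — reproducing the conclusion that a
salt-bridge structure best describes this phosphopeptide's ECD.

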