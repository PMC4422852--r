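# Bundled reference data for the APLSFRGSLPKSYVK phosphopeptide series
# (R6/L6 denote Arg or Leu at position 6; pS4/pS12 the phosphoserine
# position).

#' Sequences of the reference phosphopeptide series
#'
#' Six synthetic peptides: APLSFRGSLPKSYVK and its Leu-6 analogue, each
#' unmodified or phosphorylated at Ser-4 or Ser-12.
#'
#' @return Named character vector of modified-sequence strings keyed by the
#'   short names \code{R6pS4}, \code{R6pS12}, \code{R6unmod}, \code{L6pS4},
#'   \code{L6pS12}, \code{L6unmod}.
#' @export
reference_peptides <- function() {
  c(R6pS4   = "APLpSFRGSLPKSYVK",
    R6pS12  = "APLSFRGSLPKpSYVK",
    R6unmod = "APLSFRGSLPKSYVK",
    L6pS4   = "APLpSFLGSLPKSYVK",
    L6pS12  = "APLSFLGSLPKpSYVK",
    L6unmod = "APLSFLGSLPKSYVK")
}

#' Published ECD relative fragment-ion abundances for the reference series
#'
#' Relative abundances (percent of total fragment-ion abundance, including
#' the charge-reduced species; mean of three replicate spectra) observed
#' after ECD of the doubly protonated reference peptides.  Cell-to-peptide
#' assignments were transcribed from the typeset table guided by the
#' reported fragment summaries: the Arg-6 phosphopeptides show no
#' fragments between the phosphoserine and the flanking basic residues.
#'
#' @return Data frame with columns \code{peptide}, \code{ion_type},
#'   \code{frag_index} (fragment residue count, NA for precursor species),
#'   \code{neutral_loss} (Da) and \code{abundance} (percent).
#' @export
reference_abundances <- function() {
  path <- system.file("extdata", "ecd_fragment_abundances.csv",
                      package = "ecdims", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$frag_index <- suppressWarnings(as.integer(df$frag_index))
  df
}

#' Measured TWIMS collision cross sections of the reference series
#'
#' CCS of the least compact conformer peak of each doubly protonated
#' peptide, with its percentage deviation from the random-coil trendline
#' (regression of CCS on molecular weight over unstructured calibrant
#' peptides).
#'
#' @return Data frame with columns \code{peptide}, \code{sequence},
#'   \code{ccs_A2}, \code{delta_rc_pct} (deviation from the random-coil
#'   trendline, percent) and \code{unmod} (short name of the unmodified
#'   counterpart, NA for the unmodified peptides themselves).
#' @export
reference_ccs <- function() {
  data.frame(
    peptide = c("L6pS4", "L6pS12", "L6unmod", "R6pS4", "R6pS12", "R6unmod"),
    sequence = unname(reference_peptides()[
      c("L6pS4", "L6pS12", "L6unmod", "R6pS4", "R6pS12", "R6unmod")]),
    ccs_A2 = c(346, 372, 357, 351, 364, 360),
    delta_rc_pct = c(3.0, 10.8, 9.4, 2.7, 6.5, 10.3),
    unmod = c("L6unmod", "L6unmod", NA, "R6unmod", "R6unmod", NA),
    stringsAsFactors = FALSE
  )
}

#' CCS deviation of each phosphopeptide relative to its unmodified analogue
#'
#' Applies \code{\link{delta_to_unmod}} to the trendline deviations of
#' \code{\link{reference_ccs}}: the modified peptide's trendline deviation
#' minus its unmodified counterpart's.  Negative values indicate compaction
#' upon phosphorylation.
#'
#' @return Data frame with columns \code{peptide} and
#'   \code{delta_unmod_pct}.
#' @export
reference_delta_unmod <- function() {
  tab <- reference_ccs()
  mod <- tab[!is.na(tab$unmod), , drop = FALSE]
  ref <- tab$delta_rc_pct[match(mod$unmod, tab$peptide)]
  data.frame(peptide = mod$peptide,
             delta_unmod_pct = delta_to_unmod(mod$delta_rc_pct, ref),
             stringsAsFactors = FALSE)
}

#' Peak list, assignments and coverage for a reference peptide
#'
#' Convenience wrapper: realises the published abundance column of one
#' reference peptide as a noiseless synthetic peak list, assigns it against
#' the theoretical c/z/y/precursor ions, and computes the coverage map.
#'
#' @param name One of the names of \code{\link{reference_peptides}}.
#' @param tol_ppm Assignment tolerance (ppm).
#' @return List with \code{peptide} (\code{annotated_peptide}),
#'   \code{peaks}, \code{assignments}, \code{coverage}.
#' @export
reference_spectrum <- function(name, tol_ppm = 5) {
  seqs <- reference_peptides()
  if (!name %in% names(seqs))
    stop("unknown reference peptide '", name, "'")
  pep <- build_peptide(seqs[[name]])
  ab <- reference_abundances()
  ab <- ab[ab$peptide == name, , drop = FALSE]
  peaks <- gen_peaklist(pep, ab)
  ions <- theoretical_ions(pep,
                           types = c("c", "c_radical", "y", "z_radical",
                                     "z_prime", "M_plus_H",
                                     "charge_reduced"),
                           charges = 1L, losses = c(0, .mass_h3po4))
  asg <- relative_abundance(assign_peaks(peaks, ions, tol_ppm = tol_ppm))
  list(peptide = pep, peaks = peaks, assignments = asg,
       coverage = coverage_map(asg, pep))
}
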