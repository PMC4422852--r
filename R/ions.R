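# Theoretical ECD/CID fragment ions.
#
# Neutral fragment mass conventions (standard ECD nomenclature):
#   b  = sum of residue masses 1..site
#   a  = b - CO
#   c  = b + NH3                       (even-electron c ion)
#   c* = c - H                        (c radical)
#   y  = sum of residue masses (site+1)..N + H2O
#   z* = y - NH (16.018724)           (z radical, z-dot)
#   z' = z* + H                       (even-electron z+1 species)
# m/z = (neutral - neutral_loss + charge * 1.0072765) / charge.

.ion_alphabet <- c("a", "b", "c", "c_radical", "y", "z_radical", "z_prime",
                   "M_plus_H", "charge_reduced")
.nterm_types <- c("a", "b", "c", "c_radical")
.cterm_types <- c("y", "z_radical", "z_prime")

# Assignment tie-break precedence (most to least favoured).
.default_precedence <- c("c", "c_radical", "z_radical", "z_prime", "y", "b",
                         "a", "M_plus_H", "charge_reduced")

ion_label <- function(ion_type, frag_index, neutral_loss = 0) {
  base <- switch(ion_type,
    a = paste0("a", frag_index), b = paste0("b", frag_index),
    c = paste0("c", frag_index), c_radical = paste0("c", frag_index, "*"),
    y = paste0("y", frag_index),
    z_radical = paste0("z", frag_index, "*"),
    z_prime = paste0("z", frag_index, "'"),
    M_plus_H = "[M+H]+", charge_reduced = "[M+2H]+*"
  )
  if (neutral_loss > 0) base <- paste0(base, "-H3PO4")
  base
}

#' Enumerate theoretical fragment ions of a peptide
#'
#' Generates every requested combination of ion type, cleavage site, charge
#' and neutral loss for an annotated peptide.  Cleavage sites are 1-based:
#' site \eqn{s} lies between residues \eqn{s} and \eqn{s+1}.  N-terminal
#' ions (a/b/c types) at site \eqn{s} comprise residues \eqn{1..s};
#' C-terminal ions (y/z types) comprise residues \eqn{(s+1)..N}.  The
#' precursor-derived species \code{M_plus_H} and \code{charge_reduced}
#' ([M+2H]+ after electron capture without backbone separation) carry no
#' site.
#'
#' @param pep An \code{annotated_peptide} from \code{\link{build_peptide}}.
#' @param types Character vector of ion types, a subset of
#'   \code{c("a","b","c","c_radical","y","z_radical","z_prime","M_plus_H",
#'   "charge_reduced")}.
#' @param charges Integer vector of positive fragment charges (precursor
#'   species are always emitted at charge 1).
#' @param losses Numeric vector of neutral losses in Da (0 = none;
#'   H3PO4 = 97.976896).
#' @param sites Optional integer vector restricting cleavage sites
#'   (default all of \code{1..(n-1)}).
#' @return Data frame with columns \code{ion_type}, \code{site} (NA for
#'   precursor species), \code{frag_index} (fragment residue count as used
#'   in ion names, e.g. 11 for z11), \code{charge}, \code{neutral_loss},
#'   \code{neutral_mass}, \code{mz}, \code{label}.
#' @examples
#' pep <- build_peptide("APLSFR")
#' ions <- theoretical_ions(pep, types = c("c", "z_radical"))
#' head(ions)
#' @export
theoretical_ions <- function(pep,
                             types = c("c", "c_radical", "z_radical",
                                       "z_prime"),
                             charges = 1L,
                             losses = 0,
                             sites = NULL) {
  stopifnot(inherits(pep, "annotated_peptide"))
  if (!all(types %in% .ion_alphabet))
    stop("unknown ion type(s): ",
         paste(setdiff(types, .ion_alphabet), collapse = ", "))
  stopifnot(all(charges >= 1))
  n <- pep$n
  if (is.null(sites)) sites <- seq_len(n - 1L)
  if (length(sites) && (min(sites) < 1L || max(sites) > n - 1L))
    stop("cleavage sites must lie in 1..", n - 1L)

  res_m <- residue_masses_with_mods(pep)
  prefix <- cumsum(res_m) + nterm_mod_mass(pep)  # b-ion neutrals by site
  suffix <- rev(cumsum(rev(res_m))) + .mass_water # y-ion neutrals: site s -> suffix[s+1]

  rows <- list()
  frag_types <- intersect(types, c(.nterm_types, .cterm_types))
  for (tp in frag_types) {
    for (s in sites) {
      neutral <- switch(tp,
        b = prefix[s],
        a = prefix[s] - .mass_co,
        c = prefix[s] + .mass_nh3,
        c_radical = prefix[s] + .mass_nh3 - .mass_h,
        y = suffix[s + 1L],
        z_radical = suffix[s + 1L] - .mass_nh,
        z_prime = suffix[s + 1L] - .mass_nh + .mass_h
      )
      idx <- if (tp %in% .nterm_types) s else n - s
      for (z in charges) for (loss in losses) {
        rows[[length(rows) + 1L]] <- data.frame(
          ion_type = tp, site = s, frag_index = idx, charge = as.integer(z),
          neutral_loss = loss, neutral_mass = neutral,
          mz = (neutral - loss + z * .mass_proton) / z,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  for (tp in intersect(types, c("M_plus_H", "charge_reduced"))) {
    neutral <- if (tp == "M_plus_H") pep$mass else pep$mass + .mass_proton
    for (loss in losses) {
      rows[[length(rows) + 1L]] <- data.frame(
        ion_type = tp, site = NA_integer_, frag_index = NA_integer_,
        charge = 1L, neutral_loss = loss, neutral_mass = neutral,
        mz = neutral - loss + .mass_proton,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # a neutral loss exceeding the fragment mass is physically impossible;
  # those combinations are dropped rather than emitted with mz <= 0
  out <- out[out$neutral_mass - out$neutral_loss > 0, , drop = FALSE]
  rownames(out) <- NULL
  out$label <- mapply(ion_label, out$ion_type,
                      ifelse(is.na(out$frag_index), 0L, out$frag_index),
                      out$neutral_loss)
  out
}
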