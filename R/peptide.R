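# Monoisotopic masses (Da). Residue masses are the standard amino acid
# residue (dehydrated) masses; I and L are isobaric.
.residue_mass <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

.mass_water   <- 18.010565
.mass_proton  <- 1.0072765   # mass of H+ (charge carrier)
.mass_h       <- 1.007825    # mass of hydrogen atom
.mass_nh3     <- 17.026549
.mass_co      <- 27.994915
.mass_phospho <- 79.966331   # HPO3
.mass_acetyl  <- 42.010565   # C2H2O
.mass_h3po4   <- 97.976896   # characteristic phosphoserine neutral loss
.mass_nh      <- 16.018724   # z-radical offset from y

#' Build an annotated peptide from a modified sequence string
#'
#' Parses a one-letter-code peptide sequence in which phosphosites are
#' written with a lowercase \code{p} prefix (\code{"pS"}, \code{"pT"},
#' \code{"pY"}, e.g. \code{"APLpSFRGSLPKSYVK"}) and an optional
#' \code{"ac-"} prefix marks N-terminal acetylation.  The returned object
#' carries the residue vector, the modification map and the monoisotopic
#' neutral mass.
#'
#' @param sequence Character scalar, e.g. \code{"APLpSFRGSLPKSYVK"} or
#'   \code{"ac-APLSFRGSLPKSYVK"}.
#' @return An object of class \code{annotated_peptide} with elements
#'   \code{residues} (character vector of one-letter codes), \code{mods}
#'   (data frame with columns \code{index}, \code{name}, \code{delta}; the
#'   N-terminal acetyl is recorded at index 0), \code{n} (residue count) and
#'   \code{mass} (monoisotopic neutral mass, Da).
#' @examples
#' pep <- build_peptide("APLpSFRGSLPKSYVK")
#' pep$n        # 15
#' pep$mods     # phospho at residue 4
#' @export
build_peptide <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  seq <- sequence
  acetyl <- FALSE
  if (grepl("^ac-", seq)) {
    acetyl <- TRUE
    seq <- sub("^ac-", "", seq)
  }
  chars <- strsplit(seq, "")[[1]]
  residues <- character(0)
  mod_idx <- integer(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "p") {
      if (i == length(chars)) stop("dangling phospho marker 'p' at end of sequence")
      res <- chars[i + 1L]
      if (!res %in% c("S", "T", "Y"))
        stop("phospho marker on residue '", res, "': only S, T or Y can be phosphorylated")
      residues <- c(residues, res)
      mod_idx <- c(mod_idx, length(residues))
      i <- i + 2L
    } else {
      if (!ch %in% names(.residue_mass))
        stop("unknown residue letter '", ch, "'")
      residues <- c(residues, ch)
      i <- i + 1L
    }
  }
  mods <- data.frame(
    index = integer(0), name = character(0), delta = numeric(0),
    stringsAsFactors = FALSE
  )
  if (acetyl)
    mods <- rbind(mods, data.frame(index = 0L, name = "acetyl",
                                   delta = .mass_acetyl))
  if (length(mod_idx))
    mods <- rbind(mods, data.frame(index = mod_idx, name = "phospho",
                                   delta = .mass_phospho))
  mass <- sum(.residue_mass[residues]) + .mass_water + sum(mods$delta)
  structure(
    list(sequence = sequence, residues = residues, mods = mods,
         n = length(residues), mass = unname(mass)),
    class = "annotated_peptide"
  )
}

#' @export
print.annotated_peptide <- function(x, ...) {
  cat("Annotated peptide:", x$sequence, "\n")
  cat("  residues:", x$n, "  monoisotopic mass:",
      sprintf("%.6f Da", x$mass), "\n")
  if (nrow(x$mods)) {
    for (k in seq_len(nrow(x$mods)))
      cat(sprintf("  mod: %s at residue %d (+%.6f Da)\n",
                  x$mods$name[k], x$mods$index[k], x$mods$delta[k]))
  }
  invisible(x)
}

# Per-residue mass including any site-specific modification delta.
residue_masses_with_mods <- function(pep) {
  m <- unname(.residue_mass[pep$residues])
  if (nrow(pep$mods)) {
    site_mods <- pep$mods[pep$mods$index > 0, , drop = FALSE]
    if (nrow(site_mods))
      m[site_mods$index] <- m[site_mods$index] + site_mods$delta
  }
  m
}

# N-terminal modification mass (acetyl), 0 if none.
nterm_mod_mass <- function(pep) {
  nt <- pep$mods[pep$mods$index == 0, , drop = FALSE]
  if (nrow(nt)) sum(nt$delta) else 0
}

#' Phosphosite indices of an annotated peptide
#'
#' @param pep An \code{annotated_peptide}.
#' @return Integer vector of residue indices carrying a phospho group.
#' @export
phosphosites <- function(pep) {
  stopifnot(inherits(pep, "annotated_peptide"))
  pep$mods$index[pep$mods$name == "phospho"]
}
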