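# Charged-group identification, minimum inter-group distances and
# salt-bridge / ionic-hydrogen-bond classification under a protonation
# hypothesis.

.site_kinds <- c("arg_guanidinium", "lys_ammonium", "n_terminus")

#' Declare a protonation hypothesis
#'
#' A pattern names the formally protonated (+1) sites and the phosphate
#' state (deprotonated, -1, or neutral, 0).  Doubly protonated precursor
#' ions constrain the total charge to +2: three protonated sites with a
#' deprotonated phosphate (salt bridges anticipated), or two protonated
#' sites with a neutral phosphate (ionic hydrogen bonds anticipated).
#'
#' @param name Pattern label, e.g. \code{"R6+,K11+,K15+,POx-"}.
#' @param charged_sites Data frame with columns \code{index} (residue
#'   number) and \code{kind} (one of \code{"arg_guanidinium"},
#'   \code{"lys_ammonium"}, \code{"n_terminus"}).
#' @param phosphate_state Integer, \code{-1} (deprotonated) or \code{0}
#'   (neutral).
#' @param phosphosite Residue index of the phosphorylated residue.
#' @return Object of class \code{protonation_pattern} with a computed
#'   \code{total_charge}.
#' @export
protonation_pattern <- function(name, charged_sites, phosphate_state,
                                phosphosite) {
  stopifnot(all(c("index", "kind") %in% names(charged_sites)),
            phosphate_state %in% c(-1L, 0L),
            all(charged_sites$kind %in% .site_kinds))
  structure(
    list(name = name, charged_sites = charged_sites,
         phosphate_state = as.integer(phosphate_state),
         phosphosite = as.integer(phosphosite),
         total_charge = nrow(charged_sites) + as.integer(phosphate_state)),
    class = "protonation_pattern"
  )
}

#' @export
print.protonation_pattern <- function(x, ...) {
  cat("Protonation pattern:", x$name, " (total charge ",
      sprintf("%+d", x$total_charge), ")\n", sep = "")
  invisible(x)
}

# short display name of a basic site, e.g. "R6", "K11", "NT"
site_label <- function(kind, index) {
  switch(kind,
         arg_guanidinium = paste0("R", index),
         lys_ammonium = paste0("K", index),
         n_terminus = "NT")
}

#' Charged heavy atoms of each site under a pattern
#'
#' Resolves each charged site to its charge-carrying heavy atoms:
#' lysine ammonium to the side-chain NZ; arginine guanidinium to NE, NH1
#' and NH2; the N-terminus to the backbone N of residue 1; the phosphate
#' (whether charged or neutral) to the three terminal phosphate oxygens
#' (O1P/O2P/O3P).  Hydrogens are never used.
#'
#' @param s An \code{ims_structure} whose residue numbering matches the
#'   pattern indices.
#' @param pattern A \code{protonation_pattern}.
#' @return Named list mapping site label (\code{"R6"}, \code{"K11"},
#'   \code{"NT"}, \code{"phosphate"}) to an n x 3 coordinate matrix.
#' @export
charged_atoms <- function(s, pattern) {
  stopifnot(inherits(s, "ims_structure"),
            inherits(pattern, "protonation_pattern"))
  a <- s$atoms
  pick <- function(resno, names, what) {
    sel <- a$resno == resno & a$elety %in% names
    if (!any(sel))
      stop("residue ", resno, " lacks expected ", what, " atom(s) ",
           paste(names, collapse = "/"))
    as.matrix(a[sel, c("x", "y", "z")])
  }
  out <- list()
  for (k in seq_len(nrow(pattern$charged_sites))) {
    idx <- pattern$charged_sites$index[k]
    kind <- pattern$charged_sites$kind[k]
    out[[site_label(kind, idx)]] <- switch(kind,
      lys_ammonium = pick(idx, "NZ", "lysine ammonium"),
      arg_guanidinium = pick(idx, c("NE", "NH1", "NH2"),
                             "arginine guanidinium"),
      n_terminus = pick(1L, "N", "N-terminal amine"))
  }
  out[["phosphate"]] <- pick(pattern$phosphosite, c("O1P", "O2P", "O3P"),
                             "phosphate oxygen")
  out
}

#' Minimum distance between two atom groups
#'
#' @param a,b Coordinate matrices (n x 3), non-empty.
#' @return Minimum Euclidean distance over all cross pairs (A).
#' @export
min_group_distance <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 3)
  b <- matrix(as.numeric(b), ncol = 3)
  stopifnot(nrow(a) >= 1, nrow(b) >= 1)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

#' Classify a phosphate-to-partner contact
#'
#' A contact closer than the threshold (strict \code{<}, default 4 A
#' between charged heavy atoms) is a salt bridge when the phosphate is
#' deprotonated and the partner formally charged; an ionic hydrogen bond
#' when the phosphate is neutral and the partner charged; and a plain
#' (non-ionic) hydrogen bond when the partner is not charged.  At or beyond
#' the threshold the classification is \code{"none"}.
#'
#' @param d Distance in A.
#' @param phosphate_state \code{-1} (deprotonated) or \code{0} (neutral).
#' @param partner_charged Logical: is the partner site formally protonated?
#' @param threshold Distance cutoff in A (default 4.0).
#' @return One of \code{"salt_bridge"}, \code{"ionic_hydrogen_bond"},
#'   \code{"hydrogen_bond"}, \code{"none"}.
#' @export
classify_contact <- function(d, phosphate_state, partner_charged,
                             threshold = 4.0) {
  stopifnot(d >= 0)
  if (threshold < 0) stop("negative threshold")
  if (d >= threshold) return("none")
  if (!partner_charged) return("hydrogen_bond")
  if (phosphate_state == -1L) "salt_bridge" else "ionic_hydrogen_bond"
}

#' Distance/contact matrix of representative structures
#'
#' One row per structure, one column per basic site in the pattern (plus
#' the N-terminus if charged); each cell records the minimum
#' phosphate-to-site heavy-atom distance, its classification, and a Y/N
#' contact flag (Y iff distance < threshold).
#'
#' @param structures List of \code{ims_structure} representatives.
#' @param pattern A \code{protonation_pattern}.
#' @param threshold Contact cutoff in A (default 4.0).
#' @return Object of class \code{interaction_matrix}: data frame in long
#'   form with columns \code{structure}, \code{site}, \code{min_distance},
#'   \code{classification}, \code{contact} ("Y"/"N"), plus attributes
#'   \code{pattern} and \code{threshold}.
#' @export
interaction_table <- function(structures, pattern, threshold = 4.0) {
  stopifnot(length(structures) >= 1)
  rows <- list()
  for (si in seq_along(structures)) {
    s <- structures[[si]]
    groups <- charged_atoms(s, pattern)
    ph <- groups[["phosphate"]]
    for (nm in setdiff(names(groups), "phosphate")) {
      d <- min_group_distance(ph, groups[[nm]])
      cls <- classify_contact(d, pattern$phosphate_state, TRUE, threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        structure = if (nzchar(s$label)) s$label else paste0("structure_", si),
        site = nm, min_distance = d, classification = cls,
        contact = if (d < threshold) "Y" else "N",
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "pattern") <- pattern
  attr(out, "threshold") <- threshold
  class(out) <- c("interaction_matrix", "data.frame")
  out
}

#' Y/N contact grid of an interaction matrix
#'
#' @param x An \code{interaction_matrix}.
#' @return Character matrix (structures x sites) of "Y"/"N".
#' @export
contact_grid <- function(x) {
  stopifnot(inherits(x, "interaction_matrix"))
  structs <- unique(x$structure)
  sites <- unique(x$site)
  g <- matrix("N", length(structs), length(sites),
              dimnames = list(structs, sites))
  for (k in seq_len(nrow(x))) g[x$structure[k], x$site[k]] <- x$contact[k]
  g
}

#' Write an interaction matrix as delimited text
#'
#' @param x An \code{interaction_matrix}.
#' @param path Output path.
#' @export
write_interaction_matrix <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
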