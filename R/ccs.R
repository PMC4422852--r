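# Orientation-averaged projection-approximation (PA) collision cross
# sections of atomic structures, plus PDB structure I/O (via bio3d).

#' Default collision radii table
#'
#' Van der Waals radii for the elements common in peptides plus a probe
#' radius for the drift gas; the combined (atom + probe) radius is the
#' collision disk radius used by the projection approximation.
#'
#' @param probe Either \code{"helium"} (probe 1.0 A) or \code{"nitrogen"}
#'   (probe 1.8 A, matching TWIMS drift gas).
#' @return List with \code{radii} (named numeric vector, A) and
#'   \code{probe} (A).
#' @export
default_radii <- function(probe = c("helium", "nitrogen")) {
  probe <- match.arg(probe)
  list(
    radii = c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80),
    probe = if (probe == "helium") 1.0 else 1.8
  )
}

#' Construct a structure object from atom records
#'
#' @param element Character vector of element symbols.
#' @param xyz Numeric matrix (n x 3) of coordinates in Angstrom.
#' @param resno Integer vector of residue numbers.
#' @param resid Character vector of residue names.
#' @param elety Character vector of atom names (e.g. "CA", "NZ").
#' @param label Structure label.
#' @return Object of class \code{ims_structure}: list with \code{atoms}
#'   (data frame) and \code{label}.
#' @export
structure_from_atoms <- function(element, xyz, resno = 1L, resid = "UNK",
                                 elety = element, label = "") {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  n <- nrow(xyz)
  stopifnot(n >= 1L, all(is.finite(xyz)))
  atoms <- data.frame(
    element = rep_len(element, n), elety = rep_len(elety, n),
    resno = rep_len(as.integer(resno), n), resid = rep_len(resid, n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE
  )
  structure(list(atoms = atoms, label = label), class = "ims_structure")
}

#' @export
print.ims_structure <- function(x, ...) {
  cat("Structure", if (nzchar(x$label)) paste0("'", x$label, "'") else "",
      "with", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$resno)), "residues\n")
  invisible(x)
}

# strip digits/primes from an atom name and take the leading letter(s)
infer_element <- function(elety) {
  nm <- gsub("[^A-Za-z]", "", elety)
  two <- toupper(substr(nm, 1, 2))
  one <- toupper(substr(nm, 1, 1))
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE"), two, one)
}

#' Load a structure from a PDB file
#'
#' ATOM/HETATM records are read with \code{bio3d::read.pdb}; when the
#' element column is blank the element is inferred from the atom name.
#'
#' @param path Path to a PDB file.
#' @param label Structure label (default: file base name).
#' @return An \code{ims_structure}.
#' @export
load_structure <- function(path, label = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0L) stop("no atoms in ", path)
  elem <- at$elesy
  blank <- is.na(elem) | !nzchar(trimws(elem))
  elem[blank] <- infer_element(at$elety[blank])
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("malformed coordinates in ", path)
  if (is.null(label))
    label <- sub("\\.pdb$", "", basename(path), ignore.case = TRUE)
  structure_from_atoms(trimws(toupper(elem)), xyz, resno = at$resno,
                       resid = at$resid, elety = trimws(at$elety),
                       label = label)
}

#' Write a structure to a PDB file
#'
#' @param s An \code{ims_structure}.
#' @param path Output path.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "ims_structure"))
  a <- s$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, elety = a$elety,
                   elesy = a$element, chain = rep("A", nrow(a)))
  invisible(path)
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# n uniformly distributed rotation matrices via random unit quaternions
random_rotations <- function(n) {
  q <- matrix(stats::rnorm(4 * n), ncol = 4)
  q <- q / sqrt(rowSums(q^2))
  lapply(seq_len(n), function(i) {
    w <- q[i, 1]; x <- q[i, 2]; y <- q[i, 3]; z <- q[i, 4]
    matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
      2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
      2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
    ), nrow = 3, byrow = TRUE)
  })
}

#' Projection-approximation collision cross section
#'
#' Estimates the orientation-averaged projected area of the union of atomic
#' collision disks (atom van der Waals radius + probe radius).  For each of
#' \code{n_orientations} uniformly random rigid rotations, the projected
#' area is estimated by throwing \code{n_darts} uniform darts over the
#' projected bounding box; the CCS is the mean over orientations and the
#' quoted uncertainty the Monte-Carlo standard error over orientations.
#' Fully deterministic for a given seed.
#'
#' @param s An \code{ims_structure}.
#' @param radii Radii table from \code{\link{default_radii}} (or same shape).
#' @param n_orientations Number of random orientations (default 300).
#' @param n_darts Darts per orientation (default 512).
#' @param seed Integer RNG seed.
#' @param scale Optional multiplicative scale factor applied to the final
#'   CCS (default 1; lets users emulate a projection-to-trajectory-method
#'   offset).
#' @return Object of class \code{ccs_result}: list with \code{ccs} (A^2),
#'   \code{mc_stderr}, \code{n_orientations}, \code{n_darts}, \code{seed},
#'   \code{label}.
#' @export
pa_ccs <- function(s, radii = default_radii(), n_orientations = 300,
                   n_darts = 512, seed = 1, scale = 1) {
  stopifnot(inherits(s, "ims_structure"), n_orientations >= 1, n_darts >= 1)
  r_atom <- radii$radii[s$atoms$element]
  if (any(is.na(r_atom)))
    stop("no collision radius for element(s): ",
         paste(unique(s$atoms$element[is.na(r_atom)]), collapse = ", "))
  r <- unname(r_atom) + radii$probe
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, colMeans(xyz))
  r2 <- r^2

  areas <- with_local_seed(seed, {
    rots <- random_rotations(n_orientations)
    vapply(rots, function(R) {
      p <- xyz %*% t(R)
      px <- p[, 1]; py <- p[, 2]
      xlo <- min(px - r); xhi <- max(px + r)
      ylo <- min(py - r); yhi <- max(py + r)
      dx <- stats::runif(n_darts, xlo, xhi)
      dy <- stats::runif(n_darts, ylo, yhi)
      # hit if dart falls inside any projected disk
      hit <- rep(FALSE, n_darts)
      for (a in seq_along(px)) {
        miss <- which(!hit)
        if (!length(miss)) break
        hit[miss] <- (dx[miss] - px[a])^2 + (dy[miss] - py[a])^2 <= r2[a]
      }
      mean(hit) * (xhi - xlo) * (yhi - ylo)
    }, 0)
  })
  structure(
    list(ccs = mean(areas) * scale,
         mc_stderr = stats::sd(areas) / sqrt(n_orientations) * scale,
         n_orientations = n_orientations, n_darts = n_darts,
         seed = seed, label = s$label),
    class = "ccs_result"
  )
}

#' @export
print.ccs_result <- function(x, ...) {
  cat(sprintf("PA CCS: %.2f +/- %.2f A^2 (%d orientations x %d darts)\n",
              x$ccs, x$mc_stderr, x$n_orientations, x$n_darts))
  invisible(x)
}

#' Batch projection-approximation CCS over an ensemble
#'
#' Per-structure results with independent seeded substreams (structure
#' \eqn{i} uses \code{seed + i - 1}); input order is preserved and the same
#' master seed reproduces identical results.
#'
#' @param ensemble List of \code{ims_structure} objects.
#' @param radii,n_orientations,n_darts,scale As in \code{\link{pa_ccs}}.
#' @param seed Master seed.
#' @return Data frame with columns \code{label}, \code{ccs},
#'   \code{mc_stderr}, \code{seed}.
#' @export
batch_ccs <- function(ensemble, radii = default_radii(),
                      n_orientations = 300, n_darts = 512, seed = 1,
                      scale = 1) {
  stopifnot(length(ensemble) >= 1)
  rows <- lapply(seq_along(ensemble), function(i) {
    res <- tryCatch(
      pa_ccs(ensemble[[i]], radii, n_orientations, n_darts,
             seed = seed + i - 1, scale = scale),
      error = function(e) stop("structure ", i, " (",
                               ensemble[[i]]$label, "): ",
                               conditionMessage(e))
    )
    data.frame(label = res$label, ccs = res$ccs, mc_stderr = res$mc_stderr,
               seed = res$seed, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
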