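# Seeded synthetic generators: coarse-grained conformer ensembles with
# planted contacts, calibrant tables from a known power law, fragment peak
# lists realising specified abundances, and arrival-time profiles.

#' Specify a planted contact
#'
#' @param res_a,res_b Residue indices of the partners (phosphosite and a
#'   basic site).
#' @param distance Target minimum heavy-atom distance in A.  Present
#'   contacts must sit below 4 A, absent ones at 6 A or more, keeping a
#'   clear margin around the classification threshold.
#' @param present Logical: should the contact exist?
#' @return A one-row data frame (rbind-able contact spec).
#' @export
contact_spec <- function(res_a, res_b, distance, present = TRUE) {
  if (present && distance >= 4.0)
    stop("a present contact must be planted below 4 A")
  if (!present && distance < 6.0)
    stop("an absent contact must be planted at 6 A or more")
  data.frame(res_a = res_a, res_b = res_b, distance = distance,
             present = present)
}

# place a point along direction u from q0 so that its minimum distance to
# the atom set `cloud` is exactly d (monotone in t once past the cloud)
solve_anchor <- function(q0, cloud, u, d) {
  f <- function(t) {
    p <- q0 + t * u
    min(sqrt(rowSums(sweep(cloud, 2, p)^2))) - d
  }
  t <- stats::uniroot(f, c(max(0.1, d - 3), d + 3), tol = 1e-10)$root
  q0 + t * u
}

# unit vectors with pairwise angular separation >= 60 degrees
spread_directions <- function(k) {
  dirs <- list()
  while (length(dirs) < k) {
    v <- stats::rnorm(3)
    v <- v / sqrt(sum(v^2))
    ok <- all(vapply(dirs, function(u) sum(u * v) < 0.5, TRUE))
    if (ok) dirs[[length(dirs) + 1L]] <- v
  }
  dirs
}

#' Generate a coarse-grained conformer ensemble with planted contacts
#'
#' Builds \code{n} pseudo-peptide structures for a phosphopeptide sequence:
#' a jittered C-alpha backbone trace plus the named charged pseudo-atoms
#' the distance analysis needs (NZ for lysines, the NE/NH1/NH2 guanidinium
#' triad for arginines, O1P/O2P/O3P for the phosphoserine, the backbone N
#' of residue 1).  Each contact spec is satisfied exactly: the basic
#' group's nearest atom is placed at the requested distance from the
#' nearest phosphate oxygen, and every unspecified phosphate-to-basic-site
#' distance is at least 6 A.  Deterministic per seed.  These are geometric
#' stand-ins for force-field conformers: the tested claims concern
#' distances, CCS filtering, clustering and classification, not
#' conformational energetics.
#'
#' @param sequence Modified sequence string (see
#'   \code{\link{build_peptide}}), e.g. \code{"APLpSFRGSLPKSYVK"}.
#' @param n Number of structures.
#' @param contacts Data frame of \code{\link{contact_spec}} rows referring
#'   to (phosphosite, basic residue) pairs; unlisted basic sites are placed
#'   far (>= 6 A).
#' @param seed Integer seed.
#' @param jitter Per-structure backbone jitter (A, default 0.3).
#' @param size_spread Half-width of the uniform per-structure coordinate
#'   scale factor (default 0: all structures the same size).  Nonzero
#'   values produce a CCS distribution bracketing the base size.
#' @param far_distance Distance at which absent contacts are placed
#'   (default 9 A).
#' @return List of \code{ims_structure} objects (labels
#'   \code{"conf_0001"}, ...).
#' @export
gen_conformers <- function(sequence, n, contacts = NULL, seed = 1,
                           jitter = 0.3, size_spread = 0,
                           far_distance = 9) {
  pep <- build_peptide(sequence)
  ps <- phosphosites(pep)
  if (length(ps) != 1L)
    stop("generator expects exactly one phosphosite in the sequence")
  basic <- which(pep$residues %in% c("K", "R"))
  if (!is.null(contacts) && nrow(contacts)) {
    partners <- ifelse(contacts$res_a == ps, contacts$res_b, contacts$res_a)
    if (any(!(contacts$res_a == ps | contacts$res_b == ps)))
      stop("every contact must involve the phosphosite (residue ", ps, ")")
    if (any(!partners %in% c(basic, 1L)))
      stop("contact partner is not a basic site or the N-terminus")
  }
  stopifnot(far_distance >= 6)

  with_local_seed(seed, {
    lapply(seq_len(n), function(si) {
      scale <- if (size_spread > 0)
        stats::runif(1, 1 - size_spread, 1 + size_spread) else 1
      # extended-chain CA trace with gentle curvature + jitter; the scale
      # factor is applied to the backbone only, so planted charged-group
      # distances stay exact while the molecular extent (and hence CCS)
      # varies across the ensemble
      t_par <- seq_len(pep$n)
      ca <- cbind(3.2 * t_par, 2.5 * sin(t_par / 2), 2.5 * cos(t_par / 2))
      ca <- (ca + matrix(stats::rnorm(3 * pep$n, sd = jitter),
                         ncol = 3)) * scale

      elety <- rep("CA", pep$n)
      resno <- t_par
      xyz <- ca
      add_atom <- function(name, rn, coord) {
        elety <<- c(elety, name); resno <<- c(resno, rn)
        xyz <<- rbind(xyz, coord)
      }

      # phosphate oxygen triad anchored near the phosphosite CA
      q0 <- ca[ps, ] + c(0, 2.4, 0)
      phos <- rbind(q0, q0 + c(0, 0.6, 1.2), q0 + c(0, 0.6, -1.2))
      add_atom("O1P", ps, phos[1, ])
      add_atom("O2P", ps, phos[2, ])
      add_atom("O3P", ps, phos[3, ])

      # charged sites: every K/R side chain plus the N-terminal amine
      sites <- c(1L, basic)
      dirs <- spread_directions(length(sites))
      for (bi in seq_along(sites)) {
        res <- sites[bi]
        u <- dirs[[bi]]
        spec_row <- NULL
        if (!is.null(contacts) && nrow(contacts)) {
          hit <- which((contacts$res_a == res | contacts$res_b == res) &
                         !(res == ps))
          if (res == 1L && bi > 1L) hit <- integer(0)
          if (length(hit)) spec_row <- contacts[hit[1L], ]
        }
        d <- if (!is.null(spec_row)) spec_row$distance else far_distance
        anchor <- solve_anchor(q0, phos, u, d)
        if (bi == 1L) {
          # backbone N of residue 1 (N-terminal amine)
          add_atom("N", 1L, anchor)
        } else if (pep$residues[res] == "K") {
          add_atom("NZ", res, anchor)
        } else {
          # guanidinium triad; NE is the contact atom, NH1/NH2 sit behind
          add_atom("NE", res, anchor)
          add_atom("NH1", res, anchor + 1.1 * u + c(0, 0, 0.4))
          add_atom("NH2", res, anchor + 1.1 * u + c(0, 0, -0.4))
        }
      }
      structure_from_atoms(
        element = infer_element(elety), xyz = xyz,
        resno = resno,
        resid = vapply(resno, function(r) {
          if (r == ps) "SEP" else c(
            G = "GLY", A = "ALA", S = "SER", P = "PRO", V = "VAL",
            T = "THR", C = "CYS", L = "LEU", I = "ILE", N = "ASN",
            D = "ASP", Q = "GLN", K = "LYS", E = "GLU", M = "MET",
            H = "HIS", F = "PHE", R = "ARG", Y = "TYR",
            W = "TRP")[[pep$residues[r]]]
        }, ""),
        elety = elety,
        label = sprintf("conf_%04d", si)
      )
    })
  })
}

#' Write an ensemble to a directory of PDB files
#'
#' @param ensemble List of \code{ims_structure} objects.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths.
#' @export
write_ensemble <- function(ensemble, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vapply(ensemble, function(s) {
    path <- file.path(dir, paste0(s$label, ".pdb"))
    write_structure(s, path)
    path
  }, "")
}

#' Generate a synthetic calibrant table from a known power law
#'
#' Samples peptide-like masses and charges, assigns each a literature-style
#' CCS from a smooth mass trend, inverts the calibration relation
#' \eqn{\Omega' = A (t'_d)^X} to obtain corrected drift times, adds the EDC
#' flight-time term back, and applies multiplicative log-normal noise to
#' the drift times.
#'
#' @param A,X True power-law parameters.
#' @param edc EDC delay coefficient.
#' @param n Number of calibrants (>= 3).
#' @param noise_frac Log-normal noise fraction on drift times (0 = exact).
#' @param seed Integer seed.
#' @param gas_mass Drift gas mass (Da; default nitrogen).
#' @return Data frame with columns \code{mass}, \code{charge},
#'   \code{drift_time_ms}, \code{ccs_A2} and attributes \code{A}, \code{X}.
#' @export
gen_calibrants <- function(A, X, edc, n = 20, noise_frac = 0, seed = 1,
                           gas_mass = .mass_n2) {
  stopifnot(A > 0, X > 0)
  if (n < 3L) stop("need at least 3 calibrants")
  with_local_seed(seed, {
    mass <- stats::runif(n, 700, 2600)
    charge <- sample(1:3, n, replace = TRUE)
    ccs <- 9.0 * mass^0.5 * exp(stats::rnorm(n, sd = 0.02))
    ccs_red <- reduced_ccs(ccs, charge, mass, gas_mass)
    tdp <- (ccs_red / A)^(1 / X)
    mz <- mass / charge + .mass_proton
    td <- tdp + edc * sqrt(mz) / 1000
    if (noise_frac > 0)
      td <- td * exp(stats::rnorm(n, sd = noise_frac))
    out <- data.frame(mass = mass, charge = charge, drift_time_ms = td,
                      ccs_A2 = ccs)
    attr(out, "A") <- A
    attr(out, "X") <- X
    out
  })
}

#' Generate a peak list realising specified fragment abundances
#'
#' Places peaks at the exact theoretical m/z of the requested ions with
#' intensities proportional to the requested percentages; when the
#' percentages sum below 100 and no charge-reduced entry is given, the
#' remainder is assigned to the charge-reduced species.  Optional decoy
#' peaks are kept at least \code{decoy_min_ppm} away from every theoretical
#' ion of the peptide.
#'
#' @param pep An \code{annotated_peptide}.
#' @param abundances Data frame with columns \code{ion_type},
#'   \code{frag_index} (NA for precursor species), \code{neutral_loss}
#'   and \code{abundance} (percent, >= 0, summing to <= 100).
#' @param total_intensity Total spectrum intensity to distribute.
#' @param n_decoys Number of decoy peaks (default 0).
#' @param decoy_min_ppm Minimum ppm distance of a decoy from any
#'   theoretical ion (default 5).
#' @param seed Integer seed (used only for decoys).
#' @return A \code{peaklist}.
#' @export
gen_peaklist <- function(pep, abundances, total_intensity = 1e6,
                         n_decoys = 0, decoy_min_ppm = 5, seed = 1) {
  stopifnot(inherits(pep, "annotated_peptide"),
            all(c("ion_type", "frag_index", "abundance") %in%
                  names(abundances)))
  if (!"neutral_loss" %in% names(abundances)) abundances$neutral_loss <- 0
  if (any(abundances$abundance < 0)) stop("negative abundance")
  if (sum(abundances$abundance) > 100 + 1e-9)
    stop("abundances sum above 100%")
  full <- theoretical_ions(pep, types = .ion_alphabet, charges = 1L,
                           losses = c(0, .mass_h3po4))
  key <- function(tp, idx, loss) paste(tp, ifelse(is.na(idx), "pre", idx),
                                       round(loss, 4))
  full_key <- key(full$ion_type, full$frag_index, full$neutral_loss)
  ab <- abundances
  if (sum(ab$abundance) < 100 - 1e-9 &&
      !"charge_reduced" %in% ab$ion_type) {
    ab <- rbind(ab, data.frame(ion_type = "charge_reduced",
                               frag_index = NA_integer_, neutral_loss = 0,
                               abundance = 100 - sum(ab$abundance)))
  }
  idx <- match(key(ab$ion_type, ab$frag_index, ab$neutral_loss), full_key)
  if (any(is.na(idx)))
    stop("abundance specified for ion(s) not generatable from this ",
         "peptide: ",
         paste(ab$ion_type[is.na(idx)], ab$frag_index[is.na(idx)],
               collapse = ", "))
  mz <- full$mz[idx]
  intensity <- total_intensity * ab$abundance / 100
  keep <- intensity > 0
  mz <- mz[keep]; intensity <- intensity[keep]
  if (n_decoys > 0) {
    dec <- with_local_seed(seed, {
      out <- numeric(0)
      lo <- min(full$mz) * 0.95
      hi <- max(full$mz) * 1.05
      while (length(out) < n_decoys) {
        cand <- stats::runif(n_decoys, lo, hi)
        ppm_dist <- vapply(cand, function(m)
          min(abs(1e6 * (m - full$mz) / full$mz)), 0)
        out <- c(out, cand[ppm_dist >= decoy_min_ppm])
      }
      out[seq_len(n_decoys)]
    })
    dec_int <- rep(0.05 * max(intensity), n_decoys)
    mz <- c(mz, dec); intensity <- c(intensity, dec_int)
  }
  ord <- order(mz)
  peaklist(mz[ord], intensity[ord], source = pep$sequence)
}

#' Generate a synthetic arrival-time / CCS profile
#'
#' Sum of Gaussian conformer peaks on a CCS grid plus optional additive
#' noise; deterministic per seed.
#'
#' @param peaks Data frame with columns \code{ccs} (center), \code{width}
#'   (Gaussian sigma) and \code{height}.
#' @param grid Numeric CCS axis (default 300..420 in steps of 0.5).
#' @param noise_sd Additive Gaussian noise standard deviation (default 0).
#' @param seed Integer seed.
#' @return Data frame with columns \code{ccs}, \code{intensity}.
#' @export
gen_atd <- function(peaks, grid = seq(300, 420, by = 0.5), noise_sd = 0,
                    seed = 1) {
  stopifnot(all(c("ccs", "width", "height") %in% names(peaks)),
            nrow(peaks) >= 1, all(peaks$width > 0))
  y <- rep(0, length(grid))
  for (k in seq_len(nrow(peaks)))
    y <- y + peaks$height[k] *
      exp(-(grid - peaks$ccs[k])^2 / (2 * peaks$width[k]^2))
  if (noise_sd > 0)
    y <- y + with_local_seed(seed,
                             stats::rnorm(length(grid), sd = noise_sd))
  data.frame(ccs = grid, intensity = y)
}
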