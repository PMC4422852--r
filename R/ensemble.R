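# Conformer ensemble filtering, superposition, clustering and
# representative selection.

#' Bundle conformers with their CCS values
#'
#' @param structures List of \code{ims_structure} objects.
#' @param ccs Numeric vector of CCS values (A^2), same length.
#' @param target_ccs Experimental target CCS (A^2).
#' @param window Relative filter half-width (default 0.03, i.e. +/- 3%).
#' @return Object of class \code{conformer_set}.
#' @export
conformer_set <- function(structures, ccs, target_ccs, window = 0.03) {
  stopifnot(length(structures) == length(ccs), length(structures) >= 1,
            window > 0, target_ccs > 0)
  structure(list(structures = structures, ccs = as.numeric(ccs),
                 target_ccs = target_ccs, window = window),
            class = "conformer_set")
}

#' Filter conformers to the experimental CCS window
#'
#' Retains structures with \eqn{|\Omega - \Omega_{target}| / \Omega_{target}
#' \le} \code{window} (inclusive bounds).  An empty result is allowed and
#' reported with a warning.
#'
#' @param set A \code{conformer_set}.
#' @return A \code{conformer_set} containing only the retained records.
#' @export
filter_by_ccs <- function(set) {
  stopifnot(inherits(set, "conformer_set"))
  keep <- abs(set$ccs - set$target_ccs) / set$target_ccs <= set$window
  if (!any(keep))
    warning("no conformers within +/-", 100 * set$window,
            "% of target CCS ", set$target_ccs)
  out <- set
  out$structures <- set$structures[keep]
  out$ccs <- set$ccs[keep]
  out
}

#' Rigid least-squares superposition of two structures
#'
#' Optimal rotation/translation (Kabsch, via \code{bio3d::fit.xyz}) of the
#' mobile structure onto the reference over a common atom selection.
#'
#' @param mobile,reference \code{ims_structure} objects.
#' @param atom_names Optional atom-name selection (e.g. \code{"CA"});
#'   default uses all atoms.  Selections must pair up 1:1.
#' @return List with \code{structure} (superposed mobile) and \code{rmsd}
#'   (A, over the selection).
#' @export
superpose <- function(mobile, reference, atom_names = NULL) {
  stopifnot(inherits(mobile, "ims_structure"),
            inherits(reference, "ims_structure"))
  sel_m <- if (is.null(atom_names)) seq_len(nrow(mobile$atoms)) else
    which(mobile$atoms$elety %in% atom_names)
  sel_r <- if (is.null(atom_names)) seq_len(nrow(reference$atoms)) else
    which(reference$atoms$elety %in% atom_names)
  if (length(sel_m) != length(sel_r))
    stop("atom selections differ in size (", length(sel_m), " vs ",
         length(sel_r), ")")
  if (length(sel_m) < 3L) stop("superposition needs at least 3 paired atoms")
  fixed <- as.numeric(t(as.matrix(reference$atoms[, c("x", "y", "z")])))
  mob <- as.numeric(t(as.matrix(mobile$atoms[, c("x", "y", "z")])))
  xyz_idx <- function(i) as.numeric(rbind(3 * i - 2, 3 * i - 1, 3 * i))
  fitted <- bio3d::fit.xyz(fixed, mob,
                           fixed.inds = xyz_idx(sel_r),
                           mobile.inds = xyz_idx(sel_m))
  out <- mobile
  m <- matrix(fitted, ncol = 3, byrow = TRUE)
  out$atoms$x <- m[, 1]; out$atoms$y <- m[, 2]; out$atoms$z <- m[, 3]
  ref_sel <- matrix(fixed, ncol = 3, byrow = TRUE)[sel_r, , drop = FALSE]
  mob_sel <- m[sel_m, , drop = FALSE]
  rmsd <- sqrt(mean(rowSums((ref_sel - mob_sel)^2)))
  list(structure = out, rmsd = rmsd)
}

#' Cluster a filtered conformer set
#'
#' Every structure is superposed onto the first retained structure, the
#' coordinates are flattened and k-means (Lloyd, seeded initialisation, up
#' to 500 iterations) is run.  Cluster populations are percentages of the
#' retained structures; the representative of a cluster is the member
#' closest to the cluster mean.
#'
#' @param set A (typically filtered) \code{conformer_set}.
#' @param k Number of clusters.
#' @param seed RNG seed for the k-means initialisation.
#' @param atom_names Optional atom-name selection used for superposition
#'   and clustering (default all atoms).
#' @return Object of class \code{conformer_clustering}: list with
#'   \code{labels}, \code{k}, \code{populations} (percent, by cluster id),
#'   \code{representatives} (structure indices by cluster id),
#'   \code{sizes}, \code{tot_withinss}.
#' @export
cluster_conformers <- function(set, k, seed = 1, atom_names = NULL) {
  stopifnot(inherits(set, "conformer_set"), k >= 1)
  n <- length(set$structures)
  if (n < k) stop("fewer structures (", n, ") than clusters (", k, ")")
  ref <- set$structures[[1]]
  coords <- t(vapply(set$structures, function(s) {
    sp <- superpose(s, ref, atom_names = atom_names)$structure
    sel <- if (is.null(atom_names)) seq_len(nrow(sp$atoms)) else
      which(sp$atoms$elety %in% atom_names)
    as.numeric(t(as.matrix(sp$atoms[sel, c("x", "y", "z")])))
  }, numeric(3 * (if (is.null(atom_names)) nrow(ref$atoms) else
    sum(ref$atoms$elety %in% atom_names)))))
  if (k == 1L) {
    km <- list(cluster = rep(1L, n),
               centers = matrix(colMeans(coords), nrow = 1),
               tot.withinss = sum(sweep(coords, 2, colMeans(coords))^2))
  } else {
    km <- with_local_seed(seed,
      stats::kmeans(coords, centers = k, iter.max = 500,
                    algorithm = "Lloyd", nstart = 5))
  }
  labels <- as.integer(km$cluster)
  sizes <- tabulate(labels, nbins = k)
  reps <- vapply(seq_len(k), function(cl) {
    members <- which(labels == cl)
    d2 <- rowSums(sweep(coords[members, , drop = FALSE], 2,
                        km$centers[cl, ])^2)
    members[which.min(d2)]
  }, 0L)
  structure(
    list(labels = labels, k = as.integer(k),
         populations = 100 * sizes / n,
         representatives = reps, sizes = sizes,
         tot_withinss = km$tot.withinss),
    class = "conformer_clustering"
  )
}

#' @export
print.conformer_clustering <- function(x, ...) {
  cat("Conformer clustering: k =", x$k, "\n")
  for (cl in seq_len(x$k))
    cat(sprintf("  cluster %d: %d structures (%.1f%%), representative #%d\n",
                cl, x$sizes[cl], x$populations[cl], x$representatives[cl]))
  invisible(x)
}

#' Most populated clusters
#'
#' @param clustering A \code{conformer_clustering}.
#' @param n How many clusters to return (\code{n <= k}).
#' @return Integer vector of cluster ids sorted by population descending,
#'   ties broken by smaller id.
#' @export
top_clusters <- function(clustering, n) {
  stopifnot(inherits(clustering, "conformer_clustering"))
  if (n > clustering$k) stop("requested ", n, " clusters but k = ",
                             clustering$k)
  ord <- order(-clustering$populations, seq_len(clustering$k))
  ord[seq_len(n)]
}
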