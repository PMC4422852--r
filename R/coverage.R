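# Cleavage-site coverage and fragmentation gaps.

#' Map assigned fragments onto cleavage sites
#'
#' Counts, for each backbone cleavage site \eqn{s \in 1..N-1}, how many
#' assigned site-bearing fragments cleave there (N-terminal a/b/c ions at
#' site \eqn{i} cover site \eqn{i}; C-terminal y/z ions of fragment length
#' \eqn{j} cover site \eqn{N-j}).  Precursor-derived species count nothing.
#' Maximal runs of uncovered sites are reported as gaps.
#'
#' @param assignments A \code{fragment_assignments} data frame.
#' @param pep The \code{annotated_peptide} the assignments refer to.
#' @return Object of class \code{coverage_map}: list with \code{site_cover}
#'   (integer vector over sites \code{1..n-1}), \code{gaps} (data frame with
#'   \code{from}, \code{to}) and \code{n}.
#' @export
coverage_map <- function(assignments, pep) {
  stopifnot(inherits(pep, "annotated_peptide"))
  n <- pep$n
  cover <- integer(n - 1L)
  sites <- assignments$site[!is.na(assignments$site)]
  if (length(sites)) {
    if (min(sites) < 1L || max(sites) > n - 1L)
      stop("assignment cleavage site outside 1..", n - 1L,
           ": wrong peptide?")
    tab <- tabulate(sites, nbins = n - 1L)
    cover <- as.integer(tab)
  }
  zero <- cover == 0L
  runs <- rle(zero)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  gaps <- data.frame(from = starts[runs$values], to = ends[runs$values])
  structure(list(site_cover = cover, gaps = gaps, n = n),
            class = "coverage_map")
}

#' @export
print.coverage_map <- function(x, ...) {
  cat("Cleavage-site coverage (", x$n - 1L, " sites):\n", sep = "")
  cat(" ", paste(x$site_cover, collapse = " "), "\n")
  if (nrow(x$gaps)) {
    for (k in seq_len(nrow(x$gaps)))
      cat(sprintf("  gap: sites %d..%d uncovered\n",
                  x$gaps$from[k], x$gaps$to[k]))
  } else cat("  no gaps\n")
  invisible(x)
}

#' Fragments separating a residue pair
#'
#' The cleavage sites whose products would separate residues \code{res_a}
#' and \code{res_b} are \eqn{s} with \code{res_a} \eqn{\le s <} \code{res_b}.
#' Returns those sites and the number of assigned fragments observed at
#' them; a count of zero means no ECD fragment separates the pair,
#' consistent with a surviving noncovalent bridge between them.
#'
#' @param cov A \code{coverage_map}.
#' @param res_a,res_b Residue indices with \code{res_a < res_b}.
#' @return List with \code{sites}, \code{counts} (per-site), \code{n_fragments}
#'   (total) and \code{uncovered_sites}.
#' @export
gap_between <- function(cov, res_a, res_b) {
  stopifnot(inherits(cov, "coverage_map"))
  if (!(res_a >= 1 && res_b <= cov$n && res_a < res_b))
    stop("need 1 <= res_a < res_b <= ", cov$n)
  sites <- seq.int(res_a, res_b - 1L)
  counts <- cov$site_cover[sites]
  list(sites = sites, counts = counts, n_fragments = sum(counts),
       uncovered_sites = sites[counts == 0L])
}
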