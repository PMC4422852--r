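# Correlating detected noncovalent contacts with observed ECD coverage:
# predicted suppressed cleavage sites and hypothesis agreement scoring.

#' Cleavage sites suppressed by bridged residue pairs
#'
#' A noncovalent bridge between residues \code{res_a} and \code{res_b}
#' holds the two fragments of any cleavage at a site \eqn{s} with
#' \code{res_a} \eqn{\le s <} \code{res_b} together, so no separated
#' fragment is observed from those sites.  Returns the union over all
#' pairs.
#'
#' @param pairs Data frame (or 2-column matrix) with columns \code{res_a},
#'   \code{res_b} (\code{res_a < res_b}); may have zero rows.
#' @param n Peptide length.
#' @return Sorted integer vector of suppressed cleavage sites.
#' @export
suppressed_sites <- function(pairs, n) {
  if (is.matrix(pairs)) pairs <- data.frame(res_a = pairs[, 1],
                                            res_b = pairs[, 2])
  if (nrow(pairs) == 0L) return(integer(0))
  stopifnot(all(pairs$res_a >= 1), all(pairs$res_b <= n),
            all(pairs$res_a < pairs$res_b))
  sort(unique(unlist(
    lapply(seq_len(nrow(pairs)),
           function(k) seq.int(pairs$res_a[k], pairs$res_b[k] - 1L))
  )))
}

#' Predict suppressed cleavage sites from an interaction matrix
#'
#' Each structure's sub-threshold contacts (restricted to the classes in
#' \code{suppressing}, by default salt bridges and ionic hydrogen bonds,
#' which are assumed to survive electron capture) define bridged residue
#' pairs between the phosphosite and the contacted basic site; those pairs
#' are converted to per-structure suppressed site sets, combined across the
#' ensemble by the chosen rule (\code{"union"}: suppressed in any
#' structure; \code{"majority"}: suppressed in more than half).
#'
#' @param x An \code{interaction_matrix}.
#' @param n Peptide length.
#' @param rule \code{"union"} or \code{"majority"}.
#' @param suppressing Classifications treated as fragment-separating
#'   suppressors.
#' @return Object of class \code{suppression_prediction}: list with
#'   \code{hypothesis}, \code{per_structure} (named list of site vectors),
#'   \code{suppressed}, \code{observable}, \code{n}.
#' @export
predict_suppression <- function(x, n, rule = c("union", "majority"),
                                suppressing = c("salt_bridge",
                                                "ionic_hydrogen_bond")) {
  stopifnot(inherits(x, "interaction_matrix"), nrow(x) >= 1)
  rule <- match.arg(rule)
  pattern <- attr(x, "pattern")
  ps <- pattern$phosphosite
  site_index <- function(site) {
    if (site == "NT") return(1L)
    as.integer(sub("^[RK]", "", site))
  }
  structs <- unique(x$structure)
  per_structure <- lapply(structs, function(st) {
    sub <- x[x$structure == st & x$classification %in% suppressing, ,
             drop = FALSE]
    if (nrow(sub) == 0L) return(integer(0))
    idx <- vapply(sub$site, site_index, 0L)
    pairs <- data.frame(res_a = pmin(ps, idx), res_b = pmax(ps, idx))
    suppressed_sites(pairs, n)
  })
  names(per_structure) <- structs
  all_sites <- seq_len(n - 1L)
  counts <- tabulate(unlist(per_structure), nbins = n - 1L)
  suppressed <- switch(rule,
    union = all_sites[counts > 0],
    majority = all_sites[counts > length(structs) / 2])
  structure(
    list(hypothesis = pattern$name, per_structure = per_structure,
         suppressed = suppressed,
         observable = setdiff(all_sites, suppressed), n = n, rule = rule),
    class = "suppression_prediction"
  )
}

#' Score a suppression hypothesis against observed coverage
#'
#' A cleavage site agrees with the hypothesis when it is predicted
#' observable and carries at least one assigned fragment, or predicted
#' suppressed and carries none.  The score is the fraction of agreeing
#' sites.
#'
#' @param pred A \code{suppression_prediction}.
#' @param cov A \code{coverage_map} for the same peptide.
#' @return Object of class \code{agreement_score}: list with
#'   \code{hypothesis}, \code{matches}, \code{score}, \code{detail} (data
#'   frame with per-site prediction, observation and agreement).
#' @export
score_agreement <- function(pred, cov) {
  stopifnot(inherits(pred, "suppression_prediction"),
            inherits(cov, "coverage_map"))
  if (pred$n != cov$n)
    stop("peptide length mismatch: prediction n = ", pred$n,
         ", coverage n = ", cov$n)
  sites <- seq_len(pred$n - 1L)
  predicted_obs <- !(sites %in% pred$suppressed)
  observed <- cov$site_cover > 0
  agree <- predicted_obs == observed
  structure(
    list(hypothesis = pred$hypothesis, matches = sum(agree),
         score = mean(agree),
         detail = data.frame(site = sites,
                             predicted_observable = predicted_obs,
                             observed_fragments = cov$site_cover,
                             agrees = agree)),
    class = "agreement_score"
  )
}

#' @export
print.agreement_score <- function(x, ...) {
  cat(sprintf("Hypothesis '%s': %d/%d sites agree (score %.3f)\n",
              x$hypothesis, x$matches, nrow(x$detail), x$score))
  invisible(x)
}

#' Rank competing protonation hypotheses
#'
#' @param scores List of \code{agreement_score} objects.
#' @return Data frame ordered by descending score with columns
#'   \code{hypothesis}, \code{score}, \code{matches}, \code{tied} (TRUE for
#'   rows sharing their score with another hypothesis).
#' @export
rank_hypotheses <- function(scores) {
  stopifnot(length(scores) >= 1)
  df <- do.call(rbind, lapply(scores, function(s)
    data.frame(hypothesis = s$hypothesis, score = s$score,
               matches = s$matches, stringsAsFactors = FALSE)))
  df <- df[order(-df$score), , drop = FALSE]
  df$tied <- duplicated(df$score) | duplicated(df$score, fromLast = TRUE)
  rownames(df) <- NULL
  df
}
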