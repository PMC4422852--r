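# Peak assignment and relative fragment-ion abundance.

#' Read a centroided peak list
#'
#' Two-column delimited text (m/z, intensity); a header line is detected and
#' skipped automatically.
#'
#' @param path File path.
#' @param sep Field separator (default: any whitespace or comma is tried).
#' @return A \code{peaklist}: data frame with columns \code{mz},
#'   \code{intensity} and attribute \code{source}.
#' @export
read_peaklist <- function(path, sep = NULL) {
  first <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl(",", first)) "," else ""
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(trimws(first), if (sep == "") "[[:space:]]+" else sep)[[1]][1])
  ))
  df <- utils::read.table(path, sep = sep, header = has_header,
                          stringsAsFactors = FALSE)
  peaklist(df[[1]], df[[2]], source = path)
}

#' Construct a peak list
#'
#' @param mz Numeric vector of m/z values (strictly positive).
#' @param intensity Numeric vector of intensities (non-negative).
#' @param source Optional label.
#' @return A data frame of class \code{peaklist}.
#' @export
peaklist <- function(mz, intensity, source = "") {
  stopifnot(length(mz) == length(intensity))
  if (length(mz)) stopifnot(all(mz > 0), all(intensity >= 0))
  structure(
    data.frame(mz = as.numeric(mz), intensity = as.numeric(intensity)),
    source = source, class = c("peaklist", "data.frame")
  )
}

#' Write a peak list as two-column delimited text
#'
#' @param peaks A \code{peaklist}.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @export
write_peaklist <- function(peaks, path, sep = "\t") {
  utils::write.table(as.data.frame(peaks)[, c("mz", "intensity")], path,
                     sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assign observed peaks to theoretical ions
#'
#' Greedy one-peak-one-ion matching: all (peak, ion) pairs within the ppm
#' tolerance are ranked by absolute ppm error, ties broken by ion-type
#' precedence, and accepted greedily so that each peak and each ion is used
#' at most once.  Unmatched peaks are silently left unassigned.
#'
#' @param peaks A \code{peaklist}.
#' @param ions Theoretical ion table from \code{\link{theoretical_ions}}.
#' @param tol_ppm Matching tolerance in parts per million (default 5, an
#'   FT-ICR-appropriate window).
#' @param precedence Ion-type preference order used to break exact ppm ties.
#' @return Data frame of class \code{fragment_assignments} with the matched
#'   ion columns plus \code{observed_mz}, \code{intensity}, \code{ppm_error}
#'   and (initially NA) \code{relative_abundance}.
#' @export
assign_peaks <- function(peaks, ions, tol_ppm = 5,
                         precedence = .default_precedence) {
  stopifnot(tol_ppm > 0)
  empty <- structure(
    data.frame(ion_type = character(0), site = integer(0),
               frag_index = integer(0), charge = integer(0),
               neutral_loss = numeric(0), neutral_mass = numeric(0),
               mz = numeric(0), label = character(0),
               observed_mz = numeric(0), intensity = numeric(0),
               ppm_error = numeric(0), relative_abundance = numeric(0)),
    class = c("fragment_assignments", "data.frame")
  )
  if (nrow(peaks) == 0L || nrow(ions) == 0L) return(empty)

  # candidate pairs within tolerance
  ppm <- outer(peaks$mz, ions$mz, function(o, t) 1e6 * (o - t) / t)
  cand <- which(abs(ppm) <= tol_ppm, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  prec_rank <- match(ions$ion_type[cand[, 2]], precedence)
  prec_rank[is.na(prec_rank)] <- length(precedence) + 1L
  ord <- order(abs(ppm[cand]), prec_rank)
  cand <- cand[ord, , drop = FALSE]

  used_peak <- logical(nrow(peaks))
  used_ion <- logical(nrow(ions))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    p <- cand[k, 1]; i <- cand[k, 2]
    if (!used_peak[p] && !used_ion[i]) {
      keep[k] <- TRUE
      used_peak[p] <- TRUE
      used_ion[i] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  out <- ions[cand[, 2], , drop = FALSE]
  out$observed_mz <- peaks$mz[cand[, 1]]
  out$intensity <- peaks$intensity[cand[, 1]]
  out$ppm_error <- ppm[cand]
  out$relative_abundance <- NA_real_
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fragment_assignments", "data.frame")
  out
}

#' Compute relative fragment-ion abundances
#'
#' Each assignment's intensity is divided by the summed intensity of all
#' assigned species, including the charge-reduced species, and reported as a
#' percentage, so the values sum to 100 over the assignment set.
#'
#' @param assignments A \code{fragment_assignments} data frame.
#' @return The same data frame with \code{relative_abundance} filled in.
#' @export
relative_abundance <- function(assignments) {
  stopifnot(nrow(assignments) > 0L)
  total <- sum(assignments$intensity)
  if (total <= 0) stop("all assigned intensities are zero")
  assignments$relative_abundance <- 100 * assignments$intensity / total
  assignments
}
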