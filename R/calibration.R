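# TWIMS CCS calibration: EDC drift-time correction, reduced CCS, power-law
# fit, random-coil trendline and deviation arithmetic, and arrival-time
# peak detection.

.mass_n2 <- 28.00615  # drift gas (nitrogen) mass, Da

#' Correct a TWIMS drift time for mass-dependent post-mobility flight
#'
#' \eqn{t'_d = t_d - c \sqrt{m/z} / 1000}, with the EDC (enhanced duty
#' cycle) delay coefficient \eqn{c} an instrument constant.
#'
#' @param t_d Measured drift time (ms).
#' @param mz Ion m/z.
#' @param edc EDC delay coefficient.
#' @return Corrected drift time \eqn{t'_d} (ms).
#' @export
correct_drift_time <- function(t_d, mz, edc) {
  stopifnot(all(t_d > 0), all(mz > 0))
  td_prime <- t_d - edc * sqrt(mz) / 1000
  if (any(td_prime <= 0))
    stop("corrected drift time non-positive: EDC coefficient too large")
  td_prime
}

#' Charge- and mass-reduced collision cross section
#'
#' \eqn{\Omega' = \Omega / (z \sqrt{1/m + 1/m_g})}; the reduced quantity is
#' what scales as a power of corrected drift time.
#'
#' @param ccs Collision cross section (A^2).
#' @param z Charge state.
#' @param m Ion mass (Da).
#' @param gas_mass Drift gas mass (Da; default nitrogen).
#' @return Reduced CCS.
#' @export
reduced_ccs <- function(ccs, z, m, gas_mass = .mass_n2) {
  stopifnot(all(ccs > 0), all(z >= 1), all(m > 0), gas_mass > 0)
  ccs / (z * sqrt(1 / m + 1 / gas_mass))
}

# inverse of reduced_ccs
unreduce_ccs <- function(ccs_red, z, m, gas_mass = .mass_n2) {
  ccs_red * z * sqrt(1 / m + 1 / gas_mass)
}

#' Fit the TWIMS power-law calibration
#'
#' Given calibrant ions of known (literature) CCS, fits
#' \eqn{\ln \Omega' = \ln A + X \ln t'_d} by least squares, where
#' \eqn{\Omega'} is the reduced CCS and \eqn{t'_d} the EDC-corrected drift
#' time.
#'
#' @param entries Data frame with columns \code{mass} (Da), \code{charge},
#'   \code{drift_time_ms} and \code{ccs_A2} (literature CCS).  At least 3
#'   rows.
#' @param edc EDC delay coefficient.
#' @param gas_mass Drift gas mass (Da; default nitrogen).
#' @return Object of class \code{calibration_model} with elements \code{A},
#'   \code{X}, \code{edc}, \code{gas_mass}, \code{r_squared}, \code{n}.
#' @export
fit_calibration <- function(entries, edc, gas_mass = .mass_n2) {
  req <- c("mass", "charge", "drift_time_ms", "ccs_A2")
  stopifnot(all(req %in% names(entries)))
  if (nrow(entries) < 3L)
    stop("calibration requires at least 3 calibrant entries")
  mz <- entries$mass / entries$charge + .mass_proton
  tdp <- correct_drift_time(entries$drift_time_ms, mz, edc)
  ccs_red <- reduced_ccs(entries$ccs_A2, entries$charge, entries$mass,
                         gas_mass)
  fit <- stats::lm(log(ccs_red) ~ log(tdp))
  y <- log(ccs_red)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(
    list(A = unname(exp(stats::coef(fit)[1])),
         X = unname(stats::coef(fit)[2]),
         edc = edc, gas_mass = gas_mass,
         r_squared = r2,
         n = nrow(entries)),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "TWIMS calibration: CCS' = %.4g * t'd^%.4f  (n = %d, R^2 = %.5f)\n",
    x$A, x$X, x$n, x$r_squared))
  cat(sprintf("  EDC coefficient %.3f, drift gas mass %.5f Da\n",
              x$edc, x$gas_mass))
  invisible(x)
}

#' Convert a drift time to CCS with a fitted calibration
#'
#' \eqn{\Omega = A (t'_d)^X z \sqrt{1/m + 1/m_g}}; exact inverse of the fit
#' construction on noiseless calibrant points.
#'
#' @param model A \code{calibration_model}.
#' @param t_d Measured drift time (ms).
#' @param mz Ion m/z (for the EDC correction).
#' @param z Charge state.
#' @param m Ion mass (Da).
#' @return CCS in A^2.
#' @export
apply_calibration <- function(model, t_d, mz, z, m) {
  stopifnot(inherits(model, "calibration_model"))
  tdp <- correct_drift_time(t_d, mz, model$edc)
  unreduce_ccs(model$A * tdp^model$X, z, m, model$gas_mass)
}

#' Read a calibrant table from delimited text
#'
#' Columns: \code{mass} (Da) or \code{sequence} (from which the monoisotopic
#' mass is computed), \code{charge}, \code{drift_time_ms}, \code{ccs_A2}.
#'
#' @param path File path (tab- or comma-delimited, with header).
#' @return Data frame of calibrant entries.
#' @export
read_calibrants <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  if (!"mass" %in% names(df)) {
    if (!"sequence" %in% names(df))
      stop("calibrant table needs a 'mass' or 'sequence' column")
    df$mass <- vapply(df$sequence, function(s) build_peptide(s)$mass, 0)
  }
  df
}

#' Fit the random-coil CCS trendline
#'
#' Log-log (power-law) regression of CCS on molecular mass over a set of
#' unstructured reference peptides; the prediction at a given mass serves
#' as the random-coil reference CCS.
#'
#' @param points Data frame with columns \code{mass} and \code{ccs}.
#' @return Object of class \code{trendline_model}.
#' @export
fit_trendline <- function(points) {
  stopifnot(all(c("mass", "ccs") %in% names(points)))
  if (nrow(points) < 3L) stop("trendline requires at least 3 points")
  fit <- stats::lm(log(ccs) ~ log(mass), data = points)
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 n = nrow(points)),
            class = "trendline_model")
}

#' Random-coil reference CCS at a given mass
#'
#' @param model A \code{trendline_model}.
#' @param mass Molecular mass (Da).
#' @return Predicted CCS (A^2).
#' @export
predict_trendline <- function(model, mass) {
  stopifnot(inherits(model, "trendline_model"), all(mass > 0))
  exp(model$intercept + model$slope * log(mass))
}

#' Percentage deviation of a CCS from the random-coil trendline
#'
#' \eqn{100 (\Omega - \Omega_{rc}(M)) / \Omega_{rc}(M)}.  Positive values
#' indicate extension relative to a random coil, negative values compaction.
#'
#' @param ccs Measured CCS (A^2).
#' @param mass Molecular mass (Da).
#' @param model A \code{trendline_model}.
#' @return Deviation in percent.
#' @export
delta_to_trendline <- function(ccs, mass, model) {
  ref <- predict_trendline(model, mass)
  100 * (ccs - ref) / ref
}

#' CCS deviation of a modified peptide relative to its unmodified analogue
#'
#' Both arguments are trendline deviations (percent); the value returned is
#' their difference, i.e. how much further from (or closer to) the
#' random-coil line the modified peptide sits than its unmodified
#' counterpart.  A negative value indicates compaction upon modification.
#'
#' @param delta_rc_mod Trendline deviation of the modified peptide (%).
#' @param delta_rc_unmod Trendline deviation of the unmodified peptide (%).
#' @return Deviation difference in percent.
#' @export
delta_to_unmod <- function(delta_rc_mod, delta_rc_unmod) {
  delta_rc_mod - delta_rc_unmod
}

#' Detect conformer peaks in an arrival-time / CCS profile
#'
#' Local maxima above a configurable fraction of the global maximum,
#' enforced to be at least \code{min_spacing} apart on the CCS axis (the
#' taller of two closer peaks wins), returned in decreasing intensity
#' order.
#'
#' @param atd Data frame with columns \code{ccs} (monotone axis) and
#'   \code{intensity}.
#' @param min_frac Minimum peak height as a fraction of the global maximum
#'   (default 0.1).
#' @param min_spacing Minimum CCS separation between reported peaks
#'   (default 5 axis units).
#' @return Data frame with columns \code{ccs} and \code{intensity}, one row
#'   per detected conformer peak, ordered by decreasing intensity.
#' @export
detect_conformers <- function(atd, min_frac = 0.1, min_spacing = 5) {
  stopifnot(all(c("ccs", "intensity") %in% names(atd)))
  if (nrow(atd) == 0L) stop("empty arrival-time profile")
  y <- atd$intensity
  n <- length(y)
  if (n < 3L) {
    i <- which.max(y)
    return(data.frame(ccs = atd$ccs[i], intensity = y[i]))
  }
  thr <- min_frac * max(y)
  is_max <- c(FALSE, y[2:(n - 1)] >= y[1:(n - 2)] &
                y[2:(n - 1)] > y[3:n], FALSE)
  # plateaus and endpoints: allow an endpoint that dominates its neighbour
  is_max[1] <- y[1] > y[2]
  is_max[n] <- y[n] > y[n - 1]
  idx <- which(is_max & y >= thr)
  if (!length(idx)) idx <- which.max(y)
  idx <- idx[order(-y[idx])]
  kept <- integer(0)
  for (i in idx) {
    if (!length(kept) || all(abs(atd$ccs[i] - atd$ccs[kept]) >= min_spacing))
      kept <- c(kept, i)
  }
  data.frame(ccs = atd$ccs[kept], intensity = y[kept])
}
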