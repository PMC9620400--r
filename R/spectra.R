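# hc in eV * nm, used for all wavelength <-> energy conversions
HC_EV_NM <- 1239.842

#' Convert an emission spectrum from wavelength to energy
#'
#' Fluorescence peaks of molecular-like emitters are closer to Gaussian in
#' energy than in wavelength, so all peak fitting is done on an energy axis
#' E = hc / lambda (hc = 1239.842 eV nm).  Samples are reordered so energy
#' increases.  No intensity Jacobian is applied: raw detector counts are
#' fitted against energy (`jacobian = TRUE` applies the lambda^2/hc factor
#' for users who want per-unit-energy spectral density).
#'
#' @param wavelength_nm strictly positive wavelengths, nm.
#' @param intensity detector counts, same length.
#' @param jacobian apply the d(lambda)/dE intensity correction (default
#'   `FALSE`).
#' @return list with `energy_ev` (increasing) and `intensity`.
#' @examples
#' to_energy(c(619.921, 1239.842), c(1, 1))$energy_ev  # 1 eV, 2 eV
#' @export
to_energy <- function(wavelength_nm, intensity, jacobian = FALSE) {
  if (any(!is.finite(wavelength_nm)) || any(wavelength_nm <= 0))
    stop("wavelengths must be positive and finite", call. = FALSE)
  if (length(wavelength_nm) != length(intensity))
    stop("wavelength and intensity lengths differ", call. = FALSE)
  e <- HC_EV_NM / wavelength_nm
  y <- intensity
  if (jacobian) y <- y * wavelength_nm^2 / HC_EV_NM
  o <- order(e)
  list(energy_ev = e[o], intensity = y[o])
}

gaussian_sum <- function(e, pars) {
  # pars: 3k vector (amp, center, sigma) per component
  k <- length(pars) / 3L
  y <- numeric(length(e))
  for (j in seq_len(k)) {
    a <- pars[3L * j - 2L]; c0 <- pars[3L * j - 1L]; s <- pars[3L * j]
    y <- y + a * exp(-(e - c0)^2 / (2 * s^2))
  }
  y
}

# deterministic initial peak guesses: local maxima of the smoothed signal
smooth_peak_guesses <- function(e, y, k) {
  n <- length(y)
  ys <- if (n >= 9L) signal::sgolayfilt(y, p = 3, n = 7) else y
  is_max <- c(FALSE, ys[2:(n - 1)] > ys[1:(n - 2)] &
                     ys[2:(n - 1)] >= ys[3:n], FALSE)
  cand <- which(is_max)
  cand <- cand[order(ys[cand], decreasing = TRUE)]
  if (length(cand) == 0L) cand <- which.max(ys)
  head(cand, k)
}

fit_k_gaussians <- function(e, y, k, start = NULL) {
  span <- diff(range(e))
  sigma0 <- span / (6 * k)
  if (is.null(start)) {
    pk <- smooth_peak_guesses(e, y, k)
    start <- as.vector(rbind(pmax(y[pk], 1e-8 * max(abs(y)) + 1e-300),
                             e[pk], rep(sigma0, length(pk))))
    while (length(start) < 3L * k) {  # fewer maxima than components
      start <- c(start, max(y) / k, stats::median(e), sigma0)
    }
  }
  lower <- rep(c(0, min(e), span / 200), k)
  upper <- rep(c(2 * max(abs(y)) + 1e-300, max(e), span), k)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = pmin(pmax(start, lower), upper),
      lower = lower, upper = upper,
      fn = function(p) y - gaussian_sum(e, p),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(err) NULL)
  if (is.null(fit)) return(NULL)
  list(pars = fit$par, rss = sum(fit$fvec^2))
}

#' Fit an emission spectrum to a sum of one to three Gaussians in energy
#'
#' The spectrum is converted to an energy axis and fitted with k = 1, 2, 3
#' Gaussian components by Levenberg-Marquardt least squares.  Fits are
#' nested: the k-component fit is initialized from the (k-1)-component
#' optimum plus a new component at the largest residual, so the residual sum
#' never increases with k.  The selected k is the smallest for which adding
#' a further component reduces the residual sum by less than
#' `elbow_fraction`.  Components whose amplitude falls below
#' `amp_floor_sigma` times the robust residual noise (MAD) are dropped; a
#' spectrum with no surviving component yields an empty peak set (how Dark
#' wells arise).
#'
#' @param wavelength_nm,intensity the measured spectrum (nm, counts).
#' @param max_components 1, 2 or 3 (default 3).
#' @param elbow_fraction minimum fractional residual-sum reduction required
#'   to accept an extra component (default 0.05).
#' @param amp_floor_sigma amplitude floor in units of robust noise
#'   (default 3).
#' @param well_id optional label carried into the result.
#' @return an object of class `agn_peakset`: data frame of peaks (columns
#'   `lambda_nm`, `energy_ev`, `amplitude`, `sigma_ev`, `area`,
#'   `brightness`), sorted by descending brightness, with attributes
#'   `n_components`, `rss`, `well_id`.  `brightness` equals `area` until
#'   [normalize_brightness()] is applied.
#' @examples
#' wl <- seq(400, 850, by = 2)
#' y <- 100 * exp(-(1239.842 / wl - 1239.842 / 620)^2 / (2 * 0.05^2))
#' fit_peaks(wl, y)
#' @export
fit_peaks <- function(wavelength_nm, intensity, max_components = 3,
                      elbow_fraction = 0.05, amp_floor_sigma = 3,
                      well_id = NA_character_) {
  if (length(wavelength_nm) < 10L)
    stop("spectrum needs at least 10 samples", call. = FALSE)
  if (any(!is.finite(intensity)))
    stop("intensities must be finite", call. = FALSE)
  if (!max_components %in% 1:3)
    stop("max_components must be 1, 2 or 3", call. = FALSE)
  ax <- to_energy(wavelength_nm, intensity)
  e <- ax$energy_ev; y <- ax$intensity

  empty <- empty_peakset(well_id, rss = sum(y^2))
  if (all(y == 0) || max(y) <= 0) return(empty)

  fits <- vector("list", max_components)
  fits[[1L]] <- fit_k_gaussians(e, y, 1L)
  if (is.null(fits[[1L]])) return(empty)
  k_sel <- 1L
  if (max_components > 1L) {
    for (k in 2:max_components) {
      prev <- fits[[k - 1L]]
      resid <- y - gaussian_sum(e, prev$pars)
      new_at <- which.max(resid)
      start <- c(prev$pars, max(resid[new_at], 0) + 1e-12, e[new_at],
                 diff(range(e)) / (6 * k))
      fk <- fit_k_gaussians(e, y, k, start = start)
      if (is.null(fk) || fk$rss > prev$rss) break  # no improvement possible
      fits[[k]] <- fk
      reduction <- (prev$rss - fk$rss) / max(prev$rss, .Machine$double.eps)
      if (reduction < elbow_fraction) break
      k_sel <- k
    }
  }
  best <- fits[[k_sel]]
  pars <- best$pars
  noise <- stats::mad(y - gaussian_sum(e, pars))
  amp <- pars[seq(1L, length(pars), by = 3L)]
  keep <- amp >= amp_floor_sigma * noise & amp > 0
  if (!any(keep)) return(empty)
  idx <- which(keep)
  peaks <- data.frame(
    lambda_nm = HC_EV_NM / pars[3L * idx - 1L],
    energy_ev = pars[3L * idx - 1L],
    amplitude = pars[3L * idx - 2L],
    sigma_ev = pars[3L * idx],
    area = pars[3L * idx - 2L] * pars[3L * idx] * sqrt(2 * pi))
  peaks$brightness <- peaks$area
  peaks <- peaks[order(peaks$brightness, decreasing = TRUE), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(peaks, class = c("agn_peakset", "data.frame"),
            n_components = nrow(peaks), rss = best$rss, well_id = well_id)
}

empty_peakset <- function(well_id = NA_character_, rss = NA_real_) {
  structure(
    data.frame(lambda_nm = numeric(0), energy_ev = numeric(0),
               amplitude = numeric(0), sigma_ev = numeric(0),
               area = numeric(0), brightness = numeric(0)),
    class = c("agn_peakset", "data.frame"),
    n_components = 0L, rss = rss, well_id = well_id)
}

#' @export
print.agn_peakset <- function(x, ...) {
  cat(sprintf("Emission peak set (%d component%s", attr(x, "n_components"),
              if (attr(x, "n_components") == 1L) "" else "s"))
  if (!is.na(attr(x, "well_id"))) cat(", well ", attr(x, "well_id"), sep = "")
  cat(")\n")
  if (nrow(x) > 0L) print.data.frame(x, digits = 4) else cat("  (no peaks)\n")
  invisible(x)
}

#' Normalize peak brightness to a control emitter
#'
#' Divides every peak area by the area of a control nanocluster measured on
#' the same plate, so brightness is comparable across wells and plates.
#'
#' @param peaks an `agn_peakset` from [fit_peaks()].
#' @param control_area positive area of the control's brightest peak.
#' @return the peak set with `brightness = area / control_area`, re-sorted.
#' @export
normalize_brightness <- function(peaks, control_area) {
  if (!is.numeric(control_area) || length(control_area) != 1L ||
      !is.finite(control_area) || control_area <= 0)
    stop("'control_area' must be a single positive number", call. = FALSE)
  peaks$brightness <- peaks$area / control_area
  o <- order(peaks$brightness, decreasing = TRUE)
  at <- attributes(peaks)
  peaks <- peaks[o, , drop = FALSE]
  rownames(peaks) <- NULL
  attributes(peaks) <- utils::modifyList(
    at, list(row.names = attr(peaks, "row.names")))
  peaks
}

#' Fit every well of a plate spectrum table
#'
#' @param plate data frame whose first column is wavelength (nm) and whose
#'   remaining columns are per-well intensities, or a two-column
#'   (wavelength, intensity) frame for a single well.
#' @param ... passed to [fit_peaks()].
#' @return named list of `agn_peakset` objects, one per well column.
#' @export
fit_plate <- function(plate, ...) {
  wl <- plate[[1L]]
  wells <- names(plate)[-1L]
  out <- lapply(wells, function(w) fit_peaks(wl, plate[[w]], well_id = w, ...))
  names(out) <- wells
  out
}

#' Flatten fitted peak sets to a long table
#'
#' @param peaksets named list of `agn_peakset` objects.
#' @return data frame with one row per peak (`well_id`, `lambda_nm`, `area`,
#'   `brightness`, `n_components`); Dark wells contribute no rows.
#' @export
peaks_table <- function(peaksets) {
  rows <- lapply(names(peaksets), function(w) {
    ps <- peaksets[[w]]
    if (nrow(ps) == 0L) return(NULL)
    data.frame(well_id = w, lambda_nm = ps$lambda_nm, area = ps$area,
               brightness = ps$brightness,
               n_components = attr(ps, "n_components"))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
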