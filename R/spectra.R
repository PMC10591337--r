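# Energy grids, Gaussian broadening, relative spectral error, and peak
# location with FWHM windows.

#' Uniform energy grid of bin centers
#'
#' Builds the fixed energy grid onto which stick spectra are broadened and on
#' which all model targets and predictions live.  Grid points are bin centers:
#' `energies[i] = e_min + (i - 0.5) * delta_e` with
#' `delta_e = (e_max - e_min) / n_grid`, so the grid spacing equals the span
#' divided by the number of points.
#'
#' @param e_min,e_max Grid limits in eV; `e_max` must exceed `e_min`.
#' @param n_grid Number of grid points (at least 2).
#' @return An object of class `energy_grid` with fields `e_min`, `e_max`,
#'   `n_grid`, `delta_e` and `energies`.
#' @examples
#' g <- energy_grid(270, 300, 100)
#' g$delta_e        # 0.3 eV
#' range(g$energies)
#' @export
energy_grid <- function(e_min, e_max, n_grid) {
  if (!is.numeric(e_min) || !is.numeric(e_max) || e_max <= e_min)
    stop("`e_max` must be greater than `e_min`", call. = FALSE)
  n_grid <- as.integer(n_grid)
  if (is.na(n_grid) || n_grid < 2L)
    stop("`n_grid` must be an integer >= 2", call. = FALSE)
  delta_e <- (e_max - e_min) / n_grid
  structure(
    list(
      e_min = as.numeric(e_min),
      e_max = as.numeric(e_max),
      n_grid = n_grid,
      delta_e = delta_e,
      energies = e_min + (seq_len(n_grid) - 0.5) * delta_e
    ),
    class = "energy_grid"
  )
}

#' @export
print.energy_grid <- function(x, ...) {
  cat(sprintf("<energy_grid> %d points, %.4g..%.4g eV (delta_e = %.4g eV)\n",
              x$n_grid, x$e_min, x$e_max, x$delta_e))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$e_min, b$e_min)) &&
    isTRUE(all.equal(a$e_max, b$e_max)) &&
    a$n_grid == b$n_grid
}

#' Stick spectrum of discrete transitions
#'
#' A set of discrete (energy, oscillator strength) lines, as produced by an
#' excited-state calculation, before any broadening.
#'
#' @param energies Transition energies in eV (finite).
#' @param osc_strengths Nonnegative oscillator strengths, same length.
#' @param molecule_id Optional identifier carried through the pipeline.
#' @return An object of class `stick_spectrum` with fields `molecule_id`,
#'   `energies` and `osc_strengths`.
#' @export
stick_spectrum <- function(energies, osc_strengths, molecule_id = NA_character_) {
  energies <- as.numeric(energies)
  osc_strengths <- as.numeric(osc_strengths)
  if (length(energies) != length(osc_strengths))
    stop("`energies` and `osc_strengths` must have the same length", call. = FALSE)
  if (length(energies) && any(!is.finite(energies)))
    stop("stick energies must be finite", call. = FALSE)
  if (length(osc_strengths) && any(osc_strengths < 0))
    stop("oscillator strengths must be nonnegative", call. = FALSE)
  structure(
    list(molecule_id = molecule_id, energies = energies,
         osc_strengths = osc_strengths),
    class = "stick_spectrum"
  )
}

#' @export
print.stick_spectrum <- function(x, ...) {
  cat(sprintf("<stick_spectrum> %s: %d sticks\n",
              x$molecule_id, length(x$energies)))
  invisible(x)
}

#' Discretized spectrum on an energy grid
#'
#' @param grid An [energy_grid()].
#' @param intensities Nonnegative intensities, one per grid point
#'   (arbitrary absorption units).
#' @param molecule_id Optional identifier.
#' @return An object of class `grid_spectrum`.
#' @export
grid_spectrum <- function(grid, intensities, molecule_id = NA_character_) {
  stopifnot(inherits(grid, "energy_grid"))
  intensities <- as.numeric(intensities)
  if (length(intensities) != grid$n_grid)
    stop("`intensities` must have one value per grid point", call. = FALSE)
  structure(
    list(molecule_id = molecule_id, grid = grid, intensities = intensities),
    class = "grid_spectrum"
  )
}

# FWHM of a Gaussian = 2*sqrt(2*log(2)) * sigma
FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

#' Broaden a stick spectrum with Gaussians
#'
#' Each stick contributes a Gaussian centered at its energy with peak height
#' equal to its oscillator strength.  `width` is interpreted as the full width
#' at half maximum (FWHM), i.e. `sigma = width / 2.3548`; X-ray absorption
#' broadening conventions vary, so the width is a parameter rather than a
#' constant.  The default 0.8 eV is the conventional carbon K-edge choice.
#'
#' @param sticks A [stick_spectrum()].
#' @param grid An [energy_grid()].
#' @param width Gaussian FWHM in eV (> 0).
#' @return A [grid_spectrum()] whose intensities are
#'   `sum_s f_s * exp(-(E_i - E_s)^2 / (2 sigma^2))`.
#' @examples
#' g <- energy_grid(270, 300, 100)
#' s <- stick_spectrum(285, 1.0)
#' b <- broaden(s, g)
#' g$energies[which.max(b$intensities)]  # close to 285 eV
#' @export
broaden <- function(sticks, grid, width = 0.8) {
  stopifnot(inherits(sticks, "stick_spectrum"), inherits(grid, "energy_grid"))
  if (!is.numeric(width) || width <= 0)
    stop("`width` must be a positive FWHM in eV", call. = FALSE)
  sigma <- width * FWHM_TO_SIGMA
  y <- numeric(grid$n_grid)
  if (length(sticks$energies)) {
    # outer() over (grid point, stick); fine at n_grid ~ 100, sticks ~ dozens
    d <- outer(grid$energies, sticks$energies, "-")
    y <- as.numeric(exp(-d^2 / (2 * sigma^2)) %*% sticks$osc_strengths)
  }
  grid_spectrum(grid, y, molecule_id = sticks$molecule_id)
}

#' Relative spectral error (RSE)
#'
#' RMSE between target and predicted intensities divided by the total
#' spectral energy of the target:
#' `sqrt(sum_i (y_i^tar - y_i^pred)^2 / n_grid) / (sum_i y_i^tar * delta_e)`.
#' The measure is invariant under joint positive rescaling of both spectra
#' and zero iff the spectra are identical.
#'
#' @param target,predicted [grid_spectrum()] objects on the same grid.
#' @return A nonnegative scalar.
#' @export
rse <- function(target, predicted) {
  stopifnot(inherits(target, "grid_spectrum"), inherits(predicted, "grid_spectrum"))
  if (!same_grid(target$grid, predicted$grid))
    stop("target and predicted spectra must share the same grid", call. = FALSE)
  yt <- target$intensities
  yp <- predicted$intensities
  total <- sum(yt) * target$grid$delta_e
  if (total <= 0)
    stop("degenerate target: total spectral energy is zero", call. = FALSE)
  sqrt(mean((yt - yp)^2)) / total
}

#' A spectral peak with its FWHM window
#'
#' @param center_energy Peak center in eV.
#' @param center_index Grid index (1-based) of the peak maximum.
#' @param fwhm Full width at half maximum in eV (> 0).
#' @param window Integer vector of grid indices covered by the FWHM window.
#' @param member_stick_indices Optional indices into a stick spectrum.
#' @return An object of class `peak_region`.
#' @export
peak_region <- function(center_energy, center_index, fwhm, window,
                        member_stick_indices = integer(0)) {
  if (!is.numeric(fwhm) || fwhm <= 0) stop("`fwhm` must be positive", call. = FALSE)
  if (!length(window)) stop("peak window must be non-empty", call. = FALSE)
  if (!(center_index %in% window)) stop("`center_index` must lie in `window`", call. = FALSE)
  structure(
    list(center_energy = center_energy, center_index = as.integer(center_index),
         fwhm = fwhm, window = as.integer(window),
         member_stick_indices = as.integer(member_stick_indices)),
    class = "peak_region"
  )
}

# Half-open FWHM energy window [lo, hi) of a peak.
peak_bounds <- function(peak) {
  c(peak$center_energy - peak$fwhm / 2, peak$center_energy + peak$fwhm / 2)
}

# Prominence of the local maximum at index p: height minus the higher of the
# two valley minima between p and the nearest higher terrain (or grid edge).
.prominence <- function(y, p) {
  n <- length(y)
  left <- if (p == 1L) y[1L] else {
    i <- p - 1L; lo <- y[p]
    while (i >= 1L && y[i] <= y[p]) { lo <- min(lo, y[i]); i <- i - 1L }
    lo
  }
  right <- if (p == n) y[n] else {
    i <- p + 1L; lo <- y[p]
    while (i <= n && y[i] <= y[p]) { lo <- min(lo, y[i]); i <- i + 1L }
    lo
  }
  y[p] - max(left, right)
}

# Linear interpolation of the half-height crossings around peak index p.
.half_crossings <- function(E, y, p) {
  half <- y[p] / 2
  n <- length(y)
  # left crossing
  i <- p
  while (i > 1L && y[i - 1L] >= half && y[i - 1L] <= y[i]) i <- i - 1L
  eL <- if (i == 1L || y[i - 1L] > y[i]) E[max(i - 1L, 1L)] else {
    # y[i-1] < half <= y[i]
    E[i - 1L] + (half - y[i - 1L]) / (y[i] - y[i - 1L]) * (E[i] - E[i - 1L])
  }
  i <- p
  while (i < n && y[i + 1L] >= half && y[i + 1L] <= y[i]) i <- i + 1L
  eR <- if (i == n || y[i + 1L] > y[i]) E[min(i + 1L, n)] else {
    E[i] + (y[i] - half) / (y[i] - y[i + 1L]) * (E[i + 1L] - E[i])
  }
  c(eL, eR)
}

#' Locate peaks and their FWHM windows
#'
#' Finds local maxima whose prominence is at least `prominence_fraction`
#' times the global maximum intensity, estimates each peak's FWHM by linear
#' interpolation of the half-height crossings, and records the grid indices
#' whose energies fall inside the half-open window
#' `[center - fwhm/2, center + fwhm/2)`.  Ties between equal-height
#' neighboring points are broken toward lower energy.
#'
#' @param spec A [grid_spectrum()].
#' @param prominence_fraction Relative prominence threshold in (0, 1);
#'   default 0.05.
#' @return A list of [peak_region()] objects (empty for an all-zero
#'   spectrum).
#' @export
find_peaks <- function(spec, prominence_fraction = 0.05) {
  stopifnot(inherits(spec, "grid_spectrum"))
  if (!is.numeric(prominence_fraction) || prominence_fraction <= 0 ||
      prominence_fraction >= 1)
    stop("`prominence_fraction` must lie in (0, 1)", call. = FALSE)
  y <- spec$intensities
  E <- spec$grid$energies
  n <- length(y)
  ymax <- max(y)
  if (ymax <= 0) return(list())
  # strict rise from the left, non-strict on the right -> plateau ties break
  # toward lower energy
  cand <- which(
    y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf) & y > 0
  )
  out <- list()
  for (p in cand) {
    if (.prominence(y, p) < prominence_fraction * ymax) next
    cr <- .half_crossings(E, y, p)
    fwhm <- max(cr[2] - cr[1], spec$grid$delta_e)  # never degenerate
    lo <- E[p] - fwhm / 2
    hi <- E[p] + fwhm / 2
    window <- which(E >= lo & E < hi)
    window <- sort(unique(c(window, p)))
    out[[length(out) + 1L]] <-
      peak_region(E[p], p, fwhm, window)
  }
  out
}

#' Assign sticks to a peak's FWHM window
#'
#' Returns the indices of sticks whose energy lies in the half-open window
#' `[center - fwhm/2, center + fwhm/2)` of the peak.
#'
#' @param sticks A [stick_spectrum()].
#' @param peak A [peak_region()].
#' @return Integer vector of stick indices (possibly empty).
#' @export
assign_sticks_to_peak <- function(sticks, peak) {
  stopifnot(inherits(sticks, "stick_spectrum"), inherits(peak, "peak_region"))
  b <- peak_bounds(peak)
  which(sticks$energies >= b[1] & sticks$energies < b[2])
}

#' Read / write stick spectra as CSV
#'
#' The on-disk format has columns `molecule_id`, `energy_ev`, `osc_strength`,
#' one row per stick; several molecules may share one file.
#'
#' @param sticks A [stick_spectrum()] or list of them (for writing).
#' @param path File path.
#' @return `read_sticks_csv()` returns a named list of [stick_spectrum()]
#'   objects, one per `molecule_id`.
#' @export
write_sticks_csv <- function(sticks, path) {
  if (inherits(sticks, "stick_spectrum")) sticks <- list(sticks)
  rows <- do.call(rbind, lapply(sticks, function(s) {
    if (!length(s$energies)) return(NULL)
    data.frame(molecule_id = s$molecule_id, energy_ev = s$energies,
               osc_strength = s$osc_strengths)
  }))
  if (is.null(rows))
    rows <- data.frame(molecule_id = character(0), energy_ev = numeric(0),
                       osc_strength = numeric(0))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sticks_csv
#' @export
read_sticks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("molecule_id", "energy_ev", "osc_strength") %in% names(df)))
  ids <- unique(df$molecule_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$molecule_id == id, , drop = FALSE]
    stick_spectrum(sub$energy_ev, sub$osc_strength, molecule_id = id)
  })
  names(out) <- ids
  out
}
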