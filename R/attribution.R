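# Class activation map (CAM) attributions.  Each of the n_out output units is
# treated as an independent class c; the CAM score of atom i for class c is
# the output-layer-weighted sum of that atom's final-layer activations,
#   score[i, c] = sum_k w_k^c F_k(i).
# With sum readout and a bias-free output layer the scores are complete:
# summing over atoms reproduces the prediction exactly.

#' CAM atom attributions for every spectrum point
#'
#' Computes the class activation map of a trained model on one molecule: an
#' `n_atoms x n_out` matrix whose column `c` gives each atom's contribution
#' score for output unit (grid point) `c`.  Negative scores are kept --
#' ROC-AUC ranking only uses score order.  For a mean readout the scores are
#' divided by the atom count so that completeness (atom scores summing to the
#' prediction, up to the output bias) still holds.
#'
#' @param model An `xas_gnn` with the pooling-then-affine head built by
#'   [build_gnn()].
#' @param graph A `molecular_graph`.
#' @return An object of class `atom_attribution` with fields `molecule_id`
#'   and `scores` (`n_atoms x n_out`).
#' @export
cam <- function(model, graph) {
  stopifnot(inherits(model, "xas_gnn"), inherits(graph, "molecular_graph"))
  if (!model$config$readout %in% c("sum", "mean"))
    stop("CAM requires a global pooling readout directly before the output layer",
         call. = FALSE)
  pred <- predict_spectrum(model, graph)
  scores <- pred$activations %*% model$params$Wout
  if (model$config$readout == "mean") scores <- scores / graph$n_atoms
  structure(list(molecule_id = graph$molecule_id, scores = scores),
            class = "atom_attribution")
}

#' @export
print.atom_attribution <- function(x, ...) {
  cat(sprintf("<atom_attribution> %s: %d atoms x %d grid points\n",
              x$molecule_id, nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Aggregate CAM scores over a peak's FWHM window
#'
#' Sums each atom's CAM scores over all grid points inside the peak's FWHM
#' window, producing the single per-atom score vector that is compared with
#' the ground-truth atom labels of that peak.
#'
#' @param attr An [cam()] result.
#' @param peak A [peak_region()] whose window indices lie within the grid.
#' @return Numeric vector of per-atom aggregated scores.
#' @export
aggregate_peak <- function(attr, peak) {
  stopifnot(inherits(attr, "atom_attribution"), inherits(peak, "peak_region"))
  n_grid <- ncol(attr$scores)
  if (any(peak$window < 1L) || any(peak$window > n_grid))
    stop("peak window lies outside the attribution grid", call. = FALSE)
  rowSums(attr$scores[, peak$window, drop = FALSE])
}

#' Export an attribution matrix as CSV
#'
#' Writes one row per atom with columns named by grid energy.
#'
#' @param attr An `atom_attribution`.
#' @param grid The [energy_grid()] naming the columns.
#' @param path File path.
#' @export
write_attribution_csv <- function(attr, grid, path) {
  stopifnot(inherits(attr, "atom_attribution"), inherits(grid, "energy_grid"))
  df <- as.data.frame(attr$scores)
  names(df) <- sprintf("e_%.3f", grid$energies)
  df <- cbind(atom = seq_len(nrow(df)), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
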