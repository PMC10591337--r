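# Explanation scoring: ROC-AUC of CAM scores against ground-truth atom
# labels, per peak and per orbital channel, with aggregation over peaks and
# molecules, an RSE-decile profile, and percentage AUC change under
# perturbation.

#' ROC-AUC of attribution scores against binary labels
#'
#' Computed as the Mann-Whitney rank statistic
#' `P(score_pos > score_neg) + 0.5 * P(tie)`, the probability that a randomly
#' chosen positive atom outranks a randomly chosen negative one (ties get
#' half credit, equivalent to the trapezoidal ROC area).  Atom score vectors
#' are short and ties are common, hence the explicit convention.
#'
#' @param scores Numeric per-atom scores.
#' @param labels 0/1 per-atom labels with at least one of each class.
#' @return AUC in `[0, 1]`, or `NA_real_` when the labels are single-class
#'   (such peaks are excluded from averages and counted in reports).
#' @export
auc_roc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)  # average ranks implement the half-credit tie rule
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Explain one molecule peak by peak
#'
#' The complete single-molecule explainability workflow: broaden the
#' reference sticks onto the grid, detect peaks on that reference spectrum
#' (peaks are referenced to the quantum-chemistry curve, not the model
#' prediction), compute the model's CAM attribution, aggregate it over each
#' peak's FWHM window, derive the ground-truth atom labels for both orbital
#' channels and score each channel with ROC-AUC.
#'
#' @param model A trained `xas_gnn`.
#' @param graph The molecule's `molecular_graph`.
#' @param sticks Its [stick_spectrum()].
#' @param transitions Its [transition_record()]s, parallel to the sticks.
#' @param grid The [energy_grid()].
#' @param theta Label binarization threshold (see [binarize()]).
#' @param width Gaussian FWHM used for the reference broadening (eV).
#' @param prominence_fraction Peak detection threshold, see [find_peaks()].
#' @param attribution Optional `n_atoms x n_grid` score matrix overriding the
#'   model's CAM (used e.g. to score an oracle or random attribution); when
#'   given, `model` may be `NULL`.
#' @return List of `peak_explanation` objects, each with `peak`,
#'   `cam_peak_scores`, `labels`, `auc_core` and `auc_virtual`.
#' @export
explain_molecule <- function(model, graph, sticks, transitions, grid,
                             theta = 0.1, width = 0.8,
                             prominence_fraction = 0.05,
                             attribution = NULL) {
  stopifnot(inherits(graph, "molecular_graph"))
  target <- broaden(sticks, grid, width)
  peaks <- find_peaks(target, prominence_fraction)
  if (!length(peaks)) return(list())
  scores <- if (!is.null(attribution)) {
    stopifnot(nrow(attribution) == graph$n_atoms,
              ncol(attribution) == grid$n_grid)
    structure(list(molecule_id = graph$molecule_id, scores = attribution),
              class = "atom_attribution")
  } else {
    cam(model, graph)
  }
  out <- list()
  for (pk in peaks) {
    if (!length(assign_sticks_to_peak(sticks, pk))) next
    labels <- labels_for_peak(sticks, transitions, pk, graph$n_atoms, theta)
    agg <- aggregate_peak(scores, pk)
    out[[length(out) + 1L]] <- structure(
      list(molecule_id = graph$molecule_id, peak = pk,
           cam_peak_scores = agg, labels = labels,
           auc_core = auc_roc(agg, labels$core_labels),
           auc_virtual = auc_roc(agg, labels$virtual_labels)),
      class = "peak_explanation"
    )
  }
  out
}

#' Aggregate peak explanations over a dataset
#'
#' Averages per-peak AUC values per molecule (defined AUCs only; single-class
#' peaks are counted, not imputed) and summarizes the distribution over
#' molecules, together with each molecule's RSE when predictions are
#' available.
#'
#' @param explanations List (one element per molecule) of lists of
#'   `peak_explanation` objects, as returned by [explain_molecule()].
#' @param rse_values Optional per-molecule RSE vector, parallel to
#'   `explanations`.
#' @return An `explain_report`: data frame `per_molecule` (columns
#'   `molecule_id`, `mean_auc_core`, `mean_auc_virtual`, `n_peaks`,
#'   `n_undefined_core`, `n_undefined_virtual`, `rse`), plus overall channel
#'   means and quartile summaries.
#' @export
explain_report <- function(explanations, rse_values = NULL) {
  rows <- lapply(seq_along(explanations), function(i) {
    ex <- explanations[[i]]
    ac <- vapply(ex, `[[`, numeric(1), "auc_core")
    av <- vapply(ex, `[[`, numeric(1), "auc_virtual")
    data.frame(
      molecule_id = if (length(ex)) ex[[1]]$molecule_id else NA_character_,
      mean_auc_core = if (any(!is.na(ac))) mean(ac, na.rm = TRUE) else NA_real_,
      mean_auc_virtual = if (any(!is.na(av))) mean(av, na.rm = TRUE) else NA_real_,
      n_peaks = length(ex),
      n_undefined_core = sum(is.na(ac)),
      n_undefined_virtual = sum(is.na(av)),
      rse = if (!is.null(rse_values)) rse_values[i] else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  per_mol <- do.call(rbind, rows)
  q <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(q1 = NA_real_, median = NA_real_, q3 = NA_real_))
    stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE) |>
      stats::setNames(c("q1", "median", "q3"))
  }
  structure(
    list(per_molecule = per_mol,
         mean_auc_core = mean(per_mol$mean_auc_core, na.rm = TRUE),
         mean_auc_virtual = mean(per_mol$mean_auc_virtual, na.rm = TRUE),
         summary_core = q(per_mol$mean_auc_core),
         summary_virtual = q(per_mol$mean_auc_virtual),
         mean_rse = if (!is.null(rse_values)) mean(rse_values) else NA_real_),
    class = "explain_report"
  )
}

#' @export
print.explain_report <- function(x, ...) {
  cat(sprintf(
    "<explain_report> %d molecules | mean AUC core %.3f, virtual %.3f%s\n",
    nrow(x$per_molecule), x$mean_auc_core, x$mean_auc_virtual,
    if (!is.na(x$mean_rse)) sprintf(" | mean RSE %.4f", x$mean_rse) else ""))
  invisible(x)
}

#' Attribution AUC by RSE decile
#'
#' Sorts molecules by RSE (ascending), splits them into 10 equal-size groups
#' (any remainder spread one-per-bin over the first bins) and averages the
#' AUC within each group, profiling how explanation quality degrades as
#' prediction quality does.
#'
#' @param rse_values Per-molecule RSE.
#' @param auc_values Per-molecule mean AUC, parallel to `rse_values`.
#' @return Data frame with columns `decile`, `n`, `mean_rse`, `mean_auc`.
#' @export
rse_decile_profile <- function(rse_values, auc_values) {
  stopifnot(length(rse_values) == length(auc_values))
  n <- length(rse_values)
  if (n < 10L) stop("at least 10 molecules are required", call. = FALSE)
  ord <- order(rse_values)
  base <- n %/% 10L
  extra <- n %% 10L
  sizes <- rep(base, 10L) + c(rep(1L, extra), rep(0L, 10L - extra))
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-10L] + 1L)
  do.call(rbind, lapply(1:10, function(d) {
    idx <- ord[starts[d]:ends[d]]
    data.frame(decile = d, n = sizes[d],
               mean_rse = mean(rse_values[idx]),
               mean_auc = mean(auc_values[idx], na.rm = TRUE))
  }))
}

#' Percentage AUC change under perturbation
#'
#' `100 * (mean_after - mean_before) / mean_before` per orbital channel,
#' comparing explanation reports over paired molecule sets (e.g. before and
#' after methyl addition).
#'
#' @param before,after `explain_report` objects.
#' @return Named numeric vector with elements `core` and `virtual`, in
#'   percent.
#' @export
delta_auc <- function(before, after) {
  stopifnot(inherits(before, "explain_report"), inherits(after, "explain_report"))
  pct <- function(b, a) {
    if (!is.finite(b) || b == 0)
      stop("baseline mean AUC is zero or undefined", call. = FALSE)
    100 * (a - b) / b
  }
  c(core = pct(before$mean_auc_core, after$mean_auc_core),
    virtual = pct(before$mean_auc_virtual, after$mean_auc_virtual))
}
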