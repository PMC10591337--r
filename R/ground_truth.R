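# Ground-truth atom labels from excited-state transition records.
#
# Each X-ray transition is a core -> virtual orbital excitation with an
# oscillator strength and per-atom populations of the orbitals involved.  For
# a spectral peak, an atom's contribution weight in a channel (core or
# virtual) is the oscillator-strength- and pair-weight-weighted sum of its
# orbital populations over the peak's member transitions; weights are then
# max-normalized and thresholded into binary labels.

#' An excited-state transition record
#'
#' @param state_id Unique identifier of the excited state.
#' @param energy Excitation energy in eV.
#' @param osc_strength Nonnegative oscillator strength.
#' @param pairs List of orbital pairs, each a list with `core_mo`,
#'   `virtual_mo` (MO identifiers) and `weight` (nonnegative); pair weights
#'   are normalized to sum to 1.
#' @param mo_populations Named list mapping each referenced MO identifier to
#'   a numeric vector of per-atom population shares (summing to 1 over atoms,
#'   tolerance 1e-6; renormalized with a warning beyond that).
#' @return An object of class `transition_record`.
#' @export
transition_record <- function(state_id, energy, osc_strength, pairs,
                              mo_populations) {
  if (osc_strength < 0) stop("oscillator strength must be nonnegative", call. = FALSE)
  if (!length(pairs)) stop("a transition needs at least one orbital pair", call. = FALSE)
  w <- vapply(pairs, function(p) as.numeric(p$weight), numeric(1))
  if (any(w < 0)) stop("pair weights must be nonnegative", call. = FALSE)
  if (sum(w) <= 0) stop("pair weights must not all be zero", call. = FALSE)
  w <- w / sum(w)
  pairs <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    list(core_mo = as.character(p$core_mo),
         virtual_mo = as.character(p$virtual_mo), weight = w[i])
  })
  mo_populations <- lapply(mo_populations, function(pop) {
    pop <- as.numeric(pop)
    s <- sum(pop)
    if (s <= 0) stop("an orbital population must have positive total", call. = FALSE)
    if (abs(s - 1) > 1e-6)
      warning(sprintf("orbital population sums to %.8f; renormalizing", s))
    pop / s
  })
  structure(
    list(state_id = as.character(state_id), energy = as.numeric(energy),
         osc_strength = as.numeric(osc_strength), pairs = pairs,
         mo_populations = mo_populations),
    class = "transition_record"
  )
}

#' Per-atom contribution weights for one orbital channel
#'
#' For each atom `a`:
#' `weight(a) = sum_s f_s * sum_pairs pair_weight * population_a(MO)`,
#' where the MO is the pair's core or virtual orbital depending on `channel`.
#' Weights are normalized so the largest equals 1 (when any is positive).
#'
#' @param transitions Non-empty list of [transition_record()]s.
#' @param channel `"core"` or `"virtual"`.
#' @param n_atoms Number of atoms in the molecule.
#' @return Numeric vector of length `n_atoms`, max-normalized.
#' @export
atom_weights <- function(transitions, channel = c("core", "virtual"), n_atoms) {
  channel <- match.arg(channel)
  if (!length(transitions)) stop("`transitions` must be non-empty", call. = FALSE)
  mo_field <- if (channel == "core") "core_mo" else "virtual_mo"
  w <- numeric(n_atoms)
  for (tr in transitions) {
    for (p in tr$pairs) {
      mo <- p[[mo_field]]
      pop <- tr$mo_populations[[mo]]
      if (is.null(pop))
        stop(sprintf("population missing for orbital '%s'", mo), call. = FALSE)
      if (length(pop) != n_atoms)
        stop(sprintf("population for orbital '%s' has %d atoms, expected %d",
                     mo, length(pop), n_atoms), call. = FALSE)
      w <- w + tr$osc_strength * p$weight * pop
    }
  }
  if (max(w) > 0) w <- w / max(w)
  w
}

#' Binarize contribution weights into atom labels
#'
#' An atom is labeled 1 iff its weight is at least `theta` times the maximum
#' weight (boundary inclusive); all-zero weights give all-zero labels.  The
#' relative threshold is scale-free, so labels are invariant under a common
#' rescaling of all oscillator strengths.
#'
#' @param weights Nonnegative per-atom weights.
#' @param theta Relative threshold in (0, 1); default 0.1.
#' @return Integer vector of 0/1 labels.
#' @export
binarize <- function(weights, theta = 0.1) {
  if (!is.numeric(theta) || theta <= 0 || theta >= 1)
    stop("`theta` must lie in (0, 1)", call. = FALSE)
  mx <- max(weights)
  if (mx <= 0) return(integer(length(weights)))
  as.integer(weights >= theta * mx)
}

#' Ground-truth labels for one spectral peak
#'
#' Composes the full labeling pipeline: sticks inside the peak's FWHM window
#' are matched to their transition records by `state_id`, per-atom weights
#' are computed for the core and virtual channels, and both are binarized
#' with [binarize()].
#'
#' @param sticks The molecule's [stick_spectrum()]; stick `i` corresponds to
#'   `transitions[[i]]`'s state.
#' @param transitions List of [transition_record()]s, parallel to the sticks
#'   (matched by `state_id` when stick order differs).
#' @param peak A [peak_region()].
#' @param n_atoms Atom count of the molecule.
#' @param theta Binarization threshold, see [binarize()].
#' @return An object of class `ground_truth_labels` with `peak`,
#'   `core_weights`, `virtual_weights`, `core_labels`, `virtual_labels` and
#'   `member_state_ids`.
#' @export
labels_for_peak <- function(sticks, transitions, peak, n_atoms, theta = 0.1) {
  stopifnot(inherits(sticks, "stick_spectrum"), inherits(peak, "peak_region"))
  member <- assign_sticks_to_peak(sticks, peak)
  if (!length(member))
    stop("peak contains no transitions (empty peak)", call. = FALSE)
  trs <- transitions[member]
  cw <- atom_weights(trs, "core", n_atoms)
  vw <- atom_weights(trs, "virtual", n_atoms)
  structure(
    list(molecule_id = sticks$molecule_id, peak = peak,
         core_weights = cw, virtual_weights = vw,
         core_labels = binarize(cw, theta),
         virtual_labels = binarize(vw, theta),
         member_state_ids = vapply(trs, `[[`, "", "state_id")),
    class = "ground_truth_labels"
  )
}

# ---- JSON-lines interchange -------------------------------------------------
# One transition per line:
# {"state_id": "...", "energy": 285.1, "osc_strength": 0.03,
#  "pairs": [{"core_mo": "c1", "virtual_mo": "v1", "weight": 1}],
#  "mo_populations": {"c1": [0.9, 0.1], "v1": [0.5, 0.5]}}
# This is the package's canonical interchange with any quantum-chemistry
# backend; converting e.g. an ORCA TDDFT output means emitting one such line
# per core-excited state, with populations from any per-atom orbital
# decomposition (Loewdin, Mulliken, ...).  The electronic-structure side is
# out of scope here.

#' Write / read transition records as JSON lines
#'
#' @param transitions List of [transition_record()]s.
#' @param path File path.
#' @return `read_transitions_jsonl()` returns a list of
#'   [transition_record()]s.
#' @export
write_transitions_jsonl <- function(transitions, path) {
  lines <- vapply(transitions, function(tr) {
    jsonlite::toJSON(list(
      state_id = tr$state_id, energy = tr$energy,
      osc_strength = tr$osc_strength,
      pairs = lapply(tr$pairs, function(p)
        list(core_mo = p$core_mo, virtual_mo = p$virtual_mo,
             weight = p$weight)),
      mo_populations = tr$mo_populations
    ), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_transitions_jsonl
#' @export
read_transitions_jsonl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    transition_record(
      state_id = x$state_id, energy = x$energy,
      osc_strength = x$osc_strength,
      pairs = x$pairs,
      mo_populations = lapply(x$mo_populations, unlist)
    )
  })
}
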