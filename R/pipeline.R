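# Workflow orchestration: dataset (de)serialization, the end-to-end
# generate -> train -> explain -> evaluate pipeline, and run manifests.
# Datasets live in a plain-text directory (SMILES list, CSV sticks/spectra,
# JSON-lines transitions, JSON grid metadata) so runs are diffable.

#' Write / read a dataset directory
#'
#' Layout: `grid.json` (grid metadata and broadening width), `molecules.smi`
#' (SMILES, tab, id), `sticks.csv`, `spectra.csv` (one row per molecule:
#' `molecule_id` then one column per grid point) and `transitions.jsonl`
#' (each line one transition, tagged with its `molecule_id`).
#'
#' @param dataset List of entries as produced by [generate_dataset()].
#' @param dir Target directory (created if missing).
#' @param width Broadening FWHM recorded in the metadata.
#' @return `read_dataset()` returns the reconstructed entry list (graphs are
#'   rebuilt from the SMILES; planted labels are not persisted).
#' @export
write_dataset <- function(dataset, dir, width = 0.8) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- dataset[[1]]$spectrum$grid
  jsonlite::write_json(
    list(e_min = grid$e_min, e_max = grid$e_max, n_grid = grid$n_grid,
         width = width),
    file.path(dir, "grid.json"), auto_unbox = TRUE, digits = NA)
  writeLines(sprintf("%s\t%s",
                     vapply(dataset, `[[`, "", "smiles"),
                     vapply(dataset, `[[`, "", "molecule_id")),
             file.path(dir, "molecules.smi"))
  write_sticks_csv(lapply(dataset, `[[`, "sticks"),
                   file.path(dir, "sticks.csv"))
  spectra <- do.call(rbind, lapply(dataset, function(e) e$spectrum$intensities))
  df <- data.frame(molecule_id = vapply(dataset, `[[`, "", "molecule_id"),
                   spectra, check.names = FALSE)
  names(df)[-1] <- sprintf("i_%03d", seq_len(grid$n_grid))
  utils::write.csv(df, file.path(dir, "spectra.csv"), row.names = FALSE)
  con <- file(file.path(dir, "transitions.jsonl"), "w")
  on.exit(close(con))
  for (e in dataset) {
    for (tr in e$transitions) {
      writeLines(jsonlite::toJSON(list(
        molecule_id = e$molecule_id, state_id = tr$state_id,
        energy = tr$energy, osc_strength = tr$osc_strength,
        pairs = lapply(tr$pairs, function(p)
          list(core_mo = p$core_mo, virtual_mo = p$virtual_mo,
               weight = p$weight)),
        mo_populations = tr$mo_populations), auto_unbox = TRUE, digits = NA),
        con)
    }
  }
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "grid.json"), simplifyVector = TRUE)
  grid <- energy_grid(meta$e_min, meta$e_max, meta$n_grid)
  mols <- read_smiles_file(file.path(dir, "molecules.smi"))
  sticks <- read_sticks_csv(file.path(dir, "sticks.csv"))
  spectra <- utils::read.csv(file.path(dir, "spectra.csv"),
                             stringsAsFactors = FALSE, check.names = FALSE)
  trs <- list()
  for (ln in readLines(file.path(dir, "transitions.jsonl"))) {
    if (!nzchar(trimws(ln))) next
    x <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    rec <- transition_record(x$state_id, x$energy, x$osc_strength, x$pairs,
                             lapply(x$mo_populations, unlist))
    trs[[x$molecule_id]] <- c(trs[[x$molecule_id]], list(rec))
  }
  lapply(seq_len(nrow(mols)), function(i) {
    id <- mols$molecule_id[i]
    row <- spectra[spectra$molecule_id == id, -1, drop = FALSE]
    list(molecule_id = id, smiles = mols$smiles[i],
         graph = build_graph(mols$smiles[i], molecule_id = id),
         sticks = sticks[[id]],
         transitions = trs[[id]],
         spectrum = grid_spectrum(grid, as.numeric(row[1, ]),
                                  molecule_id = id))
  })
}

#' Explain every molecule of a dataset with a trained model
#'
#' Runs [explain_molecule()] on each entry, computes each molecule's RSE
#' between its reference spectrum and the model prediction, and aggregates
#' everything with [explain_report()].
#'
#' @param model A trained `xas_gnn`.
#' @param dataset Entry list (fields `graph`, `sticks`, `transitions`,
#'   `spectrum`).
#' @param theta,width,prominence_fraction Passed to [explain_molecule()].
#' @return An `explain_report`; the underlying per-molecule explanation
#'   lists are attached as attribute `explanations`.
#' @export
explain_dataset <- function(model, dataset, theta = 0.1, width = 0.8,
                            prominence_fraction = 0.05) {
  grid <- dataset[[1]]$spectrum$grid
  explanations <- vector("list", length(dataset))
  rses <- numeric(length(dataset))
  for (i in seq_along(dataset)) {
    e <- dataset[[i]]
    pred <- predict_spectrum(model, e$graph)
    rses[i] <- rse(e$spectrum,
                   grid_spectrum(grid, pmax(pred$intensities, 0)))
    explanations[[i]] <- explain_molecule(model, e$graph, e$sticks,
                                          e$transitions, grid, theta = theta,
                                          width = width,
                                          prominence_fraction = prominence_fraction)
  }
  rep <- explain_report(explanations, rses)
  attr(rep, "explanations") <- explanations
  rep
}

.default_workflow_config <- function() {
  list(
    seed = 1L,
    out_dir = "xascam_run",
    grid = list(e_min = 270, e_max = 300, n_grid = 100L, width = 0.8),
    data = list(n_molecules = 100L),
    model = list(architecture = "gatv2", hidden_sizes = c(32L, 64L),
                 n_heads = 4L, readout = "sum"),
    train = list(epochs = 200L, lr = 1e-3, lr_decay = 0.8,
                 decay_every = 100L, batch_size = 100L, val_fraction = 0.2,
                 val_check_every = 50L),
    theta = 0.1,
    prominence_fraction = 0.05
  )
}

.merge_config <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]]))
      .merge_config(base[[nm]], user[[nm]]) else user[[nm]]
  }
  base
}

.validate_workflow_config <- function(cfg) {
  bad <- character(0)
  if (!is.numeric(cfg$seed)) bad <- c(bad, "seed")
  with_grid <- cfg$grid
  if (!is.numeric(with_grid$e_min) || !is.numeric(with_grid$e_max) ||
      with_grid$e_max <= with_grid$e_min) bad <- c(bad, "grid.e_min/e_max")
  if (!is.numeric(with_grid$n_grid) || with_grid$n_grid < 2) bad <- c(bad, "grid.n_grid")
  if (!is.numeric(with_grid$width) || with_grid$width <= 0) bad <- c(bad, "grid.width")
  if (!cfg$model$architecture %in% c("gcn", "graphnet", "gatv2"))
    bad <- c(bad, "model.architecture")
  if (!is.numeric(cfg$theta) || cfg$theta <= 0 || cfg$theta >= 1)
    bad <- c(bad, "theta")
  if (length(bad))
    stop("invalid workflow configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(cfg)
}

#' Run the full synthetic explainability workflow
#'
#' Generate a synthetic dataset, train a GNN, explain every molecule, and
#' evaluate attribution AUC -- writing the dataset directory, the model
#' checkpoint, the training metrics log, the evaluation report and a run
#' manifest (config hash, seeds, package version) under `out_dir`.  The run
#' is deterministic given the configured seeds.
#'
#' @param config Path to a YAML configuration file, or a configuration list.
#'   Unset keys fall back to defaults (GATv2 small profile, 100 molecules,
#'   200 epochs, 270-300 eV / 100-point grid, 0.8 eV broadening,
#'   `theta = 0.1`).
#' @return Invisibly, a list with `out_dir`, `report`, `fit` and `config`.
#' @export
run_workflow <- function(config = list()) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    config <- yaml::read_yaml(config)
  }
  cfg <- .validate_workflow_config(.merge_config(.default_workflow_config(),
                                                 config))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- energy_grid(cfg$grid$e_min, cfg$grid$e_max, cfg$grid$n_grid)

  message(sprintf("[generate] %d synthetic molecules (seed %d)",
                  cfg$data$n_molecules, cfg$seed))
  dataset <- generate_dataset(cfg$data$n_molecules, seed = cfg$seed,
                              grid = grid, width = cfg$grid$width)
  write_dataset(dataset, file.path(cfg$out_dir, "dataset"),
                width = cfg$grid$width)

  mcfg <- model_config(architecture = cfg$model$architecture,
                       hidden_sizes = cfg$model$hidden_sizes,
                       n_out = grid$n_grid,
                       n_heads = cfg$model$n_heads,
                       readout = cfg$model$readout,
                       seed = cfg$seed)
  tcfg <- do.call(train_config, c(cfg$train, list(seed = cfg$seed)))
  message(sprintf("[train] %s for %d epochs on %d molecules",
                  mcfg$architecture, tcfg$epochs, length(dataset)))
  fit <- train_gnn(build_gnn(mcfg, grid), dataset, tcfg)
  save_checkpoint(fit$model, file.path(cfg$out_dir, "checkpoint.json"))
  utils::write.csv(fit$history, file.path(cfg$out_dir, "metrics.csv"),
                   row.names = FALSE)

  message("[explain] scoring CAM attributions against ground truth")
  report <- explain_dataset(fit$model, dataset, theta = cfg$theta,
                            width = cfg$grid$width,
                            prominence_fraction = cfg$prominence_fraction)
  jsonlite::write_json(
    list(mean_auc_core = report$mean_auc_core,
         mean_auc_virtual = report$mean_auc_virtual,
         summary_core = as.list(report$summary_core),
         summary_virtual = as.list(report$summary_virtual),
         mean_rse = report$mean_rse,
         best_val_rmse = fit$best_val_rmse,
         best_val_rse = fit$best_val_rse),
    file.path(cfg$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$per_molecule,
                   file.path(cfg$out_dir, "report_per_molecule.csv"),
                   row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("xascam")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    config = cfg,
    config_md5 = if (!is.null(cfg_path)) unname(tools::md5sum(cfg_path))
                 else NA_character_,
    n_molecules = length(dataset),
    n_transitions = sum(vapply(dataset, function(e) length(e$transitions), 1L))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  message(sprintf("[done] mean AUC core %.3f, virtual %.3f, mean RSE %.4f",
                  report$mean_auc_core, report$mean_auc_virtual,
                  report$mean_rse))
  invisible(list(out_dir = cfg$out_dir, report = report, fit = fit,
                 config = cfg))
}
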