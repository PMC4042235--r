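# End-to-end orchestration: align -> fields -> filter -> split/unicolumn ->
# select -> fit -> validate -> (optionally) pharmacophore -> screen, with all
# artifacts written to disk and a manifest that makes the run reproducible.

#' Pipeline configuration
#'
#' Defaults follow the method's canonical settings: constant dielectric
#' 1.0, at most 4 descriptors in the final equation, descriptor variance
#' cutoff 0.1, at most 5 pharmacophore sites.
#'
#' @param input list with `sdf` or `smiles` plus `activities` file paths,
#'   or NULL when `synthetic` is given.
#' @param synthetic list of arguments for [generate_congeneric_series()],
#'   or NULL.
#' @param template scaffold substructure (SMILES) for alignment; NULL skips
#'   re-alignment (synthetic input arrives aligned).
#' @param rmsd_cutoff congener-selection cutoff (angstrom).
#' @param grid list(margin, spacing).
#' @param probe [probe_params()].
#' @param variance_cutoff invariable-column threshold.
#' @param split list with `test_ids` (manual selection) or `n_test` for the
#'   automated interpolative split.
#' @param model list(max_descriptors, max_components).
#' @param randomization list(n_permutations, seed); 0 permutations skips.
#' @param pharmacophore list(enabled, max_sites, distance_bin, n_active);
#'   the `n_active` most active training compounds form the active set.
#' @param screening list(library_sdf, external_scores, top_n, tolerance);
#'   NULL library skips screening.
#' @param seed master seed.
#' @param output_dir artifact directory.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL, template = NULL,
                            rmsd_cutoff = 1.0,
                            grid = list(margin = 5, spacing = 2),
                            probe = probe_params(),
                            variance_cutoff = 0.1,
                            split = list(test_ids = NULL, n_test = 5),
                            model = list(max_descriptors = 4, max_components = 4),
                            randomization = list(n_permutations = 100, seed = NULL),
                            pharmacophore = list(enabled = FALSE, max_sites = 5,
                                                 distance_bin = 1.0, n_active = NULL),
                            screening = list(library_sdf = NULL,
                                             external_scores = NULL,
                                             top_n = 10, tolerance = 2.0),
                            seed = 42L, output_dir = tempfile("fieldqsar_run")) {
  cfg <- list(input = input, synthetic = synthetic, template = template,
              rmsd_cutoff = rmsd_cutoff, grid = grid, probe = probe,
              variance_cutoff = variance_cutoff, split = split, model = model,
              randomization = randomization, pharmacophore = pharmacophore,
              screening = screening, seed = as.integer(seed),
              output_dir = output_dir)
  if (is.null(cfg$randomization$seed)) cfg$randomization$seed <- cfg$seed
  if (is.null(cfg$input) && is.null(cfg$synthetic))
    stop("config needs either 'input' files or a 'synthetic' generator spec")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys override the defaults of [pipeline_config()]. Note the
#' YAML 1.1 convention: bare keys `y`/`n`/`yes`/`no` parse as booleans, so
#' quote them (e.g. `"n": 33`).
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full workflow
#'
#' Executes alignment, field computation, filtering, splitting with
#' unicolumn statistics, stepwise-forward selection, PLS fitting,
#' validation (with Y-randomization), and optionally pharmacophore
#' enumeration and library screening. All tables and a manifest (config,
#' seeds, md5 of numeric outputs) are written under `output_dir`.
#'
#' @param config [pipeline_config()] or path to a YAML file.
#' @return list with the fitted model, validation report, split,
#'   descriptor matrix, hypotheses and screening hits (invisible).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$synthetic)) {
    series <- stage("synthetic", do.call(generate_congeneric_series,
                                         c(config$synthetic, list(seed = config$seed))))
    mols <- series$molecules
    filt <- series$matrix
    grid <- series$grid
    stage("write-series", write_series(series, file.path(out_dir, "series")))
  } else {
    inp <- config$input
    mols <- stage("read-structures",
                  if (!is.null(inp$sdf)) read_molecules(inp$sdf, "sdf")
                  else read_molecules(inp$smiles, "smiles", seed = config$seed))
    acts <- stage("read-activities", read_activities(inp$activities))
    mols <- stage("charges", lapply(mols, function(m)
      if (length(m$charges)) m else assign_peoe_charges(m)))
    if (!is.null(config$template)) {
      ref <- mols[[which.max(acts$pic50[match(vapply(mols, `[[`, "", "id"),
                                              acts$compound_id)])]]
      al <- stage("align", select_congeners(mols, config$template, ref,
                                            config$rmsd_cutoff))
      mols <- lapply(al, `[[`, "molecule")
    }
    grid <- stage("grid", build_grid(mols, config$grid$margin, config$grid$spacing))
    full <- stage("fields", assemble_descriptor_matrix(mols, acts, grid,
                                                       config$probe))
    filt <- stage("filter", filter_invariant_columns(full, config$variance_cutoff))
  }
  stage("write-descriptors", write_descriptor_csv(filt, file.path(out_dir, "descriptors.csv")))
  write_grid_json(grid, file.path(out_dir, "grid.json"))

  split <- stage("split",
                 if (!is.null(config$split$test_ids))
                   split_spec(setdiff(filt$compound_ids, config$split$test_ids),
                              config$split$test_ids)
                 else activity_ranked_split(filt, config$split$n_test))
  uni <- unicolumn_report(filt, split)
  utils::write.csv(uni, file.path(out_dir, "unicolumn.csv"), row.names = FALSE)
  interp <- check_split_interpolative(filt$activities[split$train_ids],
                                      filt$activities[split$test_ids])
  if (!interp) warning("test set is not interpolative: ",
                       paste(attr(interp, "messages"), collapse = "; "))

  selected <- stage("select", stepwise_forward_select(filt, split,
                                                      config$model$max_descriptors))
  model <- stage("fit", fit_pls(filt, split, selected,
                                config$model$max_components))
  write_model_json(model, file.path(out_dir, "model.json"))
  contrib <- contribution_percentages(model, filt, split)
  utils::write.csv(data.frame(descriptor = names(contrib),
                              contribution_percent = unname(contrib)),
                   file.path(out_dir, "contributions.csv"), row.names = FALSE)

  report <- stage("validate", validate_model(
    filt, split, model,
    n_permutations = config$randomization$n_permutations,
    seed = config$randomization$seed))
  write_validation_report(report, file.path(out_dir, "validation.json"),
                          file.path(out_dir, "randomization.csv"))

  hypotheses <- NULL; hyp_scores <- NULL; hits <- NULL
  if (isTRUE(config$pharmacophore$enabled)) {
    ph <- config$pharmacophore
    n_active <- if (is.null(ph$n_active)) length(split$train_ids) else ph$n_active
    ids <- names(sort(filt$activities[split$train_ids], decreasing = TRUE))
    act_ids <- utils::head(ids, n_active)
    actives <- mols[match(act_ids, vapply(mols, `[[`, "", "id"))]
    hypotheses <- stage("pharmacophore",
                        enumerate_hypotheses(actives, ph$max_sites, ph$distance_bin))
    if (length(hypotheses) > 0) {
      hyp_scores <- lapply(hypotheses, score_hypothesis, actives = actives)
      ord <- rank_hypotheses(hyp_scores)
      utils::write.csv(do.call(rbind, lapply(ord, function(s)
        data.frame(ID = s$id, Survival = s$survival,
                   `Survival-inactive` = s$survival_inactive,
                   Selectivity = s$selectivity, Matches = s$matches,
                   check.names = FALSE))),
        file.path(out_dir, "hypotheses.csv"), row.names = FALSE)
      best <- hypotheses[[match(ord[[1]]$id,
                                vapply(hypotheses, `[[`, "", "id"))]]
      if (!is.null(config$screening$library_sdf)) {
        lib <- stage("read-library",
                     read_molecules(config$screening$library_sdf, "sdf"))
        hits <- stage("screen", screen_library(
          best, lib, model, grid, top_n = config$screening$top_n,
          tolerance = config$screening$tolerance))
        if (!is.null(config$screening$external_scores))
          hits <- merge_external_scores(hits, config$screening$external_scores)
        utils::write.csv(hits, file.path(out_dir, "hits.csv"), row.names = FALSE)
      }
    }
  }

  numeric_outputs <- intersect(c("model.json", "validation.json",
                                 "contributions.csv", "unicolumn.csv",
                                 "hits.csv", "hypotheses.csv"),
                               list.files(out_dir))
  manifest <- list(seed = config$seed,
                   settings = config[c("rmsd_cutoff", "grid", "variance_cutoff",
                                       "model", "randomization")],
                   outputs = as.list(tools::md5sum(file.path(out_dir, numeric_outputs))))
  names(manifest$outputs) <- numeric_outputs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(model = model, report = report, split = split, matrix = filt,
                 grid = grid, selected = selected, contributions = contrib,
                 hypotheses = hypotheses, hypothesis_scores = hyp_scores,
                 hits = hits, output_dir = out_dir))
}
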