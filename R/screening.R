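# Library screening against a pharmacophore hypothesis, with QSAR activity
# prediction for the matched hits.

# all injective assignments of hypothesis sites to molecule sites with
# matching types; cap guards pathological feature counts
site_assignments <- function(h_types, mol_types, cap = 5000L) {
  groups <- split(seq_along(h_types), h_types)
  cand <- lapply(names(groups), function(ty) which(mol_types == ty))
  names(cand) <- names(groups)
  if (any(vapply(cand, length, integer(1)) <
          vapply(groups, length, integer(1)))) return(NULL)
  k_perm <- function(v, k) {       # ordered k-subsets of v
    if (k == 0) return(list(integer(0)))
    out <- list()
    for (i in seq_along(v)) for (p in k_perm(v[-i], k - 1))
      out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  per_type <- lapply(names(groups),
                     function(ty) k_perm(cand[[ty]], length(groups[[ty]])))
  counts <- vapply(per_type, length, integer(1))
  if (prod(counts) > cap) {
    warning("assignment count ", prod(counts), " exceeds cap ", cap,
            "; truncating search")
  }
  idx <- expand.grid(lapply(counts, seq_len), KEEP.OUT.ATTRS = FALSE)
  idx <- idx[seq_len(min(nrow(idx), cap)), , drop = FALSE]
  n_sites <- length(h_types)
  lapply(seq_len(nrow(idx)), function(r) {
    asg <- integer(n_sites)
    for (g in seq_along(groups))
      asg[groups[[g]]] <- per_type[[g]][[idx[r, g]]]
    asg
  })
}

# grid-sampled shared/union volume of two hard-sphere heavy-atom models
volume_overlap <- function(xyz_a, xyz_b, radius = 1.7, step = 0.4) {
  lo <- pmin(apply(xyz_a, 2, min), apply(xyz_b, 2, min)) - radius
  hi <- pmax(apply(xyz_a, 2, max), apply(xyz_b, 2, max)) + radius
  ax <- lapply(1:3, function(d) seq(lo[d], hi[d], by = step))
  pts <- as.matrix(expand.grid(ax, KEEP.OUT.ATTRS = FALSE))
  inside <- function(xyz) {
    d2 <- outer(rowSums(pts^2), rowSums(xyz^2), `+`) - 2 * pts %*% t(xyz)
    rowSums(d2 <= radius^2) > 0
  }
  ia <- inside(xyz_a); ib <- inside(xyz_b)
  u <- sum(ia | ib)
  if (u == 0) return(0)
  sum(ia & ib) / u
}

#' Match a molecule against a pharmacophore hypothesis
#'
#' Searches all type-respecting assignments of the molecule's feature sites
#' to the hypothesis sites, superposes each assignment by least squares and
#' keeps the one minimizing the site RMSD. A molecule matches when that
#' RMSD does not exceed the tolerance; a missing feature type yields
#' `matched = FALSE`, never an error.
#'
#' @param h pharmacophore_hypothesis.
#' @param mol molecule.
#' @param tolerance maximum site RMSD (angstrom, default 2).
#' @param fitness_weights length-3 weights of the fitness
#'   `w1*(1 - align/tolerance) + w2*vector + w3*volume`.
#' @param rules [feature_rules()].
#' @return object of class `match_result`: `compound_id`, `matched`,
#'   `align_score` (site RMSD), `vector_score`, `volume_score`, `fitness`,
#'   plus the rigid `transform` into the hypothesis frame and the
#'   transformed `molecule`.
#' @export
match_molecule <- function(h, mol, tolerance = 2.0, fitness_weights = c(1, 1, 1),
                           rules = feature_rules()) {
  no_match <- structure(list(compound_id = mol$id, matched = FALSE,
                             align_score = NA_real_, vector_score = NA_real_,
                             volume_score = NA_real_, fitness = NA_real_,
                             predicted_activity = NA_real_,
                             external_score = NA_real_),
                        class = "match_result")
  sites <- tryCatch(perceive_features(mol, rules), error = function(e) NULL)
  if (is.null(sites) || length(sites) == 0) return(no_match)
  h_types <- site_types(h$sites)
  assignments <- site_assignments(h_types, site_types(sites))
  if (is.null(assignments)) return(no_match)
  h_pos <- site_positions(h$sites)
  best <- NULL
  for (asg in assignments) {
    fit <- kabsch_superpose(site_positions(sites[asg]), h_pos)
    if (is.null(best) || fit$rmsd < best$rmsd - 1e-12)
      best <- list(fit = fit, asg = asg, rmsd = fit$rmsd)
  }
  if (best$rmsd > tolerance) return(no_match)
  # vector score: mean cosine between transformed molecule directions and
  # hypothesis directions, over site pairs where both exist
  cosines <- numeric(0)
  for (s in seq_along(h_types)) {
    dh <- h$sites[[s]]$direction
    dm <- sites[[best$asg[s]]]$direction
    if (!is.null(dh) && !is.null(dm)) {
      dmr <- as.vector(best$fit$R %*% dm)
      cosines <- c(cosines, abs(sum(dmr * dh)))   # ring normals are sign-free
    }
  }
  vec <- if (length(cosines)) mean(cosines) else 1
  out_mol <- mol
  coords(out_mol) <- best$fit$transform(coords(mol))
  vol <- if (!is.null(h$ref_molecule))
    volume_overlap(coords(out_mol)[heavy_atoms(out_mol), , drop = FALSE],
                   coords(h$ref_molecule)[heavy_atoms(h$ref_molecule), , drop = FALSE])
  else 0
  fw <- fitness_weights
  structure(list(compound_id = mol$id, matched = TRUE, align_score = best$rmsd,
                 vector_score = vec, volume_score = vol,
                 fitness = fw[1] * (1 - best$rmsd / tolerance) + fw[2] * vec + fw[3] * vol,
                 predicted_activity = NA_real_, external_score = NA_real_,
                 transform = best$fit, molecule = out_mol),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  if (x$matched)
    cat(sprintf("<match %s: align %.4f, vector %.4f, volume %.4f, fitness %.4f%s>\n",
                x$compound_id, x$align_score, x$vector_score, x$volume_score,
                x$fitness,
                if (is.finite(x$predicted_activity))
                  sprintf(", predicted pIC50 %.3f", x$predicted_activity) else ""))
  else cat(sprintf("<match %s: no match>\n", x$compound_id))
  invisible(x)
}

#' The published four-descriptor grid-field model
#'
#' Fixture of the reported linear model:
#' pIC50 = 3.89857 E_86 + 3.12363 E_943 - 0.114297 E_463 + 0.0152502 S_482
#' + 5.73211, two electrostatic enhancers, one negatively contributing
#' electrostatic term, one steric term, and the regression constant.
#'
#' @return [qsar_model()].
#' @export
published_model <- function() {
  qsar_model(descriptor_names = c("E_86", "E_943", "E_463", "S_482"),
             coefficients = c(3.89857, 3.12363, -0.114297, 0.0152502),
             intercept = 5.73211, n_components = 1L,
             training_mean_activity = 6.51)
}

#' Screen a library against a hypothesis and predict activities
#'
#' Each library molecule is matched to the hypothesis; matched molecules
#' are carried into the training frame by the match's rigid transform,
#' their grid-field descriptors computed on the training grid, and their
#' activity predicted with the QSAR model. Results are ranked by fitness
#' (ties: higher predicted activity, then id).
#'
#' @param h pharmacophore_hypothesis (built in the training frame).
#' @param library list of molecules.
#' @param model qsar_model.
#' @param grid grid_spec of the training fields.
#' @param top_n how many results to return (default all).
#' @param tolerance,fitness_weights,probe,rules passed through.
#' @return data.frame of class `screen_report` with one row per returned
#'   molecule: compound_id, matched, align/vector/volume scores, fitness,
#'   predicted_activity, external_score.
#' @export
screen_library <- function(h, library, model, grid, top_n = Inf,
                           tolerance = 2.0, fitness_weights = c(1, 1, 1),
                           probe = probe_params(), rules = feature_rules()) {
  need <- parse_descriptor_name(model$descriptor_names)
  if (any(need$index > n_grid_points(grid)))
    stop("model descriptors reference grid indices beyond this grid")
  rows <- list()
  for (mol in library) {
    mr <- match_molecule(h, mol, tolerance, fitness_weights, rules)
    if (mr$matched) {
      mt <- mr$molecule
      if (length(mt$charges) == 0) mt <- assign_peoe_charges(mt)
      f <- compute_fields(mt, grid, probe)
      vals <- f[cbind(need$index,
                      match(need$field_type, colnames(f)))]
      mr$predicted_activity <- predict(model, stats::setNames(vals, model$descriptor_names))
    }
    rows[[length(rows) + 1]] <- mr
  }
  d <- do.call(rbind, lapply(rows, function(r)
    data.frame(compound_id = r$compound_id, matched = r$matched,
               align_score = r$align_score, vector_score = r$vector_score,
               volume_score = r$volume_score, fitness = r$fitness,
               predicted_activity = r$predicted_activity,
               external_score = r$external_score)))
  hit <- d[d$matched, , drop = FALSE]
  hit <- hit[order(-hit$fitness, -hit$predicted_activity, hit$compound_id), ,
             drop = FALSE]
  out <- utils::head(hit, top_n)
  rownames(out) <- NULL
  class(out) <- c("screen_report", "data.frame")
  out
}

#' Merge externally computed scores (e.g. docking) into screen results
#'
#' @param results `screen_report` (or data.frame with `compound_id`).
#' @param scores_csv CSV with columns `compound_id` and a score column
#'   (first non-id numeric column is used).
#' @param rerank re-sort ascending by external score (docking convention:
#'   more negative is better).
#' @return results with `external_score` populated; ids without a score are
#'   left NA with a warning.
#' @export
merge_external_scores <- function(results, scores_csv, rerank = FALSE) {
  d <- utils::read.csv(scores_csv, stringsAsFactors = FALSE)
  if (nrow(d) == 0) return(results)
  if (!"compound_id" %in% names(d)) stop("scores CSV lacks a 'compound_id' column")
  score_col <- setdiff(names(d), "compound_id")[1]
  if (is.na(score_col) || !is.numeric(d[[score_col]]))
    stop("scores CSV lacks a numeric score column")
  i <- match(results$compound_id, d$compound_id)
  results$external_score <- d[[score_col]][i]
  if (anyNA(i))
    warning("no external score for: ",
            paste(results$compound_id[is.na(i)], collapse = ", "))
  if (rerank)
    results <- results[order(results$external_score), , drop = FALSE]
  rownames(results) <- NULL
  results
}
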