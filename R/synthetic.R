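# Synthetic congeneric series with planted linear structure.
#
# The generator emulates the input of field-based 3D QSAR: a common scaffold
# decorated with varying substituents, embedded in 3D, aligned on the
# scaffold, with activities that are a known ("planted") linear function of
# a few grid-field descriptors plus Gaussian noise. Because the ground
# truth is returned alongside, every pipeline stage can be checked for
# parameter recovery.

#' Planted linear activity model
#'
#' @param informative_descriptors descriptor names carrying signal, or NULL
#'   to let the generator choose identifiable columns (high variance,
#'   mutually weakly correlated) and record them in the truth.
#' @param coefficients numeric; same length as the names when both given.
#'   NULL (with NULL names) lets the generator scale coefficients to a
#'   target activity spread.
#' @param intercept baseline activity (default 6.5 pIC50).
#' @param noise_sd Gaussian noise on the activities (pIC50 units).
#' @export
planted_model <- function(informative_descriptors = NULL, coefficients = NULL,
                          intercept = 6.5, noise_sd = 0) {
  if (!is.null(informative_descriptors) && !is.null(coefficients) &&
      length(informative_descriptors) != length(coefficients))
    stop("informative_descriptors and coefficients differ in length")
  stopifnot(noise_sd >= 0)
  structure(list(informative_descriptors = informative_descriptors,
                 coefficients = coefficients, intercept = intercept,
                 noise_sd = noise_sd),
            class = "planted_model")
}

# greedy identifiable-column choice. Two classes of column are unusable as
# ground truth: truncation-saturated ones (values pinned at +/- cutoff near
# atoms behave like step functions) and columns with a near-duplicate proxy
# elsewhere on the grid (a forward search cannot tell a column from a 0.95
# correlate, so planted names would be unrecoverable by construction).
# Among smooth, proxy-free columns take the highest variance first, then
# the highest variance among columns correlated < max_cor with everything
# already chosen.
choose_informative <- function(values, k, max_cor = 0.3, saturation = 30,
                               proxy_cor = 0.6) {
  smooth <- apply(abs(values) < 0.99 * saturation, 2, all)
  v <- apply(values, 2, stats::var)
  cand <- which(smooth & v > 1e-8)
  if (length(cand) < k) stop("too few usable descriptor columns to plant on")
  C <- abs(suppressWarnings(stats::cor(values[, cand, drop = FALSE], values)))
  C[cbind(seq_along(cand), cand)] <- 0      # self-correlation
  C[!is.finite(C)] <- 0
  proxy_max <- apply(C, 1, max)
  # candidate sets, strictest isolation first, relaxing the bounds only as
  # far as this geometry requires; several alternative sets per bound pair
  # (shifting the greedy start) so a caller can certify and fall through
  sets <- list()
  for (pc in unique(pmax(proxy_cor, c(proxy_cor, 0.8, 0.85, 0.9, 0.95)))) {
    for (mc in unique(pmax(max_cor, c(max_cor, 0.4, 0.5)))) {
      iso <- cand[proxy_max <= pc]
      orderings <- list(iso[order(-v[iso])],                 # variance-first
                        iso[order(proxy_max[cand %in% iso])]) # isolation-first
      for (ord in orderings) for (offset in 0:7) {
        pool <- if (offset == 0) ord else ord[-seq_len(min(offset, length(ord)))]
        chosen <- integer(0)
        for (j in pool) {
          if (length(chosen) == k) break
          ok <- all(abs(suppressWarnings(
            stats::cor(values[, j], values[, chosen, drop = FALSE]))) < mc)
          if (length(chosen) == 0 || isTRUE(ok)) chosen <- c(chosen, j)
        }
        if (length(chosen) == k) {
          key <- paste(sort(chosen), collapse = ",")
          if (!key %in% names(sets)) sets[[key]] <- colnames(values)[chosen]
        }
      }
    }
  }
  if (length(sets) == 0)
    stop("could not find ", k, " mutually weakly correlated, proxy-free columns")
  unname(sets)
}

# coefficients for a candidate descriptor set: geometrically decaying
# variance shares (greedy-friendly: the leading term dominates, so a
# forward search meets the terms in order); signs echo a mixed
# enhancer/detractor model
auto_coefficients <- function(X, target_sd) {
  k <- ncol(X)
  signs <- rep_len(c(1, 1, -1, 1), k)
  shares <- 2^(-(seq_len(k) - 1)); shares <- shares / sum(shares)
  signs * sqrt(shares) * target_sd / apply(X, 2, stats::sd)
}

# identifiability certification of a candidate planted set. Emulating the
# default workflow (interpolative split, selection on the training subset),
# forward selection on the noiseless activities must recover exactly the
# planted columns, and (for noisy models) must keep recovering at least
# `min_recover` of them on a few internal noise replicates. Returns the
# number of failed checks (0 = fully certified).
certify_planted <- function(m, names_, coefs, noise_sd,
                            n_replicates = 3L, min_recover = NULL,
                            centrality = descriptor_centrality(m$values)) {
  k <- length(names_)
  if (is.null(min_recover)) min_recover <- k - 1L
  y0 <- drop(m$values[, names_, drop = FALSE] %*% coefs)
  n <- length(y0)
  n_test <- min(5L, n - 4L)
  eval_recovery <- function(y) {
    # inline interpolative split (precomputed centrality, see
    # activity_ranked_split)
    ord <- order(y)
    interior <- ord[2:(n - 1)]
    eligible <- interior[order(centrality[interior])]
    eligible <- eligible[seq_len(max(n_test, ceiling(length(eligible) * 0.6)))]
    eligible <- eligible[order(y[eligible])]
    pick <- eligible[round(seq(1, length(eligible), length.out = n_test))]
    tri <- setdiff(seq_len(n), pick)
    sel <- colnames(m$values)[
      forward_select_matrix(m$values[tri, , drop = FALSE], y[tri], k)$selected]
    length(intersect(sel, names_))
  }
  fails <- if (eval_recovery(y0) == k) 0L else 2L * n_replicates
  if (noise_sd > 0) {
    for (r in seq_len(n_replicates)) {
      yr <- y0 + stats::rnorm(length(y0), 0, noise_sd)
      if (eval_recovery(yr) < min_recover) fails <- fails + 1L
    }
  }
  fails
}

realize_planted <- function(planted, m, target_sd = 0.7, target_mean = 6.5) {
  values <- m$values
  k <- if (!is.null(planted$coefficients)) length(planted$coefficients) else 4L
  names_ <- planted$informative_descriptors
  auto <- is.null(names_)
  if (auto) {
    # try candidate isolated sets until one is certified identifiable
    candidates <- choose_informative(values, k)
    candidates <- candidates[seq_len(min(length(candidates), 16L))]
    centrality <- descriptor_centrality(values)
    best <- NULL
    for (names_c in candidates) {
      coefs_c <- auto_coefficients(values[, names_c, drop = FALSE], target_sd)
      fails <- certify_planted(m, names_c, coefs_c, planted$noise_sd,
                               centrality = centrality)
      if (is.null(best) || fails < best$fails)
        best <- list(names = names_c, coefs = coefs_c, fails = fails)
      if (best$fails == 0L) break
    }
    names_ <- best$names
  }
  miss <- setdiff(names_, colnames(values))
  if (length(miss) > 0)
    stop("planted descriptor(s) not present in the matrix: ",
         paste(miss, collapse = ", "))
  X <- values[, names_, drop = FALSE]
  coefs <- planted$coefficients
  if (is.null(coefs)) coefs <- auto_coefficients(X, target_sd)
  intercept <- planted$intercept
  if (is.null(intercept)) intercept <- target_mean
  if (is.null(planted$coefficients))  # auto-scaled model: center on target mean
    intercept <- intercept - sum(coefs * colMeans(X))
  planted_model(names_, coefs, intercept, planted$noise_sd)
}

planted_activities <- function(planted, values) {
  X <- values[, planted$informative_descriptors, drop = FALSE]
  drop(planted$intercept + X %*% planted$coefficients) +
    stats::rnorm(nrow(values), 0, planted$noise_sd)
}

#' Default substituent fragments
#'
#' Small organic substituents (halogens, alkyls, ethers, amines, nitrile,
#' trifluoromethyl, ...) written as SMILES fragments; the empty string is
#' hydrogen.
#' @export
default_substituents <- function() {
  c("", "F", "Cl", "Br", "C", "CC", "CCC", "C(C)C", "O", "OC", "OCC",
    "N", "NC", "C#N", "C(F)(F)F", "C=C")
}

#' Generate a synthetic congeneric series
#'
#' Enumerates scaffold/substituent combinations (every `(*)` marker in the
#' scaffold SMILES is an attachment point), samples `n` of them (seeded),
#' embeds 3D structures, assigns PEOE charges, aligns all molecules on the
#' scaffold core, computes grid fields, and plants activities as a linear
#' function of named grid descriptors plus Gaussian noise.
#'
#' @param scaffold SMILES with >= 1 attachment marker `(*)`; default a
#'   benzaldehyde-thiosemicarbazone core with two phenyl attachment points.
#' @param substituents character vector of SMILES fragments (`""` = H).
#' @param n series size (default 33: a 28-compound training pool plus a
#'   5-compound test set).
#' @param planted [planted_model()]; NULL plants a 4-descriptor model with
#'   an activity spread echoing a typical congeneric series (pIC50 roughly
#'   5.3-7.6).
#' @param seed integer seed controlling substituent sampling, embedding and
#'   activity noise.
#' @param margin,spacing grid construction parameters (angstrom).
#' @param variance_cutoff variance filter applied before choosing/checking
#'   planted descriptors.
#' @return list of class `congeneric_series`: `molecules` (aligned, with
#'   charges), `activities` (data.frame), `matrix` (filtered
#'   descriptor_matrix), `grid`, `truth` (realized planted model),
#'   `alignments`.
#' @export
generate_congeneric_series <- function(scaffold = "NC(=S)N/N=C/c1cc(*)cc(*)c1",
                                       substituents = default_substituents(),
                                       n = 33L, planted = NULL, seed = 42L,
                                       margin = 5, spacing = 2,
                                       variance_cutoff = 0.1) {
  n_sites <- lengths(regmatches(scaffold, gregexpr("(*)", scaffold, fixed = TRUE)))
  if (n_sites == 0) stop("scaffold has no '(*)' attachment point")
  combos <- expand.grid(rep(list(seq_along(substituents)), n_sites),
                        KEEP.OUT.ATTRS = FALSE)
  if (n > nrow(combos))
    stop("requested ", n, " compounds but only ", nrow(combos),
         " scaffold/substituent combinations exist")
  set.seed(seed)
  pick <- sample(nrow(combos), n)
  smiles <- character(n)
  for (i in seq_len(n)) {
    s <- scaffold
    for (frag in substituents[unlist(combos[pick[i], ])]) {
      rep_ <- if (nzchar(frag)) paste0("(", frag, ")") else ""
      s <- sub("(*)", rep_, s, fixed = TRUE)
    }
    smiles[i] <- s
  }
  ids <- sprintf("SYN%02d", seq_len(n))
  mols <- parse_smiles(smiles, ids = ids, seed = seed)
  mols <- lapply(mols, assign_peoe_charges)
  template <- parse_smiles_topology(gsub("(*)", "", scaffold, fixed = TRUE))
  reference <- mols[[1]]
  alignments <- lapply(mols, align_to_template, template = template,
                       reference = reference)
  aligned <- lapply(alignments, `[[`, "molecule")
  grid <- build_grid(aligned, margin = margin, spacing = spacing)
  zero <- stats::setNames(rep(0, n), ids)
  full <- assemble_descriptor_matrix(aligned, zero, grid)
  filt <- filter_invariant_columns(full, variance_cutoff)
  truth <- realize_planted(if (is.null(planted)) planted_model() else planted,
                           filt)
  y <- planted_activities(truth, filt$values)
  filt$activities[] <- y
  structure(list(molecules = aligned, alignments = alignments,
                 activities = data.frame(compound_id = ids, pic50 = y),
                 matrix = filt, grid = grid, truth = truth, smiles = smiles,
                 seed = seed),
            class = "congeneric_series")
}

#' @export
print.congeneric_series <- function(x, ...) {
  cat(sprintf("<congeneric_series: %d compounds, %d descriptors after filtering, planted on %s (noise sd %.3g)>\n",
              length(x$molecules), ncol(x$matrix$values),
              paste(x$truth$informative_descriptors, collapse = ", "),
              x$truth$noise_sd))
  invisible(x)
}

#' Write a synthetic series to disk
#'
#' Standard formats so synthetic data flows through the same readers as
#' real data: `molecules.sdf`, `activities.csv`, and `truth.json` (the
#' planted ground truth, serialized so tests never re-derive it).
#'
#' @param series congeneric_series.
#' @param dir output directory (created if needed).
#' @export
write_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sdf(series$molecules, file.path(dir, "molecules.sdf"))
  utils::write.csv(series$activities, file.path(dir, "activities.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
    informative_descriptors = series$truth$informative_descriptors,
    coefficients = series$truth$coefficients,
    intercept = series$truth$intercept,
    noise_sd = series$truth$noise_sd,
    seed = series$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  write_grid_json(series$grid, file.path(dir, "grid.json"))
  invisible(dir)
}

#' Generate a purely numeric descriptor matrix with planted structure
#'
#' Descriptor values are i.i.d. standard normal except for an optional
#' block of constant columns; activities come from the planted linear model
#' plus noise. Useful for testing selection and validation machinery
#' without any chemistry.
#'
#' @param n_compounds,n_descriptors dimensions.
#' @param planted [planted_model()]; NULL-named models get evenly spaced
#'   informative columns.
#' @param seed RNG seed.
#' @param n_constant number of constant (zero) columns planted among the
#'   descriptors (seeded positions).
#' @return descriptor_matrix with the realized truth in `$truth`.
#' @export
generate_descriptor_matrix <- function(n_compounds, n_descriptors, planted,
                                       seed = 42L, n_constant = 0L) {
  stopifnot(n_constant < n_descriptors)
  set.seed(seed)
  vals <- matrix(stats::rnorm(n_compounds * n_descriptors), n_compounds)
  # field types in thirds (steric, then electrostatic, then hydrophobic),
  # indices global, mirroring an assembled grid matrix
  third <- ceiling(n_descriptors / 3)
  prefix <- rep(c("S", "E", "H"),
                c(third, min(third, max(n_descriptors - third, 0)),
                  max(n_descriptors - 2 * third, 0)))[seq_len(n_descriptors)]
  names_ <- paste0(prefix, "_", seq_len(n_descriptors))
  colnames(vals) <- names_
  if (is.null(planted$informative_descriptors)) {
    k <- length(planted$coefficients)
    if (k == 0) stop("planted model needs coefficients or descriptor names")
    planted$informative_descriptors <-
      names_[round(seq(1, n_descriptors - n_constant, length.out = k))]
  }
  if (is.null(planted$coefficients))
    stop("planted model needs explicit coefficients for a pure-noise matrix")
  if (length(planted$coefficients) != length(planted$informative_descriptors))
    stop("planted coefficients and descriptor names differ in length")
  if (n_constant > 0) {
    free <- setdiff(seq_len(n_descriptors),
                    match(planted$informative_descriptors, names_))
    vals[, sample(free, n_constant)] <- 0
  }
  miss <- setdiff(planted$informative_descriptors, names_)
  if (length(miss) > 0) stop("planted descriptors out of range: ",
                             paste(miss, collapse = ", "))
  ids <- sprintf("C%03d", seq_len(n_compounds))
  y <- planted_activities(planted, vals)
  desc <- data.frame(name = names_,
                     field_type = c(S = "steric", E = "electrostatic",
                                    H = "hydrophobic")[prefix],
                     index = seq_len(n_descriptors),
                     x = NA_real_, y = NA_real_, z = NA_real_)
  out <- descriptor_matrix(ids, desc, vals, y)
  out$truth <- planted
  out
}
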