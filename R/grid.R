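# CoMFA-style probe-interaction fields on a rectangular grid.
#
# The probe is an sp3 carbon with +1 e charge. At every grid point three
# energies are evaluated against all atoms of a molecule:
#   steric        Lennard-Jones 6-12,  eps_ij*((rmin_ij/r)^12 - 2(rmin_ij/r)^6)
#   electrostatic Coulomb, 332.063 * q_atom * q_probe / (eps_diel * r) kcal/mol
#   hydrophobic   Gaussian-damped atomic hydrophobicity, h_atom * exp(-r^2/2s^2)
# LJ and Coulomb are truncated to +/- cutoff (default 30 kcal/mol) so grid
# points inside atoms stay finite; the same bound is applied to all stored
# values.

#' Rectangular grid specification
#'
#' @param origin numeric length-3, minimum corner (angstrom).
#' @param spacing grid spacing (angstrom), > 0.
#' @param counts integer length-3, points per axis, >= 1.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(origin, spacing, counts) {
  stopifnot(length(origin) == 3, spacing > 0, length(counts) == 3, all(counts >= 1))
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 counts = as.integer(counts)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid %d x %d x %d (%d points), spacing %.2f A, origin (%.2f, %.2f, %.2f)>\n",
              x$counts[1], x$counts[2], x$counts[3], prod(x$counts), x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Total number of grid points
#' @param grid grid_spec.
#' @export
n_grid_points <- function(grid) prod(grid$counts)

#' Cartesian coordinates of all grid points
#'
#' Points are ordered x-fastest, then y, then z; row k corresponds to the
#' 1-based linear index used in descriptor names (S_k / E_k / H_k).
#'
#' @param grid grid_spec.
#' @return n x 3 matrix.
#' @export
grid_points <- function(grid) {
  ax <- lapply(1:3, function(d) grid$origin[d] + grid$spacing * (seq_len(grid$counts[d]) - 1))
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]], KEEP.OUT.ATTRS = FALSE)
  as.matrix(g)
}

#' Build a grid around an aligned series
#'
#' The grid covers the union bounding box of all atoms (hydrogens included)
#' extended by `margin` on every side; per axis the number of points is
#' `ceil(extent / spacing) + 1`.
#'
#' @param aligned list of molecules (or `alignment_result`s) in a common frame.
#' @param margin border in angstrom (>= 0), default 5.
#' @param spacing grid spacing in angstrom (> 0), default 2.
#' @return grid_spec.
#' @export
build_grid <- function(aligned, margin = 5, spacing = 2) {
  stopifnot(margin >= 0, spacing > 0)
  mols <- unwrap_molecules(aligned)
  if (length(mols) == 0) stop("cannot build a grid from an empty molecule list")
  xyz <- do.call(rbind, lapply(mols, coords))
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  counts <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  grid_spec(lo, spacing, counts)
}

unwrap_molecules <- function(x) {
  if (inherits(x, "molecule")) return(list(x))
  lapply(x, function(e) if (inherits(e, "alignment_result")) e$molecule else e)
}

#' Probe and field parameters
#'
#' @param r_vdw probe van der Waals radius (sp3 carbon, angstrom).
#' @param eps probe LJ well depth (kcal/mol).
#' @param charge probe charge (e).
#' @param dielectric constant dielectric for the Coulomb term.
#' @param cutoff truncation bound for stored energies (kcal/mol).
#' @param sigma_h Gaussian width of the hydrophobic field (angstrom).
#' @export
probe_params <- function(r_vdw = 1.7, eps = 0.07, charge = 1.0,
                         dielectric = 1.0, cutoff = 30, sigma_h = 1.5) {
  list(r_vdw = r_vdw, eps = eps, charge = charge, dielectric = dielectric,
       cutoff = cutoff, sigma_h = sigma_h)
}

# per-element van der Waals radius (A), LJ well depth (kcal/mol) and atomic
# hydrophobicity contribution (Crippen-type sign pattern, coarse per-element)
.atom_params <- data.frame(
  element = c("H",  "C",  "N",   "O",   "F",  "S",  "Cl", "Br", "I",  "P"),
  r_vdw   = c(1.20, 1.70, 1.55,  1.52,  1.47, 1.80, 1.75, 1.85, 1.98, 1.80),
  eps     = c(0.03, 0.07, 0.12,  0.12,  0.08, 0.25, 0.30, 0.35, 0.40, 0.20),
  hydro   = c(0.10, 0.20, -0.60, -0.64, 0.22, 0.25, 0.65, 0.89, 1.20, -0.10))

atom_field_params <- function(elements) {
  i <- match(elements, .atom_params$element)
  if (anyNA(i)) {
    warning("no field parameters for element(s) ",
            paste(unique(elements[is.na(i)]), collapse = ", "),
            "; using carbon values")
    i[is.na(i)] <- match("C", .atom_params$element)
  }
  .atom_params[i, ]
}

#' Compute probe-interaction fields for one molecule
#'
#' @param mol molecule with partial charges assigned.
#' @param grid grid_spec.
#' @param probe parameters from [probe_params()].
#' @return matrix `n_grid_points x 3` with columns `steric`,
#'   `electrostatic`, `hydrophobic` (kcal/mol), every value within
#'   `[-cutoff, +cutoff]`.
#' @export
compute_fields <- function(mol, grid, probe = probe_params()) {
  if (length(mol$charges) == 0)
    stop("molecule '", mol$id, "' has no partial charges; run assign_peoe_charges() first")
  pts <- grid_points(grid)
  xyz <- coords(mol)
  ap <- atom_field_params(mol$atoms$element)
  # squared distances: points x atoms
  d2 <- outer(rowSums(pts^2), rowSums(xyz^2), `+`) - 2 * pts %*% t(xyz)
  d2[d2 < 1e-12] <- 1e-12
  r <- sqrt(d2)
  rmin <- ap$r_vdw + probe$r_vdw
  epsij <- sqrt(ap$eps * probe$eps)
  sr6 <- sweep(1 / r, 2, rmin, `*`)^6
  steric <- rowSums(sweep(sr6^2 - 2 * sr6, 2, epsij, `*`))
  elec <- 332.063 * probe$charge / probe$dielectric *
    rowSums(sweep(1 / r, 2, mol$charges, `*`))
  hydro <- rowSums(sweep(exp(-d2 / (2 * probe$sigma_h^2)), 2, ap$hydro, `*`))
  out <- cbind(steric = pmin(pmax(steric, -probe$cutoff), probe$cutoff),
               electrostatic = pmin(pmax(elec, -probe$cutoff), probe$cutoff),
               hydrophobic = pmin(pmax(hydro, -probe$cutoff), probe$cutoff))
  out
}

# ---- descriptor matrix -----------------------------------------------------

#' Descriptor matrix container
#'
#' Compounds x grid-field descriptors plus per-compound activities.
#' Descriptor names follow the `S_k`/`E_k`/`H_k` convention: field-type
#' prefix (steric, electrostatic, hydrophobic) plus the 1-based linear grid
#' index of the point.
#'
#' @param compound_ids character vector.
#' @param descriptors data.frame with columns `name`, `field_type`,
#'   `index`, `x`, `y`, `z`.
#' @param values numeric matrix, compounds x descriptors.
#' @param activities numeric pIC50 vector aligned with `compound_ids`.
#' @export
descriptor_matrix <- function(compound_ids, descriptors, values, activities) {
  stopifnot(nrow(values) == length(compound_ids),
            ncol(values) == nrow(descriptors),
            length(activities) == length(compound_ids),
            all(is.finite(values)))
  rownames(values) <- compound_ids
  colnames(values) <- descriptors$name
  structure(list(compound_ids = as.character(compound_ids),
                 descriptors = descriptors, values = values,
                 activities = stats::setNames(as.numeric(activities), compound_ids)),
            class = "descriptor_matrix")
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("<descriptor_matrix: %d compounds x %d descriptors (%s)>\n",
              length(x$compound_ids), ncol(x$values),
              paste(table(x$descriptors$field_type), names(table(x$descriptors$field_type)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.descriptor_matrix <- function(x) dim(x$values)

#' Parse a descriptor name into field type and grid index
#' @param name character vector like `"E_86"`.
#' @return data.frame with `field_type`, `index`.
#' @export
parse_descriptor_name <- function(name) {
  type <- c(S = "steric", E = "electrostatic", H = "hydrophobic")[sub("_.*$", "", name)]
  data.frame(field_type = unname(type), index = as.integer(sub("^._", "", name)))
}

#' Assemble the descriptor matrix for an aligned series
#'
#' Columns are ordered steric first, then electrostatic, then hydrophobic,
#' each by linear grid index, so names are stable for a fixed grid.
#'
#' @param aligned list of molecules (or alignment results) with charges.
#' @param activities data.frame (`compound_id`, `pic50`) or named numeric.
#' @param grid grid_spec.
#' @param probe probe parameters.
#' @return [descriptor_matrix()].
#' @export
assemble_descriptor_matrix <- function(aligned, activities, grid,
                                       probe = probe_params()) {
  mols <- unwrap_molecules(aligned)
  ids <- vapply(mols, function(m) m$id, character(1))
  if (is.data.frame(activities))
    activities <- stats::setNames(activities$pic50, activities$compound_id)
  missing <- setdiff(ids, names(activities))
  if (length(missing) > 0)
    stop("no activity record for compound(s): ", paste(missing, collapse = ", "))
  P <- n_grid_points(grid)
  pts <- grid_points(grid)
  vals <- matrix(NA_real_, nrow = length(mols), ncol = 3 * P)
  for (k in seq_along(mols)) {
    f <- compute_fields(mols[[k]], grid, probe)
    vals[k, ] <- c(f[, "steric"], f[, "electrostatic"], f[, "hydrophobic"])
  }
  desc <- data.frame(
    name = c(paste0("S_", seq_len(P)), paste0("E_", seq_len(P)), paste0("H_", seq_len(P))),
    field_type = rep(c("steric", "electrostatic", "hydrophobic"), each = P),
    index = rep(seq_len(P), 3),
    x = rep(pts[, 1], 3), y = rep(pts[, 2], 3), z = rep(pts[, 3], 3))
  descriptor_matrix(ids, desc, vals, activities[ids])
}

#' Remove invariable descriptor columns
#'
#' Drops every column whose sample variance across compounds is below the
#' cutoff (the "invariable columns"); survivor order is preserved and the
#' removed names are recorded in the `removed` attribute.
#'
#' @param m descriptor_matrix.
#' @param variance_cutoff minimum sample variance to keep (default 0.1).
#' @return filtered descriptor_matrix.
#' @export
filter_invariant_columns <- function(m, variance_cutoff = 0.1) {
  stopifnot(variance_cutoff >= 0)
  v <- apply(m$values, 2, stats::var)
  keep <- v >= variance_cutoff
  if (!any(keep)) stop("variance cutoff ", variance_cutoff, " removes every descriptor column")
  out <- descriptor_matrix(m$compound_ids, m$descriptors[keep, , drop = FALSE],
                           m$values[, keep, drop = FALSE], m$activities)
  attr(out, "removed") <- colnames(m$values)[!keep]
  out
}

#' Write a descriptor matrix as CSV
#'
#' First columns `compound_id`, `pic50`, then one column per descriptor.
#' @param m descriptor_matrix.
#' @param path output CSV.
#' @export
write_descriptor_csv <- function(m, path) {
  d <- data.frame(compound_id = m$compound_ids, pic50 = unname(m$activities),
                  m$values, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a grid specification as JSON
#' @param grid grid_spec.
#' @param path output file.
#' @export
write_grid_json <- function(grid, path) {
  jsonlite::write_json(list(origin = grid$origin, spacing = grid$spacing,
                            counts = grid$counts),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
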