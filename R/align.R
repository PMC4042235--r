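# Template-based rigid alignment: VF2 substructure matching on the heavy-atom
# graph (element-coloured) plus Kabsch least-squares superposition.

#' Least-squares (Kabsch) superposition
#'
#' Finds the rigid transform (rotation + translation, det(R) = +1) that
#' minimizes the RMSD between paired point sets, mapping `P` onto `Q`.
#'
#' @param P,Q n x 3 matrices of paired coordinates.
#' @return list with `R` (3 x 3 rotation), `t` (translation), `rmsd`, and
#'   `transform(X)` applying the fit to arbitrary coordinates.
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(ncol(P) == 3, all(dim(P) == dim(Q)))
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  transform <- function(X) sweep(sweep(as.matrix(X), 2, cp) %*% t(R), 2, cq, `+`)
  rmsd <- sqrt(mean(rowSums((transform(P) - Q)^2)))
  list(R = R, t = cq - as.vector(R %*% cp), rmsd = rmsd, transform = transform)
}

#' RMSD between paired coordinate sets (no fitting)
#' @param P,Q n x 3 matrices.
#' @export
rmsd <- function(P, Q) sqrt(mean(rowSums((as.matrix(P) - as.matrix(Q))^2)))

# heavy-atom igraph with element vertex colours shared across two molecules
mol_graph <- function(m, palette) {
  heavy <- heavy_atoms(m)
  remap <- match(seq_len(n_atoms(m)), heavy)
  b <- m$bonds
  keep <- !is.na(remap[b$i]) & !is.na(remap[b$j])
  el <- cbind(remap[b$i[keep]], remap[b$j[keep]])
  g <- igraph::make_empty_graph(n = length(heavy), directed = FALSE)
  if (nrow(el) > 0) g <- igraph::add_edges(g, t(el))
  igraph::V(g)$color <- match(m$atoms$element[heavy], palette)
  attr(g, "atom_index") <- heavy
  g
}

as_template <- function(template) {
  if (inherits(template, "molecule")) template else parse_smiles_topology(template)
}

#' Substructure matches of a template in a molecule
#'
#' VF2 subgraph isomorphism on the heavy-atom graphs with element labels as
#' vertex colours. Hydrogens never take part in matching.
#'
#' @param mol molecule.
#' @param template molecule or SMILES string describing the substructure.
#' @return list of integer vectors; each maps template heavy atom k to the
#'   matched atom index in `mol`. Empty list if there is no match.
#' @export
substructure_matches <- function(mol, template) {
  tm <- as_template(template)
  palette <- unique(c(tm$atoms$element, mol$atoms$element))
  gt <- mol_graph(tm, palette)
  gm <- mol_graph(mol, palette)
  maps <- igraph::subgraph_isomorphisms(pattern = gt, target = gm, method = "vf2",
                                        vertex.color1 = igraph::V(gm)$color,
                                        vertex.color2 = igraph::V(gt)$color)
  out <- lapply(maps, function(mp) attr(gm, "atom_index")[as.integer(mp)])
  unique(out)
}

#' Align a molecule onto a reference by a shared template substructure
#'
#' Both molecules are matched against the template; the molecule's template
#' atoms are rigidly superposed (least squares) onto the reference's. When
#' the template matches in several ways (symmetry), every combination of
#' matches is tried and the lowest-RMSD one kept.
#'
#' @param mol molecule with 3D coordinates.
#' @param template substructure (molecule or SMILES) shared by both.
#' @param reference molecule defining the target frame; must match the
#'   template.
#' @return object of class `alignment_result`: `molecule` (transformed
#'   copy), `template_match` (2-column matrix of mol/reference atom index
#'   pairs), `rmsd` (angstrom), `matched` (logical). A molecule that does
#'   not contain the template yields `matched = FALSE`, not an error.
#' @export
align_to_template <- function(mol, template, reference) {
  tm <- as_template(template)
  ref_matches <- substructure_matches(reference, tm)
  if (length(ref_matches) == 0) stop("reference molecule does not match the template")
  mol_matches <- substructure_matches(mol, tm)
  if (length(mol_matches) == 0) {
    return(structure(list(molecule = mol, template_match = NULL, rmsd = NA_real_,
                          matched = FALSE), class = "alignment_result"))
  }
  ref_xyz <- coords(reference)
  mol_xyz <- coords(mol)
  best <- NULL
  for (rm_ in ref_matches) for (mm in mol_matches) {
    fit <- kabsch_superpose(mol_xyz[mm, , drop = FALSE], ref_xyz[rm_, , drop = FALSE])
    if (is.null(best) || fit$rmsd < best$rmsd - 1e-12)
      best <- list(fit = fit, mm = mm, rm = rm_, rmsd = fit$rmsd)
  }
  out <- mol
  coords(out) <- best$fit$transform(mol_xyz)
  structure(list(molecule = out,
                 template_match = cbind(mol_atom = best$mm, ref_atom = best$rm),
                 rmsd = best$rmsd, matched = TRUE),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  if (x$matched)
    cat(sprintf("<alignment %s: rmsd %.4f A over %d template atoms>\n",
                x$molecule$id, x$rmsd, nrow(x$template_match)))
  else cat(sprintf("<alignment %s: no template match>\n", x$molecule$id))
  invisible(x)
}

#' Select and align congeners by template RMSD
#'
#' Aligns every molecule onto the reference via the template and keeps those
#' whose template RMSD does not exceed the cutoff, sorted by ascending RMSD.
#' Molecules lacking the template core are excluded (and named in the
#' `excluded` attribute together with above-cutoff ones).
#'
#' @param mols list of molecules.
#' @param template shared substructure (molecule or SMILES).
#' @param reference reference molecule (typically the most active).
#' @param rmsd_cutoff maximum template RMSD in angstrom (default 1.0).
#' @return list of `alignment_result`, sorted ascending by RMSD, with an
#'   `excluded` attribute naming dropped molecules.
#' @export
select_congeners <- function(mols, template, reference, rmsd_cutoff = 1.0) {
  stopifnot(rmsd_cutoff > 0)
  tm <- as_template(template)
  res <- lapply(mols, align_to_template, template = tm, reference = reference)
  ok <- vapply(res, function(r) r$matched && r$rmsd <= rmsd_cutoff, logical(1))
  excluded <- vapply(res[!ok], function(r) r$molecule$id, character(1))
  kept <- res[ok]
  kept <- kept[order(vapply(kept, `[[`, numeric(1), "rmsd"))]
  if (length(kept) == 0)
    stop("no molecule passed the template-RMSD cutoff (", rmsd_cutoff,
         " A); consider increasing it")
  attr(kept, "excluded") <- excluded
  kept
}
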