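#' Molecule container
#'
#' A light S3 container for a small molecule: atoms (element, cartesian
#' coordinates in angstrom, formal charge), bonds (atom indices and integer
#' order) and, once assigned, PEOE partial charges in elementary-charge
#' units. Every downstream stage (alignment, grid fields, pharmacophore
#' perception, screening) consumes this type.
#'
#' @param id character scalar identifier.
#' @param atoms data.frame with columns `element`, `x`, `y`, `z`,
#'   `formal_charge`.
#' @param bonds data.frame with columns `i`, `j`, `order` (1, 2, 3).
#' @param charges numeric vector of partial charges (length 0 until
#'   [assign_peoe_charges()] has run).
#' @return object of class `molecule`.
#' @export
molecule <- function(id, atoms, bonds, charges = numeric(0)) {
  atoms <- as.data.frame(atoms)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  if (is.null(atoms$formal_charge)) atoms$formal_charge <- 0L
  atoms$element <- as.character(atoms$element)
  bonds <- as.data.frame(bonds)
  if (nrow(bonds) == 0) bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  stopifnot(all(c("i", "j", "order") %in% names(bonds)))
  m <- structure(list(id = as.character(id), atoms = atoms, bonds = bonds,
                      charges = as.numeric(charges)),
                 class = "molecule")
  validate_molecule(m)
  m
}

validate_molecule <- function(m) {
  co <- coords(m)
  if (!all(is.finite(co))) stop("molecule '", m$id, "': non-finite coordinates")
  n <- n_atoms(m)
  b <- m$bonds
  if (nrow(b) > 0 && (any(b$i < 1 | b$i > n) || any(b$j < 1 | b$j > n)))
    stop("molecule '", m$id, "': bond atom index out of range")
  if (length(m$charges) > 0) {
    if (length(m$charges) != n)
      stop("molecule '", m$id, "': partial charge vector length != atom count")
    dq <- abs(sum(m$charges) - sum(m$atoms$formal_charge))
    if (dq > 1e-3)
      stop("molecule '", m$id, "': partial charges sum differs from net formal charge by ", signif(dq, 3))
  }
  invisible(m)
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule %s: %d atoms (%d heavy), %d bonds, charges %s>\n",
              x$id, n_atoms(x), sum(x$atoms$element != "H"), nrow(x$bonds),
              if (length(x$charges)) "assigned" else "unassigned"))
  invisible(x)
}

#' Number of atoms of a molecule
#' @param m molecule.
#' @export
n_atoms <- function(m) nrow(m$atoms)

#' Atom coordinates as an n x 3 matrix
#' @param m molecule.
#' @export
coords <- function(m) as.matrix(m$atoms[, c("x", "y", "z")])

`coords<-` <- function(m, value) {
  m$atoms[, c("x", "y", "z")] <- value
  m
}

#' Indices of heavy (non-hydrogen) atoms
#' @param m molecule.
#' @export
heavy_atoms <- function(m) which(m$atoms$element != "H")

# ---- I/O -------------------------------------------------------------------

python_bin <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) stop("no 'python' interpreter found on PATH (required for SMILES parsing/embedding)")
  p
}

embed_script <- function() {
  s <- system.file("scripts", "embed_smiles.py", package = "fieldqsar")
  if (!nzchar(s)) stop("bundled embed_smiles.py not found; is fieldqsar installed?")
  s
}

smiles_to_sdf_text <- function(lines, mode = c("embed", "topo"), seed = 42L) {
  mode <- match.arg(mode)
  out <- suppressWarnings(system2(python_bin(), c(embed_script(), mode, as.integer(seed)),
                                  input = lines, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  bad <- grep("^(PARSE|EMBED)_FAIL", out)
  if (length(bad) > 0) {
    info <- sub("\t", " at record ", out[bad[1]])
    stop("SMILES conversion failed: ", info)
  }
  if (!is.null(status) && status != 0)
    stop("SMILES conversion failed (python exit status ", status, ")")
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Read molecules from SDF or SMILES
#'
#' SDF (V2000) records are parsed with ChemmineR; `M  CHG` formal-charge
#' lines are honoured. SMILES input (one per line, optional tab-separated
#' id) is parsed with RDKit through a bundled helper and given a single
#' deterministic 3D conformer (ETKDGv3 with a fixed per-record random seed,
#' followed by a bounded MMFF94 minimization) with explicit hydrogens.
#'
#' @param path file path.
#' @param format `"sdf"` or `"smiles"`.
#' @param seed integer seed for the conformer embedding (SMILES only).
#' @return list of [molecule()] objects.
#' @export
read_molecules <- function(path, format = c("sdf", "smiles"), seed = 42L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) stop("empty SMILES file: ", path)
    return(parse_smiles(lines, seed = seed))
  }
  txt <- readLines(path, warn = FALSE)
  if (length(txt) == 0 || !any(nzchar(txt))) stop("empty SDF file: ", path)
  sdf_text_to_molecules(txt)
}

#' Parse SMILES strings into embedded 3D molecules
#'
#' @param smiles character vector of SMILES, each optionally followed by a
#'   tab and an id.
#' @param ids optional character vector of ids (overrides ids in `smiles`).
#' @param seed integer embedding seed.
#' @return list of [molecule()] objects with explicit hydrogens and 3D
#'   coordinates.
#' @export
parse_smiles <- function(smiles, ids = NULL, seed = 42L) {
  if (!is.null(ids)) smiles <- paste(vapply(strsplit(smiles, "\t"), `[[`, "", 1L), ids, sep = "\t")
  sdf <- smiles_to_sdf_text(smiles, mode = "embed", seed = seed)
  sdf_text_to_molecules(strsplit(sdf, "\n")[[1]])
}

# Parse a SMILES into a connectivity-only molecule (no H, zero coordinates).
# Used for template/substructure graphs.
parse_smiles_topology <- function(smiles) {
  sdf <- smiles_to_sdf_text(smiles, mode = "topo")
  sdf_text_to_molecules(strsplit(sdf, "\n")[[1]])[[1]]
}

sdf_text_to_molecules <- function(lines) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  sdfset <- tryCatch(ChemmineR::read.SDFset(tf, skipErrors = TRUE),
                     error = function(e) stop("failed to parse SDF: ", conditionMessage(e)))
  sdfstr <- ChemmineR::read.SDFstr(tf)
  mols <- vector("list", length(sdfset))
  for (k in seq_along(sdfset)) {
    sdf <- sdfset[[k]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    if (is.null(ab) || nrow(ab) == 0) stop("unparsable SDF record at index ", k)
    el <- sub("_.*$", "", rownames(ab))
    fc <- integer(nrow(ab))
    # V2000 "M  CHG" lines carry formal charges (ChemmineR drops them)
    raw <- sdfstr[[k]]
    for (ln in grep("^M  CHG", raw, value = TRUE)) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
      nn <- f[1]
      for (q in seq_len(nn)) fc[f[2 * q]] <- f[2 * q + 1]
    }
    id <- ChemmineR::sdfid(sdf)
    if (is.null(id) || !nzchar(id)) id <- paste0("mol", k)
    bonds <- if (!is.null(bb) && nrow(bb) > 0)
      data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]), order = as.integer(bb[, 3]))
    else data.frame(i = integer(0), j = integer(0), order = integer(0))
    mols[[k]] <- molecule(
      id = id,
      atoms = data.frame(element = el, x = ab[, 1], y = ab[, 2], z = ab[, 3],
                         formal_charge = fc),
      bonds = bonds)
  }
  mols
}

#' Write molecules to an SDF (V2000) file
#'
#' @param mols list of molecules.
#' @param path output file.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in mols) {
    n <- n_atoms(m)
    nb <- nrow(m$bonds)
    writeLines(c(m$id, "  fieldqsar", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb), con)
    co <- coords(m)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       co[, 1], co[, 2], co[, 3], m$atoms$element), con)
    if (nb > 0)
      writeLines(sprintf("%3d%3d%3d  0  0  0  0", m$bonds$i, m$bonds$j, m$bonds$order), con)
    chg <- which(m$atoms$formal_charge != 0)
    if (length(chg) > 0)
      writeLines(paste0("M  CHG", sprintf("%3d", length(chg)),
                        paste0(sprintf("%4d%4d", chg, m$atoms$formal_charge[chg]), collapse = "")), con)
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}

# ---- activities ------------------------------------------------------------

#' Read an activity table
#'
#' CSV with a `compound_id` column plus either `pic50` or `ic50_nM`.
#' IC50 values (nanomolar) are converted to pIC50 = -log10(IC50 in molar);
#' if both columns are present they must agree to 1e-6.
#'
#' @param path CSV file.
#' @return data.frame with columns `compound_id`, `pic50`.
#' @export
read_activities <- function(path) {
  if (!file.exists(path)) stop("activity file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"compound_id" %in% names(d)) stop("activity CSV lacks a 'compound_id' column")
  has_p <- "pic50" %in% names(d)
  has_i <- "ic50_nM" %in% names(d)
  if (!has_p && !has_i) stop("activity CSV needs a 'pic50' or 'ic50_nM' column")
  if (has_i) {
    p_from_i <- -log10(d$ic50_nM * 1e-9)
    if (has_p && any(abs(d$pic50 - p_from_i) > 1e-6, na.rm = TRUE))
      stop("pic50 and ic50_nM columns disagree beyond 1e-6")
    if (!has_p) d$pic50 <- p_from_i
  }
  d[, c("compound_id", "pic50")]
}
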