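# Gasteiger-Marsili partial equalization of orbital electronegativities.
#
# Electronegativity of an atom as a function of its charge Q is modelled as
# chi(Q) = a + b*Q + c*Q^2; in each iteration n charge flows across every
# bond from the less to the more electronegative atom in proportion to the
# electronegativity difference, scaled by the cation electronegativity of
# the donor atom and damped by (1/2)^n. Six iterations are the conventional
# fixed point for organic molecules.

# a, b, c per element/hybridization; chi_plus = a + b + c except hydrogen,
# whose cation electronegativity is fixed at 20.02.
.peoe_params <- local({
  p <- rbind(
    H      = c(7.17,  6.24, -0.56),
    C.sp3  = c(7.98,  9.18,  1.88),
    C.sp2  = c(8.79,  9.32,  1.51),
    C.sp   = c(10.39, 9.45,  0.73),
    N.sp3  = c(11.54, 10.82, 1.36),
    N.sp2  = c(12.87, 11.15, 0.85),
    N.sp   = c(15.68, 11.70, -0.27),
    O.sp3  = c(14.18, 12.92, 1.39),
    O.sp2  = c(17.07, 13.79, 0.47),
    F      = c(14.66, 13.85, 2.31),
    Cl     = c(11.00, 9.69,  1.35),
    Br     = c(10.08, 8.47,  1.16),
    I      = c(9.90,  7.96,  0.96),
    S      = c(10.14, 9.13,  1.38),
    P      = c(8.90,  8.24,  0.96))
  colnames(p) <- c("a", "b", "c")
  chi_plus <- p[, "a"] + p[, "b"] + p[, "c"]
  chi_plus["H"] <- 20.02
  list(p = p, chi_plus = chi_plus)
})

# crude hybridization from bond orders: sp if any triple bond or >=2 double
# bonds on the atom, sp2 if any double bond, else sp3
atom_hybridization <- function(m) {
  n <- n_atoms(m)
  ndouble <- ntriple <- integer(n)
  b <- m$bonds
  for (k in seq_len(nrow(b))) {
    if (b$order[k] == 2) {
      ndouble[b$i[k]] <- ndouble[b$i[k]] + 1L
      ndouble[b$j[k]] <- ndouble[b$j[k]] + 1L
    } else if (b$order[k] == 3) {
      ntriple[b$i[k]] <- ntriple[b$i[k]] + 1L
      ntriple[b$j[k]] <- ntriple[b$j[k]] + 1L
    }
  }
  ifelse(ntriple > 0 | ndouble >= 2, "sp", ifelse(ndouble > 0, "sp2", "sp3"))
}

peoe_param_key <- function(element, hyb) {
  key <- ifelse(element %in% c("C", "N", "O"), paste(element, hyb, sep = "."), element)
  bad <- !(key %in% rownames(.peoe_params$p))
  if (any(bad))
    stop("no PEOE parameters for element(s): ", paste(unique(element[bad]), collapse = ", "))
  key
}

#' Assign Gasteiger-Marsili (PEOE) partial charges
#'
#' Iterative partial equalization of orbital electronegativities with
#' geometric damping (1/2)^n. Initial charges are the formal charges; the
#' total charge is conserved exactly, so the assigned charges sum to the
#' molecule's net formal charge.
#'
#' @param mol molecule with explicit hydrogens (donor/acceptor hydrogens
#'   influence the charge distribution; embed via [read_molecules()] to get
#'   them).
#' @param iterations number of damped iterations (default 6, the
#'   conventional fixed point).
#' @return the molecule with `charges` populated (elementary-charge units).
#' @export
assign_peoe_charges <- function(mol, iterations = 6L) {
  n <- n_atoms(mol)
  key <- peoe_param_key(mol$atoms$element, atom_hybridization(mol))
  par <- .peoe_params$p[key, , drop = FALSE]
  chi_plus <- .peoe_params$chi_plus[key]
  q <- as.numeric(mol$atoms$formal_charge)
  b <- mol$bonds
  for (it in seq_len(iterations)) {
    damp <- 0.5^it
    chi <- par[, "a"] + par[, "b"] * q + par[, "c"] * q^2
    dq <- numeric(n)
    for (k in seq_len(nrow(b))) {
      i <- b$i[k]; j <- b$j[k]
      if (chi[i] == chi[j]) next
      if (chi[j] > chi[i]) {                 # i donates electron density to j
        t <- (chi[j] - chi[i]) / chi_plus[i] * damp
        dq[i] <- dq[i] + t; dq[j] <- dq[j] - t
      } else {
        t <- (chi[i] - chi[j]) / chi_plus[j] * damp
        dq[j] <- dq[j] + t; dq[i] <- dq[i] - t
      }
    }
    q <- q + dq
  }
  mol$charges <- q
  validate_molecule(mol)
  mol
}
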