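# Programmatic fixtures shared across the suite. Everything is built in
# code; the slower synthetic series are memoised so several test files can
# share one generation.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

fixture_series <- function(noise_sd = 0, seed = 1L, n = 33L) {
  cached(sprintf("series_%g_%d_%d", noise_sd, seed, n),
         generate_congeneric_series(n = n, seed = seed,
                                    planted = planted_model(noise_sd = noise_sd)))
}

fixture_smiles_mol <- function(smiles, id = "m") {
  m <- cached(paste0("smi_", smiles), parse_smiles(paste0(smiles, "\tm"))[[1]])
  m$id <- id
  m
}

# a bare molecule from coordinate/bond tables (no embedding round trip)
make_mol <- function(id, el, xyz, bonds = NULL, formal = 0L, charges = numeric(0)) {
  if (is.null(bonds)) bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  molecule(id, data.frame(element = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                          formal_charge = formal), bonds, charges)
}

# regular hexagon of aromatic (kekulized) carbons with hydrogens, in the
# z = 0 plane around `center`; returns atoms/bonds offset by `offset`
benzene_block <- function(center, offset = 0L) {
  ang <- (0:5) * pi / 3
  cx <- cbind(center[1] + 1.39 * cos(ang), center[2] + 1.39 * sin(ang), center[3])
  hx <- cbind(center[1] + 2.47 * cos(ang), center[2] + 2.47 * sin(ang), center[3])
  atoms <- data.frame(element = rep(c("C", "H"), each = 6),
                      x = c(cx[, 1], hx[, 1]), y = c(cx[, 2], hx[, 2]),
                      z = c(cx[, 3], hx[, 3]), formal_charge = 0L)
  ring <- data.frame(i = 1:6, j = c(2:6, 1), order = c(2L, 1L, 2L, 1L, 2L, 1L))
  ch <- data.frame(i = 1:6, j = 7:12, order = 1L)
  bonds <- rbind(ring, ch)
  bonds$i <- bonds$i + offset; bonds$j <- bonds$j + offset
  list(atoms = atoms, bonds = bonds, ring_center = center)
}

# formamide-like donor fragment: C(=O)-N(H); the N is a donor (and an
# excluded amide acceptor), the O an acceptor. N sits at `n_pos`, H along +y.
amide_block <- function(n_pos, offset = 0L) {
  atoms <- data.frame(
    element = c("C", "O", "N", "H", "H"),
    x = c(n_pos[1] + 1.35, n_pos[1] + 2.0, n_pos[1], n_pos[1], n_pos[1] + 1.45),
    y = c(n_pos[2], n_pos[2] + 1.0, n_pos[2], n_pos[2] + 1.01, n_pos[2] - 1.05),
    z = n_pos[3], formal_charge = 0L)
  bonds <- data.frame(i = c(1, 1, 3, 1) + offset, j = c(2, 3, 4, 5) + offset,
                      order = c(2L, 1L, 1L, 1L))
  list(atoms = atoms, bonds = bonds, donor_pos = n_pos)
}

# propane fragment (3 C + H each): one hydrophobe site at the C centroid
propane_block <- function(centroid, offset = 0L) {
  cx <- rbind(centroid + c(-1.5, 0, 0), centroid, centroid + c(1.5, 0, 0))
  hx <- cx + matrix(rep(c(0, 1.1, 0), each = 3), ncol = 3)
  atoms <- data.frame(element = rep(c("C", "H"), each = 3),
                      x = c(cx[, 1], hx[, 1]), y = c(cx[, 2], hx[, 2]),
                      z = c(cx[, 3], hx[, 3]), formal_charge = 0L)
  bonds <- data.frame(i = c(1, 2, 1, 2, 3) + offset, j = c(2, 3, 4, 5, 6) + offset,
                      order = 1L)
  list(atoms = atoms, bonds = bonds, centroid = colMeans(cx))
}

# a disconnected test molecule whose features realize a known DDHRR
# geometry: two amide donors, one propane hydrophobe, two benzene rings
ddhrr_molecule <- function(id = "ddhrr",
                           ring1 = c(0, 0, 0), ring2 = c(7, 0, 0),
                           d1 = c(2.0, 4.0, 0), d2 = c(5.0, -4.0, 0),
                           hctr = c(10, 4, 0)) {
  blocks <- list()
  atoms <- NULL; bonds <- NULL; off <- 0L
  for (b in list(benzene_block(ring1, 0), benzene_block(ring2, 0),
                 amide_block(d1, 0), amide_block(d2, 0), propane_block(hctr, 0))) {
    b$bonds$i <- b$bonds$i + off; b$bonds$j <- b$bonds$j + off
    atoms <- rbind(atoms, b$atoms); bonds <- rbind(bonds, b$bonds)
    off <- off + nrow(b$atoms)
  }
  molecule(id, atoms, bonds)
}

# apply a rigid motion (rotation about z by theta + translation) to a molecule
rigid_move <- function(m, theta = 0, shift = c(0, 0, 0)) {
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta),  cos(theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  xyz <- coords(m) %*% t(R)
  m$atoms[, c("x", "y", "z")] <- sweep(xyz, 2, shift, `+`)
  m
}

# independent superposition oracle: minimum RMSD over rigid motions found
# by direct numerical optimization over an angle-axis parameterization
oracle_superpose_rmsd <- function(P, Q) {
  rot <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    k <- v / th
    K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3, byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  }
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  obj <- function(v) sqrt(mean(rowSums((Pc %*% t(rot(v)) - Qc)^2)))
  best <- Inf
  for (s in list(c(0, 0, 0), c(pi, 0, 0), c(0, pi, 0), c(0, 0, pi)))
    best <- min(best, stats::optim(s, obj, method = "Nelder-Mead",
                                   control = list(maxit = 2000, reltol = 1e-14))$value)
  best
}
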