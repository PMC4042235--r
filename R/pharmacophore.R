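# Rule-based pharmacophore perception, common-hypothesis enumeration and
# survival scoring.
#
# Feature types follow the usual letters: A acceptor, D donor, H hydrophobe,
# N negative ionisable, P positive ionisable, R aromatic ring. Hypotheses of
# k sites are enumerated per active molecule, keyed by the sorted type
# letters plus a binned intersite-distance vector, and keys common to
# (almost) all actives become candidate hypotheses. Each hypothesis is then
# scored: site (alignment tightness), vector (direction agreement), volume
# (shared van der Waals volume), selectivity (rarity of the key), combined
# into the weighted survival score
#   S = Wsite*Ssite + Wvec*Svec + Wvol*Svol + Wsel*Ssel + Wrev^m - WE*dE + Wact*A.

#' Editable feature-perception rules
#'
#' @param donor_elements heavy elements that donate an H-bond when carrying
#'   a hydrogen.
#' @param acceptor_elements heavy elements with usable lone pairs.
#' @param exclude_amide_n drop amide/thioamide nitrogens from acceptors.
#' @param min_hydrophobe_size minimum number of contiguous
#'   carbons-with-only-C/H-neighbours forming a hydrophobe.
#' @param ring_sizes ring sizes considered for aromaticity.
#' @export
feature_rules <- function(donor_elements = c("N", "O"),
                          acceptor_elements = c("N", "O"),
                          exclude_amide_n = TRUE,
                          min_hydrophobe_size = 2L,
                          ring_sizes = c(5L, 6L)) {
  list(donor_elements = donor_elements, acceptor_elements = acceptor_elements,
       exclude_amide_n = exclude_amide_n,
       min_hydrophobe_size = as.integer(min_hydrophobe_size),
       ring_sizes = as.integer(ring_sizes))
}

adjacency_list <- function(m) {
  n <- n_atoms(m)
  adj <- vector("list", n)
  for (k in seq_len(nrow(m$bonds))) {
    i <- m$bonds$i[k]; j <- m$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

bond_order_lookup <- function(m) {
  key <- paste(pmin(m$bonds$i, m$bonds$j), pmax(m$bonds$i, m$bonds$j))
  stats::setNames(m$bonds$order, key)
}

# all simple rings of the requested sizes on the heavy-atom graph,
# deduplicated by vertex set (VF2 against a cycle pattern graph)
find_rings <- function(m, sizes = c(5L, 6L)) {
  heavy <- heavy_atoms(m)
  if (length(heavy) < min(sizes)) return(list())
  palette <- unique(m$atoms$element)
  g <- mol_graph(m, palette)
  g2 <- igraph::delete_vertex_attr(g, "color")   # ring search is element-blind
  rings <- list()
  seen <- character(0)
  for (s in sizes) {
    if (igraph::vcount(g2) < s) next
    cyc <- igraph::make_ring(s)
    maps <- igraph::subgraph_isomorphisms(cyc, g2, method = "vf2")
    for (mp in maps) {
      v <- attr(g, "atom_index")[as.integer(mp)]
      key <- paste(sort(v), collapse = "-")
      if (!(key %in% seen)) { seen <- c(seen, key); rings[[length(rings) + 1]] <- v }
    }
  }
  rings
}

# aromatic if every ring atom either takes part in a double bond to another
# ring member (kekule alternation) or is an N/O/S lone-pair contributor
ring_is_aromatic <- function(m, ring, orders) {
  el <- m$atoms$element[ring]
  for (i in seq_along(ring)) {
    a <- ring[i]
    others <- setdiff(ring, a)
    dbl <- any(orders[paste(pmin(a, others), pmax(a, others))] == 2, na.rm = TRUE)
    if (!dbl && !(el[i] %in% c("N", "O", "S"))) return(FALSE)
  }
  TRUE
}

ring_normal <- function(xyz) {
  c0 <- colMeans(xyz)
  s <- svd(sweep(xyz, 2, c0))
  n <- s$v[, 3]
  n / sqrt(sum(n^2))
}

feature_site <- function(type, position, direction = NULL, source_atoms = integer(0)) {
  if (!is.null(direction)) {
    nn <- sqrt(sum(direction^2))
    if (abs(nn - 1) > 1e-6) direction <- direction / nn
  }
  structure(list(type = type, position = as.numeric(position),
                 direction = direction, source_atoms = as.integer(source_atoms)),
            class = "feature_site")
}

#' Perceive pharmacophore feature sites
#'
#' Rule-based detection on a 3D molecule with explicit hydrogens:
#' * D — N/O carrying an H; site at the heavy atom, direction along the
#'   heavy-to-H bond.
#' * A — N/O with a lone pair; quaternary/positively charged and (by
#'   default) amide nitrogens are excluded.
#' * R — aromatic 5/6-ring; site at the centroid, direction = ring normal.
#' * H — connected group of >= 2 carbons none of which touches a
#'   heteroatom; site at the group centroid.
#' * N/P — negatively/positively charged groups (formal charge, plus the
#'   carboxylate oxygen pattern).
#'
#' @param mol molecule with 3D coordinates.
#' @param rules [feature_rules()].
#' @return list of `feature_site` objects (fields `type`, `position`,
#'   `direction`, `source_atoms`).
#' @export
perceive_features <- function(mol, rules = feature_rules()) {
  xyz <- coords(mol)
  if (all(abs(xyz) < 1e-12)) stop("molecule '", mol$id, "' has no 3D coordinates")
  el <- mol$atoms$element
  fc <- mol$atoms$formal_charge
  adj <- adjacency_list(mol)
  orders <- bond_order_lookup(mol)
  sites <- list()
  add <- function(s) sites[[length(sites) + 1]] <<- s

  is_amide_n <- function(a) {
    for (nb in adj[[a]]) {
      if (el[nb] != "C") next
      for (nb2 in adj[[nb]]) {
        if (nb2 == a) next
        o <- orders[paste(min(nb, nb2), max(nb, nb2))]
        if (!is.na(o) && o == 2 && el[nb2] %in% c("O", "S")) return(TRUE)
      }
    }
    FALSE
  }

  for (a in seq_along(el)) {
    if (el[a] == "H") next
    hs <- adj[[a]][el[adj[[a]]] == "H"]
    heavy_deg <- sum(el[adj[[a]]] != "H")
    # donors
    if (el[a] %in% rules$donor_elements && length(hs) > 0 && fc[a] <= 0) {
      dir <- xyz[hs[1], ] - xyz[a, ]
      add(feature_site("D", xyz[a, ], dir, c(a, hs[1])))
    }
    # acceptors: quaternary and (optionally) amide nitrogens have no free
    # lone pair and are excluded
    if (el[a] %in% rules$acceptor_elements && fc[a] <= 0) {
      excluded <- el[a] == "N" &&
        (length(adj[[a]]) >= 4 || (rules$exclude_amide_n && is_amide_n(a)))
      if (!excluded) add(feature_site("A", xyz[a, ], NULL, a))
    }
    # ionisable
    if (fc[a] < 0) add(feature_site("N", xyz[a, ], NULL, a))
    if (fc[a] > 0) add(feature_site("P", xyz[a, ], NULL, a))
  }

  # aromatic rings
  for (ring in find_rings(mol, rules$ring_sizes)) {
    if (ring_is_aromatic(mol, ring, orders)) {
      rxyz <- xyz[ring, , drop = FALSE]
      add(feature_site("R", colMeans(rxyz), ring_normal(rxyz), ring))
    }
  }

  # hydrophobes: components of carbons whose neighbours are all C or H
  plain_c <- which(el == "C" &
                     vapply(adj, function(nb) all(el[nb] %in% c("C", "H")), logical(1)))
  if (length(plain_c) >= rules$min_hydrophobe_size) {
    sub <- igraph::make_empty_graph(length(plain_c), directed = FALSE)
    eb <- m_bonds_between(mol, plain_c)
    if (nrow(eb) > 0) sub <- igraph::add_edges(sub, t(eb))
    comp <- igraph::components(sub)
    for (cc in seq_len(comp$no)) {
      members <- plain_c[comp$membership == cc]
      if (length(members) >= rules$min_hydrophobe_size)
        add(feature_site("H", colMeans(xyz[members, , drop = FALSE]), NULL, members))
    }
  }
  sites
}

m_bonds_between <- function(m, atoms) {
  b <- m$bonds
  keep <- b$i %in% atoms & b$j %in% atoms
  cbind(match(b$i[keep], atoms), match(b$j[keep], atoms))
}

#' @export
print.feature_site <- function(x, ...) {
  cat(sprintf("<site %s at (%.2f, %.2f, %.2f)%s>\n", x$type,
              x$position[1], x$position[2], x$position[3],
              if (!is.null(x$direction)) " with direction" else ""))
  invisible(x)
}

site_types <- function(sites) vapply(sites, `[[`, character(1), "type")
site_positions <- function(sites) do.call(rbind, lapply(sites, `[[`, "position"))

# canonical (type-sorted, within-type permutation-minimized) binned distance
# key of a site combination; returns the canonical ordering too
canonical_site_key <- function(sites, distance_bin) {
  ty <- site_types(sites)
  ord0 <- order(ty)
  groups <- split(ord0, ty[ord0])
  perms_of <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms_of(v[-i]))
      out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  group_perms <- lapply(groups, perms_of)
  combos <- expand.grid(lapply(group_perms, seq_along), KEEP.OUT.ATTRS = FALSE)
  pos <- site_positions(sites)
  best <- NULL
  for (r in seq_len(nrow(combos))) {
    ord <- unlist(lapply(seq_along(group_perms),
                         function(g) group_perms[[g]][[combos[r, g]]]),
                  use.names = FALSE)
    d <- as.vector(stats::dist(pos[ord, , drop = FALSE]))
    bins <- as.integer(round(d / distance_bin))
    key <- paste(bins, collapse = ",")
    if (is.null(best) || key < best$key)
      best <- list(key = key, order = ord, distances = d)
  }
  list(letters = paste(sort(ty), collapse = ""), key = best$key,
       order = best$order, distances = best$distances)
}

#' Pharmacophore hypothesis object
#'
#' @param id character like `"DDHRR.8"` (type letters + variant index).
#' @param sites list of feature sites in canonical (type-sorted) order.
#' @param intersite_distances pairwise distances (angstrom) in canonical
#'   pair order.
#' @param match_count number of actives sharing the key.
#' @param selectivity rarity score of the key (see
#'   [enumerate_hypotheses()]).
#' @param ref_molecule the representative molecule the geometry was taken
#'   from (used for volume scoring).
#' @export
pharmacophore_hypothesis <- function(id, sites, intersite_distances,
                                     match_count = NA_integer_,
                                     selectivity = NA_real_,
                                     ref_molecule = NULL) {
  structure(list(id = id, sites = sites,
                 intersite_distances = as.numeric(intersite_distances),
                 match_count = as.integer(match_count),
                 selectivity = as.numeric(selectivity),
                 ref_molecule = ref_molecule),
            class = "pharmacophore_hypothesis")
}

#' @export
print.pharmacophore_hypothesis <- function(x, ...) {
  cat(sprintf("<hypothesis %s: %d sites, %d matches, selectivity %.3f>\n",
              x$id, length(x$sites), x$match_count, x$selectivity))
  invisible(x)
}

#' Enumerate common pharmacophore hypotheses
#'
#' For every active all k-site combinations of its perceived features are
#' keyed by (sorted type letters, binned canonical intersite-distance
#' vector). Keys present in at least `min_match` actives become common
#' hypotheses; geometry is taken from the first active containing the key.
#' Variants sharing a letter set are numbered `.1, .2, ...` by decreasing
#' match count, then lexicographic key. The selectivity stored on each
#' hypothesis is the rarity of its key, -log10 of the fraction of all
#' enumerated combinations that map to it.
#'
#' @param actives list of molecules (>= 2).
#' @param max_sites sites per hypothesis (default 5, range 3..7).
#' @param distance_bin bin width for intersite distances (angstrom).
#' @param min_match minimum number of actives sharing the key; default
#'   `ceiling(0.9 * length(actives))`.
#' @param rules [feature_rules()].
#' @return list of [pharmacophore_hypothesis()] sorted by decreasing match
#'   count; empty (with a warning) when no key is common.
#' @export
enumerate_hypotheses <- function(actives, max_sites = 5L, distance_bin = 1.0,
                                 min_match = NULL, rules = feature_rules()) {
  stopifnot(length(actives) >= 2, max_sites >= 3, max_sites <= 7)
  if (is.null(min_match)) min_match <- ceiling(0.9 * length(actives))
  tally <- new.env(parent = emptyenv())
  total_combos <- 0
  for (mi in seq_along(actives)) {
    sites <- perceive_features(actives[[mi]], rules)
    if (length(sites) < max_sites) next
    combos <- utils::combn(length(sites), max_sites, simplify = FALSE)
    seen_here <- character(0)
    for (cb in combos) {
      ck <- canonical_site_key(sites[cb], distance_bin)
      full <- paste(ck$letters, ck$key, sep = "|")
      total_combos <- total_combos + 1
      rec <- if (!is.null(tally[[full]])) tally[[full]] else
        list(letters = ck$letters, key = ck$key, mols = integer(0), n_combos = 0,
             rep_mol = mi, rep_sites = sites[cb][ck$order], rep_dist = ck$distances)
      rec$n_combos <- rec$n_combos + 1
      if (!(full %in% seen_here)) {
        rec$mols <- c(rec$mols, mi)
        seen_here <- c(seen_here, full)
      }
      tally[[full]] <- rec
    }
  }
  recs <- Filter(function(r) length(r$mols) >= min_match,
                 mget(ls(tally), envir = tally))
  if (length(recs) == 0) {
    warning("no site combination is common to ", min_match, " of ",
            length(actives), " actives")
    return(list())
  }
  counts <- vapply(recs, function(r) length(r$mols), integer(1))
  keys <- vapply(recs, `[[`, character(1), "key")
  letters <- vapply(recs, `[[`, character(1), "letters")
  out <- list()
  for (lt in sort(unique(letters))) {
    sel <- which(letters == lt)
    sel <- sel[order(-counts[sel], keys[sel])]
    for (v in seq_along(sel)) {
      r <- recs[[sel[v]]]
      out[[length(out) + 1]] <- pharmacophore_hypothesis(
        id = paste0(lt, ".", v), sites = r$rep_sites,
        intersite_distances = r$rep_dist, match_count = length(r$mols),
        selectivity = -log10(r$n_combos / total_combos),
        ref_molecule = actives[[r$rep_mol]])
    }
  }
  out[order(-vapply(out, `[[`, integer(1), "match_count"))]
}

#' Survival-score weights
#'
#' Weights of the survival score
#' `S = Wsite*Ssite + Wvec*Svec + Wvol*Svol + Wsel*Ssel + Wrev^m - WE*dE + Wact*A`.
#' The reversed-hypothesis term `Wrev^m` is disabled by default
#' (`w_rev = 0`); conformer energy and reference-activity terms default to
#' weight 0 so the score depends only on geometry unless enabled.
#'
#' @param w_site,w_vec,w_vol,w_sel,w_rev,w_energy,w_act nonnegative weights.
#' @param m integer exponent on the reversed term.
#' @export
survival_weights <- function(w_site = 1, w_vec = 1, w_vol = 1, w_sel = 1,
                             w_rev = 0, w_energy = 0, w_act = 0, m = 1L) {
  stopifnot(all(c(w_site, w_vec, w_vol, w_sel, w_rev, w_energy, w_act) >= 0))
  list(w_site = w_site, w_vec = w_vec, w_vol = w_vol, w_sel = w_sel,
       w_rev = w_rev, w_energy = w_energy, w_act = w_act, m = as.integer(m))
}

#' Evaluate the survival score from its components
#'
#' The weighted sum itself, exposed so scores can be recomputed or audited
#' from reported components.
#'
#' @param s_site,s_vec,s_vol,s_sel component scores.
#' @param w [survival_weights()].
#' @param delta_e conformer relative energy (kcal/mol).
#' @param activity reference-ligand activity (pIC50).
#' @export
survival_score <- function(s_site, s_vec, s_vol, s_sel = 0,
                           w = survival_weights(), delta_e = 0, activity = 0) {
  w$w_site * s_site + w$w_vec * s_vec + w$w_vol * s_vol + w$w_sel * s_sel +
    w$w_rev^w$m - w$w_energy * delta_e + w$w_act * activity
}

#' Score a hypothesis against active (and inactive) sets
#'
#' Every active is matched to the hypothesis ([match_molecule()]); matched
#' actives contribute a site score (1 - RMSD/tolerance, floored at 0), a
#' vector score (mean cosine of matched direction vectors) and a volume
#' score (shared / union van der Waals volume against the reference
#' ligand). The means over matched actives enter the survival score; when
#' inactives are supplied, `survival_inactive` = survival minus the same
#' weighted geometric score over matched inactives.
#'
#' @param h pharmacophore_hypothesis.
#' @param actives list of molecules.
#' @param inactives optional list of molecules.
#' @param w [survival_weights()].
#' @param tolerance site-match tolerance (angstrom).
#' @param delta_e,reference_activity optional energy/activity terms.
#' @return object of class `hypothesis_scores`.
#' @export
score_hypothesis <- function(h, actives, inactives = NULL,
                             w = survival_weights(), tolerance = 2.0,
                             delta_e = 0, reference_activity = 0) {
  geo <- function(mols) {
    res <- lapply(mols, function(mm) match_molecule(h, mm, tolerance))
    ok <- vapply(res, `[[`, logical(1), "matched")
    res <- res[ok]
    if (length(res) == 0) return(list(n = 0L, site = 0, vec = 0, vol = 0))
    list(n = length(res),
         site = mean(vapply(res, function(r) max(0, 1 - r$align_score / tolerance),
                            numeric(1))),
         vec = mean(vapply(res, `[[`, numeric(1), "vector_score")),
         vol = mean(vapply(res, `[[`, numeric(1), "volume_score")))
  }
  ga <- geo(actives)
  if (ga$n == 0) stop("hypothesis ", h$id, " matches none of the actives")
  surv <- survival_score(ga$site, ga$vec, ga$vol, h$selectivity, w,
                         delta_e, reference_activity)
  surv_inact <- NA_real_
  if (!is.null(inactives) && length(inactives) > 0) {
    gi <- geo(inactives)
    surv_inact <- surv - (w$w_site * gi$site + w$w_vec * gi$vec + w$w_vol * gi$vol)
  } else if (!is.null(inactives)) {
    message("no inactives supplied; survival_inactive omitted")
  }
  structure(list(id = h$id, site_score = ga$site, vector_score = ga$vec,
                 volume_score = ga$vol, selectivity = h$selectivity,
                 energy_term = delta_e, reference_activity = reference_activity,
                 matches = ga$n, survival = surv, survival_inactive = surv_inact),
            class = "hypothesis_scores")
}

#' @export
print.hypothesis_scores <- function(x, ...) {
  cat(sprintf("<scores %s: survival %.4f (site %.4f, vec %.4f, vol %.4f, sel %.4f), matches %d>\n",
              x$id, x$survival, x$site_score, x$vector_score, x$volume_score,
              x$selectivity, x$matches))
  invisible(x)
}

#' Rank scored hypotheses
#'
#' Primary sort by survival descending; ties broken by selectivity
#' descending. Deterministic for permuted input.
#'
#' @param scored list of `hypothesis_scores` (or a list of lists with
#'   `survival` and `selectivity`).
#' @return the list reordered.
#' @export
rank_hypotheses <- function(scored) {
  stopifnot(length(scored) > 0)
  surv <- vapply(scored, `[[`, numeric(1), "survival")
  sel <- vapply(scored, `[[`, numeric(1), "selectivity")
  id <- vapply(scored, function(s) as.character(s$id), character(1))
  scored[order(-surv, -sel, id)]
}

#' Write a hypothesis as JSON
#' @param h pharmacophore_hypothesis.
#' @param path output file.
#' @param scores optional `hypothesis_scores` to embed.
#' @export
write_hypothesis_json <- function(h, path, scores = NULL) {
  j <- list(id = h$id,
            sites = lapply(h$sites, function(s)
              list(type = s$type, position = s$position, direction = s$direction)),
            distances = h$intersite_distances,
            match_count = h$match_count, selectivity = h$selectivity)
  if (!is.null(scores)) j$scores <- unclass(scores)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
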