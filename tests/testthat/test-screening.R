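# Hypothesis matching, the published-model fixture, library screening and
# external-score merging.

oracle_min_assignment_rmsd <- function(sites, h_sites) {
  ty_m <- vapply(sites, `[[`, character(1), "type")
  ty_h <- vapply(h_sites, `[[`, character(1), "type")
  Q <- do.call(rbind, lapply(h_sites, `[[`, "position"))
  best <- Inf
  # brute force over permutations of same-type groups
  perm_all <- function(v) if (length(v) <= 1) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perm_all(v[-i]), function(p) c(v[i], p))))
  groups <- lapply(unique(ty_h), function(t) which(ty_m == t))
  names(groups) <- unique(ty_h)
  assigns <- list(integer(length(ty_h)))
  for (t in unique(ty_h)) {
    slots <- which(ty_h == t)
    opts <- perm_all(groups[[t]])
    opts <- lapply(opts, function(p) p[seq_along(slots)])
    assigns <- do.call(c, lapply(assigns, function(a)
      lapply(opts, function(p) { a[slots] <- p; a })))
  }
  for (a in assigns) {
    P <- do.call(rbind, lapply(sites[a], `[[`, "position"))
    best <- min(best, oracle_superpose_rmsd(P, Q))
  }
  best
}

ddhrr_hypothesis <- function() {
  actives <- list(ddhrr_molecule("a1"),
                  rigid_move(ddhrr_molecule("a2"), 0.6, c(4, 1, -2)),
                  rigid_move(ddhrr_molecule("a3"), -1.2, c(-3, 2, 5)))
  hyps <- enumerate_hypotheses(actives, max_sites = 5)
  letters <- vapply(hyps, function(h)
    paste(sort(vapply(h$sites, `[[`, character(1), "type")), collapse = ""),
    character(1))
  hyps[letters == "DDHRR"][[1]]
}

test_that("a molecule matches its own hypothesis with zero alignment error", {
  h <- ddhrr_hypothesis()
  mr <- match_molecule(h, rigid_move(ddhrr_molecule("probe"), 1.3, c(9, -4, 2)))
  expect_true(mr$matched)
  expect_lt(mr$align_score, 1e-8)
  expect_equal(mr$vector_score, 1, tolerance = 1e-8)
  expect_equal(mr$fitness, 1 * (1 - 0) + 1 * mr$vector_score + 1 * mr$volume_score,
               tolerance = 1e-10)
})

test_that("a missing feature type means no match, and matches obey the tolerance", {
  h <- ddhrr_hypothesis()
  norings <- fixture_smiles_mol("NC(=S)NCC", "nr")   # donors but no ring
  expect_false(match_molecule(h, norings)$matched)
  tsc <- fixture_smiles_mol("NC(=S)N/N=C/c1ccccc1", "tsc")  # only one ring
  expect_false(match_molecule(h, tsc)$matched)
})

test_that("site displacement is reported as the least-squares RMSD", {
  h <- ddhrr_hypothesis()
  # displace whole feature-bearing fragments of a fresh copy by 0.5 A in
  # balanced directions; the expected align score is the independent
  # numerical superposition optimum over the displaced site positions
  m <- ddhrr_molecule("disp",
                      ring1 = c(0, 0, 0) + c(0.5, 0, 0),
                      ring2 = c(7, 0, 0) + c(-0.5, 0, 0),
                      d1 = c(2.0, 4.0, 0) + c(0, 0.5, 0),
                      d2 = c(5.0, -4.0, 0) + c(0, -0.5, 0),
                      hctr = c(10, 4, 0))
  mr <- match_molecule(h, m)
  expect_true(mr$matched)
  sites_m <- perceive_features(m)
  keep <- vapply(sites_m, `[[`, character(1), "type") %in% c("D", "H", "R")
  P <- do.call(rbind, lapply(sites_m[keep], `[[`, "position"))
  Q <- do.call(rbind, lapply(h$sites, `[[`, "position"))
  # canonical orders differ; take the best over type-respecting assignments
  expect_equal(mr$align_score,
               oracle_min_assignment_rmsd(sites_m[keep], h$sites),
               tolerance = 1e-4)
  expect_gt(mr$align_score, 0.2)
  expect_lt(mr$align_score, 0.8)
})


test_that("the published-model fixture encodes the reported equation", {
  pub <- published_model()
  expect_length(pub$descriptor_names, 4)
  expect_identical(predict(pub, setNames(rep(0, 4), pub$descriptor_names)),
                   5.73211)
  expect_lt(pub$coefficients[["E_463"]], 0)   # the negative contributor
  expect_gt(pub$coefficients[["E_86"]], 0)
})

test_that("screening ranks actives and planted potent congeners sensibly", {
  series <- fixture_series(noise_sd = 0, seed = 1)
  m <- series$matrix
  split <- activity_ranked_split(m, 5)
  sel <- stepwise_forward_select(m, split, 4)
  model <- fit_pls(m, split, sel, 4)
  ord <- order(-m$activities)
  top_mol <- series$molecules[[ord[1]]]
  hyps <- enumerate_hypotheses(list(top_mol, top_mol), max_sites = 4)
  h <- hyps[[1]]
  lib <- series$molecules[ord[1:8]]
  hits <- screen_library(h, lib, model, series$grid, top_n = 5)
  expect_lte(nrow(hits), 5)
  expect_true(all(hits$matched))
  expect_true(all(hits$align_score <= 2.0))
  expect_true(all(diff(hits$fitness) <= 1e-12))
  # predicted activity equals the model applied to the computed descriptors
  # (no hidden rescaling): recompute for the top hit
  top <- series$molecules[[match(hits$compound_id[1],
                                 vapply(series$molecules, `[[`, "", "id"))]]
  mr <- match_molecule(h, top)
  f <- compute_fields(assign_peoe_charges(mr$molecule), series$grid)
  need <- parse_descriptor_name(model$descriptor_names)
  vals <- f[cbind(need$index, match(need$field_type, colnames(f)))]
  expect_equal(hits$predicted_activity[1],
               predict(model, setNames(vals, model$descriptor_names)),
               tolerance = 1e-10)
  expect_equal(nrow(screen_library(h, lib, model, series$grid, top_n = 2)), 2)
})

test_that("external score merging attaches by id and reranks on request", {
  res <- data.frame(compound_id = c("x", "y", "z"), matched = TRUE,
                    align_score = 0.1, vector_score = 0.9, volume_score = 0.5,
                    fitness = c(2.2, 2.0, 1.8),
                    predicted_activity = 6, external_score = NA_real_)
  tf <- tempfile(fileext = ".csv")
  # empty score table leaves results untouched
  writeLines("compound_id,xp_score", tf)
  expect_identical(merge_external_scores(res, tf), res)
  # partial coverage warns and fills what it can
  writeLines(c("compound_id,xp_score", "x,-7.575686", "y,-7.972908"), tf)
  expect_warning(out <- merge_external_scores(res, tf), "z")
  expect_equal(out$external_score[1:2], c(-7.575686, -7.972908))
  # docking convention: more negative first after rerank
  out2 <- suppressWarnings(merge_external_scores(res, tf, rerank = TRUE))
  expect_equal(out2$compound_id[1], "y")
  expect_equal(out2$external_score[1], -7.972908)
  writeLines(c("id,score", "x,1"), tf)
  expect_error(merge_external_scores(res, tf), "compound_id")
})
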