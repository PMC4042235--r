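# Feature perception, common-hypothesis enumeration and survival scoring.

site_types_of <- function(h) vapply(h$sites, `[[`, character(1), "type")

test_that("rule-based perception finds the expected sites on small molecules", {
  bz <- fixture_smiles_mol("c1ccccc1", "bz")
  ty <- vapply(perceive_features(bz), `[[`, character(1), "type")
  expect_equal(sum(ty == "R"), 1)
  expect_equal(sum(ty %in% c("D", "A")), 0)
  water <- fixture_smiles_mol("O", "water")
  tw <- vapply(perceive_features(water), `[[`, character(1), "type")
  expect_equal(sort(tw), c("A", "D"))
  tsc <- fixture_smiles_mol("NC(=S)N/N=C/c1ccccc1", "tsc")
  tt <- vapply(perceive_features(tsc), `[[`, character(1), "type")
  expect_gte(sum(tt == "D"), 2)    # terminal NH2 and hydrazide NH
  expect_gte(sum(tt == "R"), 1)    # the phenyl ring
  # ionisable groups by formal charge
  ac <- fixture_smiles_mol("CC(=O)[O-]", "acet")
  expect_true("N" %in% vapply(perceive_features(ac), `[[`, character(1), "type"))
  expect_error(perceive_features(make_mol("flat", "C", matrix(0, 1, 3))),
               "coordinates")
})

test_that("aromatic ring sites sit at the centroid with a unit normal", {
  bz <- fixture_smiles_mol("c1ccccc1", "bz")
  r <- Filter(function(s) s$type == "R", perceive_features(bz))[[1]]
  ring_xyz <- coords(bz)[bz$atoms$element == "C", ]
  expect_equal(r$position, unname(colMeans(ring_xyz)), tolerance = 1e-8)
  expect_equal(sqrt(sum(r$direction^2)), 1, tolerance = 1e-6)
})

test_that("feature sites move covariantly under rigid motion", {
  m <- ddhrr_molecule()
  f1 <- perceive_features(m)
  m2 <- rigid_move(m, theta = 0.8, shift = c(2, -3, 1))
  f2 <- perceive_features(m2)
  expect_equal(vapply(f1, `[[`, character(1), "type"),
               vapply(f2, `[[`, character(1), "type"))
  R <- matrix(c(cos(0.8), -sin(0.8), 0, sin(0.8), cos(0.8), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  for (k in seq_along(f1))
    expect_equal(f2[[k]]$position,
                 as.vector(R %*% f1[[k]]$position) + c(2, -3, 1),
                 tolerance = 1e-8)
})

test_that("a constructed 3-molecule set yields the shared DDHRR hypothesis", {
  actives <- list(ddhrr_molecule("a1"),
                  rigid_move(ddhrr_molecule("a2"), 0.6, c(4, 1, -2)),
                  rigid_move(ddhrr_molecule("a3"), -1.2, c(-3, 2, 5)))
  hyps <- enumerate_hypotheses(actives, max_sites = 5, distance_bin = 1.0)
  expect_gt(length(hyps), 0)
  letters <- vapply(hyps, function(h)
    paste(sort(site_types_of(h)), collapse = ""), character(1))
  ddhrr <- hyps[letters == "DDHRR"]
  expect_gt(length(ddhrr), 0)
  expect_true(all(vapply(ddhrr, `[[`, integer(1), "match_count") == 3))
  # id letters match the site-type multiset
  expect_match(ddhrr[[1]]$id, "^DDHRR\\.[0-9]+$")
  # intersite distances are the pairwise distances of the stored sites
  pos <- do.call(rbind, lapply(ddhrr[[1]]$sites, `[[`, "position"))
  expect_equal(sort(ddhrr[[1]]$intersite_distances),
               sort(as.vector(dist(pos))), tolerance = 1e-8)
})

test_that("molecules sharing no feature key give an empty result with warning", {
  a <- fixture_smiles_mol("CCCCCC", "hex")      # hydrophobe only
  b <- fixture_smiles_mol("OCC(O)CO", "triol")  # donors/acceptors only
  expect_warning(out <- enumerate_hypotheses(list(a, b), max_sites = 3),
                 "common")
  expect_length(out, 0)
})

test_that("identical molecules make every combination common", {
  m <- ddhrr_molecule()
  hyps <- enumerate_hypotheses(list(m, m), max_sites = 4)
  expect_gt(length(hyps), 0)
  expect_true(all(vapply(hyps, `[[`, integer(1), "match_count") == 2))
})

test_that("the survival score is exactly the weighted component sum", {
  set.seed(77)
  for (i in 1:10) {
    w <- survival_weights(w_site = runif(1, 0, 2), w_vec = runif(1, 0, 2),
                          w_vol = runif(1, 0, 2), w_sel = runif(1, 0, 2),
                          w_rev = runif(1, 0, 1), w_energy = runif(1, 0, 1),
                          w_act = runif(1, 0, 1), m = sample(1:3, 1))
    s <- runif(4); de <- runif(1, 0, 5); act <- runif(1, 5, 8)
    expect_equal(survival_score(s[1], s[2], s[3], s[4], w, de, act),
                 w$w_site * s[1] + w$w_vec * s[2] + w$w_vol * s[3] +
                   w$w_sel * s[4] + w$w_rev^w$m - w$w_energy * de + w$w_act * act,
                 tolerance = 1e-12)
  }
  # the reported component scores of a chosen hypothesis sum under unit weights
  expect_equal(survival_score(0.318008, 0.908012, 0.581835, 0,
                              survival_weights(1, 1, 1, 1, 0, 0, 0)),
               1.807855, tolerance = 1e-12)
})

test_that("scoring a hypothesis against its own actives is near-maximal", {
  actives <- list(ddhrr_molecule("a1"),
                  rigid_move(ddhrr_molecule("a2"), 0.6, c(4, 1, -2)))
  hyps <- enumerate_hypotheses(actives, max_sites = 5)
  letters <- vapply(hyps, function(h)
    paste(sort(site_types_of(h)), collapse = ""), character(1))
  h <- hyps[letters == "DDHRR"][[1]]
  sc <- score_hypothesis(h, actives)
  expect_equal(sc$matches, 2)
  expect_equal(sc$site_score, 1, tolerance = 1e-6)   # identical geometry
  expect_equal(sc$vector_score, 1, tolerance = 1e-6)
  expect_equal(sc$volume_score, 1, tolerance = 1e-6)
  expect_equal(sc$survival,
               survival_score(sc$site_score, sc$vector_score, sc$volume_score,
                              h$selectivity),
               tolerance = 1e-12)
})

test_that("ranking is by survival then selectivity and permutation-stable", {
  mk <- function(id, surv, sel)
    structure(list(id = id, survival = surv, selectivity = sel),
              class = "hypothesis_scores")
  a <- mk("A.1", 2.0, 1.0); b <- mk("B.1", 2.0, 1.5); c <- mk("C.1", 2.5, 0.1)
  r1 <- rank_hypotheses(list(a, b, c))
  expect_equal(vapply(r1, `[[`, character(1), "id"), c("C.1", "B.1", "A.1"))
  r2 <- rank_hypotheses(list(c, a, b))
  expect_equal(vapply(r2, `[[`, character(1), "id"),
               vapply(r1, `[[`, character(1), "id"))
  expect_equal(rank_hypotheses(list(a))[[1]]$id, "A.1")
})
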