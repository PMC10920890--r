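test_that("log-odds identities and sign convention hold", {
  p <- stats::setNames(rep(1 / 20, 20), aa_alphabet())
  expect_equal(log_odds(p, "ALA", "MET"), 0)   # equal probabilities
  p2 <- p
  p2["MET"] <- 0.8; p2["ALA"] <- 0.2
  p2 <- p2 / sum(p2)
  expect_equal(log_odds(p2, "ALA", "MET"), log(4), tolerance = 1e-12)
  expect_gt(log_odds(p2, "ALA", "MET"), 0)     # favorable substitution
  # antisymmetry and wt->wt zero for an arbitrary profile
  set.seed(4)
  q <- runif(20); q <- q / sum(q); names(q) <- aa_alphabet()
  for (pair in list(c("TRP", "GLY"), c("A", "V"))) {
    expect_equal(log_odds(q, pair[1], pair[2]),
                 -log_odds(q, pair[2], pair[1]))
  }
  expect_equal(log_odds(q, "LYS", "LYS"), 0)
  expect_error(log_odds(q, "XXX", "ALA"), "unknown amino-acid")
})

test_that("ensembling averages member probabilities", {
  m1 <- tiny_model(seed = 1)
  m2 <- tiny_model(seed = 2)
  m3 <- tiny_model(seed = 3)
  set.seed(9)
  grids <- lapply(1:3, function(i) array(rnorm(8^3 * 3), c(8, 8, 8, 3)))
  p1 <- predict_proba(m1, grids)
  p2 <- predict_proba(m2, grids)
  p3 <- predict_proba(m3, grids)
  # single model passes through unchanged
  expect_equal(ensemble_predict_grids(list(m1), grids), p1)
  # two models: elementwise mean
  expect_equal(ensemble_predict_grids(list(m1, m2), grids), (p1 + p2) / 2)
  # three models match the direct average oracle
  expect_lt(max(abs(ensemble_predict_grids(list(m1, m2, m3), grids) -
                      (p1 + p2 + p3) / 3)), 1e-9)
  # an ensemble of identical models equals the single model exactly
  expect_equal(ensemble_predict_grids(list(m1, m1, m1), grids), p1)
})

test_that("zero-shot benchmark matches brute-force correlations", {
  fx <- make_mutation_table(10, rho = 0.6, seed = 3)
  bench <- zero_shot_benchmark(NULL, NULL, fx$table, profiles = fx$profiles)
  sc <- bench$scores$log_odds
  # independent oracle: stats::cor on the scored values
  expect_equal(bench$correlations$pearson[1],
               stats::cor(sc, fx$table$dTm, method = "pearson"),
               tolerance = 1e-12)
  expect_equal(bench$correlations$spearman[1],
               stats::cor(sc, fx$table$dTm, method = "spearman"),
               tolerance = 1e-12)
  # row order invariance
  perm <- sample(nrow(fx$table))
  bench2 <- zero_shot_benchmark(NULL, NULL, fx$table[perm, ],
                                profiles = fx$profiles)
  expect_equal(bench2$correlations, bench$correlations, tolerance = 1e-12)
})

test_that("a planted perfect relation gives correlation 1 and ddG flips sign", {
  fx <- make_mutation_table(25, rho = 1, seed = 8)
  tab <- fx$table
  tab$ddG <- -tab$dTm   # destabilizing convention mirrors a ddG columns
  bench <- zero_shot_benchmark(NULL, NULL, tab, profiles = fx$profiles)
  cr <- bench$correlations
  expect_equal(cr$pearson[cr$property == "dTm"], 1, tolerance = 1e-9)
  expect_equal(cr$spearman[cr$property == "dTm"], 1, tolerance = 1e-9)
  expect_equal(cr$pearson[cr$property == "ddG"], -1, tolerance = 1e-9)
  expect_equal(cr$spearman[cr$property == "ddG"], -1, tolerance = 1e-9)
})

test_that("too few scorable mutations yields absent correlations", {
  fx <- make_mutation_table(2, rho = 1, seed = 2)
  bench <- zero_shot_benchmark(NULL, NULL, fx$table, profiles = fx$profiles)
  expect_true(is.na(bench$correlations$pearson[1]))
  expect_equal(bench$correlations$n[1], 2)
})

test_that("wild-type mismatches are skipped through the structure path", {
  s <- suppressWarnings(annotate_structure(make_toy_structure(5)))
  models <- list(build_model(model_config(n_residual_blocks = 0,
                                          base_width = 2, seed = 1)))
  tab <- tibble::tibble(structure = "toy", chain = "A", position = c(2, 3),
                        wt = c("ALA", "TRP"), mut = c("MET", "GLY"),
                        dTm = c(1, -1))
  expect_message(
    bench <- zero_shot_benchmark(models, list(toy = s), tab),
    "skipped")
  expect_equal(bench$n_skipped, 1L)              # TRP row mismatches ALA
  expect_false(is.na(bench$scores$log_odds[1]))  # matching row scored
})

test_that("design ranking sorts by log-odds with distance annotations", {
  s <- suppressWarnings(annotate_structure(
    make_toy_structure(5, placements = list(
      list(element = "P", residue = 2, distance = 4.0)))))
  models <- list(build_model(model_config(n_residual_blocks = 0,
                                          base_width = 2, seed = 1)))
  rep_ <- rank_designs(s, models)
  expect_equal(nrow(rep_), 5)
  expect_true(all(diff(rep_$log_odds) <= 0))           # sorted descending
  expect_true(all(c("wt_aa", "best_mut", "ligand_distance") %in% names(rep_)))
  expect_true(all(rep_$best_mut != rep_$wt_aa))
  # distance filter semantics
  near <- rank_designs(s, models, max_ligand_distance = 6)
  expect_true(all(near$ligand_distance <= 6))
  expect_lt(nrow(near), 5)
  # top_k cap
  expect_equal(nrow(rank_designs(s, models, top_k = 2)), 2)
})

test_that("ligand atoms in the cube change the input tensor", {
  # the pipeline must not silently drop non-protein atoms: the same residue
  # with and without a nearby ligand produces different voxel tensors
  s_apo <- suppressWarnings(annotate_structure(make_toy_structure(5)))
  s_holo <- suppressWarnings(annotate_structure(
    make_toy_structure(5, placements = list(
      list(element = "P", residue = 3, distance = 3.0)))))
  g_apo <- voxelize(extract_microenvironment(s_apo, "A", 3))
  g_holo <- voxelize(extract_microenvironment(s_holo, "A", 3))
  expect_gt(max(abs(g_holo - g_apo)), 0)
  # and the P channel specifically carries the ligand
  expect_true(all(g_apo[, , , 6] == 0))
  expect_gt(max(g_holo[, , , 6]), 0)
})
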