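# Bias metrics: DOE, doppelganger, AVE, ML separability, report assembly.

test_that("DOE hits its analytic limits", {
  ident <- matrix(rep(c(1.2, -3, 0.5), 9), 9, 3, byrow = TRUE)
  expect_equal(as.numeric(doe_score(ident[1:4, ], ident[5:9, ])), 0)
  sep <- make_separable_sets(5, 20, 3, 100, seed = 2)
  expect_equal(as.numeric(doe_score(sep$actives, sep$decoys)), 0.5)
  expect_error(doe_score(ident[1, , drop = FALSE], ident[2:5, ]), "2 actives")
})

test_that("DOE equals the brute-force enumeration oracle", {
  # fixed 1-D example, hand-traceable
  a <- matrix(c(0, 1, 2)); d <- matrix(c(0.5, 1.5, 3, 4))
  expect_equal(as.numeric(doe_score(a, d)), 0.1875, tolerance = 1e-12)
  set.seed(99)
  got <- numeric(40); want <- numeric(40)
  for (i in 1:40) {
    na <- sample(2:10, 1); nd <- sample(1:20, 1); k <- sample(1:3, 1)
    actives <- matrix(round(rnorm(na * k), sample(0:2, 1)), na, k)
    decoys <- matrix(round(rnorm(nd * k), sample(0:2, 1)), nd, k)
    got[i] <- as.numeric(doe_score(actives, decoys))
    want[i] <- oracle_doe(actives, decoys)
  }
  expect_lt(max(abs(got - want)), 1e-10)
})

test_that("DOE is invariant under affine rescaling of a property column", {
  set.seed(7)
  a <- matrix(rnorm(12), 4, 3); d <- matrix(rnorm(18), 6, 3)
  base <- as.numeric(doe_score(a, d))
  a2 <- a; d2 <- d
  a2[, 2] <- 100 * a[, 2] - 7; d2[, 2] <- 100 * d[, 2] - 7
  expect_equal(as.numeric(doe_score(a2, d2)), base, tolerance = 1e-10)
})

test_that("doppelganger scores reduce the pairwise similarity table", {
  fp <- function(bits) structure(list(length = 1024L, bits = as.integer(bits),
                                      flavor = "functional_fcfp6like"),
                                 class = "fingerprint")
  actives <- list(fp(1:4), fp(5:8), fp(9:12))
  decoys <- list(fp(c(1:3, 20)), fp(c(9:12)))
  # hand computation: decoy 1 best matches active 1 (3/5), decoy 2 = active 3
  res <- doppelganger_scores(decoys, actives)
  expect_equal(res$scores, c(0.6, 1))
  expect_equal(res$mean, 0.8)
  expect_equal(res$max, 1)
  # identical and disjoint molecules at the extremes
  m <- fixture_mol("aspirin")
  expect_equal(doppelganger_scores(list(m), list(m))$max, 1)
  # adding a decoy never decreases the maximum
  res2 <- doppelganger_scores(c(decoys, list(fp(30:33))), actives)
  expect_gte(res2$max, res$max)
})

test_that("AVE matches a hand-evaluated two-fold example and its limits", {
  # 8 points in 1-D, two clusters; explicit folds make the four H terms
  # directly computable
  actives <- matrix(c(0, 0.2, 10, 10.2))
  decoys <- matrix(c(0.1, 0.3, 10.1, 10.3))
  folds <- list(actives = c(1L, 2L, 1L, 2L), decoys = c(1L, 2L, 1L, 2L))
  got <- ave_bias(actives, decoys, grid_size = 50, folds = folds)
  # independent evaluation of H terms
  all_v <- c(actives, decoys)
  s <- sd(all_v)
  z <- (all_v - mean(all_v)) / s
  za <- z[1:4]; zd <- z[5:8]
  grid <- seq(0, max(dist(z)), length.out = 50)
  H <- function(v, t) mean(vapply(v, function(vi)
    mean(min(abs(vi - t)) < grid), numeric(1)))
  manual <- mean(vapply(1:2, function(k) {
    va <- za[folds$actives == k]; ta <- za[folds$actives != k]
    vd <- zd[folds$decoys == k]; td <- zd[folds$decoys != k]
    (H(va, ta) - H(va, td)) + (H(vd, td) - H(vd, ta))
  }, numeric(1)))
  expect_equal(as.numeric(got), manual, tolerance = 1e-12)

  # one common distribution: AVE near zero (band over repeated seeds)
  vals <- vapply(1:5, function(s) {
    pop <- make_separable_sets(30, 30, 3, 0, seed = 100 + s)
    as.numeric(ave_bias(pop$actives, pop$decoys, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.1)
  # fully separated clusters: strongly positive
  sep <- make_separable_sets(30, 30, 3, 100, seed = 1)
  expect_gt(as.numeric(ave_bias(sep$actives, sep$decoys, seed = 1)), 1)
})

test_that("ML bias assessment enumerates subsets and hits the limits", {
  sep <- make_separable_sets(25, 25, 3, 50, seed = 4)
  tab <- ml_bias_assessment(sep$actives, sep$decoys, "1NN", n_folds = 5,
                            seed = 1)
  expect_equal(nrow(tab), 7L) # 2^3 - 1
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  # every subset contains the separating signal (spread over all axes)
  expect_true(all(tab$auc > 0.95))
  # RF agrees on the separable limit for the full subset
  rf <- ml_bias_assessment(sep$actives, sep$decoys, "RF", n_folds = 5,
                           seed = 1)
  expect_gt(rf$auc[rf$k == 3], 0.95)
  # determinism under seed
  tab2 <- ml_bias_assessment(sep$actives, sep$decoys, "1NN", n_folds = 5,
                             seed = 1)
  expect_identical(tab, tab2)
  # small classes reduce the fold count with a warning
  tiny <- make_separable_sets(6, 6, 2, 0, seed = 2)
  expect_warning(ml_bias_assessment(tiny$actives, tiny$decoys, "1NN",
                                    n_folds = 10, seed = 1), "reduced")
})

test_that("1NN AUC cross-checks against an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  score <- rnorm(60)
  label <- rep(c(TRUE, FALSE), 30)
  ours <- decoygen:::rank_auc(score, label)
  theirs <- as.numeric(pROC::auc(pROC::roc(response = label,
                                           predictor = score,
                                           direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("compile_report populates every metric with valid ranges", {
  fx <- fixture_model()
  actives <- fx$library[1:4]
  decoys <- fx$library[5:14]
  pset <- property_set("dude6")
  path <- withr::local_tempfile(fileext = ".json")
  rep <- compile_report("fixture-target", actives, decoys, pset,
                        n_folds = 3L, seed = 5, path = path)
  expect_s3_class(rep, "bias_report")
  expect_gte(rep$doe_score, 0); expect_lte(rep$doe_score, 0.5)
  expect_gte(rep$doppelganger$mean, 0); expect_lte(rep$doppelganger$max, 1)
  expect_gte(rep$ave, -2); expect_lte(rep$ave, 2)
  expect_equal(nrow(rep$subset_auc), 2L * (2^6 - 1)) # both model kinds
  expect_true(file.exists(path))
  # identical inputs and seed give byte-identical JSON
  path2 <- withr::local_tempfile(fileext = ".json")
  compile_report("fixture-target", actives, decoys, pset,
                 n_folds = 3L, seed = 5, path = path2)
  expect_identical(readLines(path), readLines(path2))
})
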