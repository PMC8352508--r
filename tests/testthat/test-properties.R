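# Property registries, descriptors, normalization, distances, SA score.
# Reference MW/logP values frozen from an independent descriptor
# implementation (Wildman-Crippen contributions; average atomic masses).

test_that("built-in registries have the documented sizes", {
  expect_length(property_set("dude6")$properties, 6L)
  expect_length(property_set("dekois8")$properties, 8L)
  expect_length(property_set("extended27")$properties, 27L)
  expect_error(property_set(members = c("mw", "nope")), "unknown")
})

test_that("ethanol descriptors match hand counts and frozen references", {
  v <- compute_properties(fixture_mol("ethanol"), property_set("dude6"))
  expect_equal(v[["hbd"]], 1)
  expect_equal(v[["hba"]], 1)
  expect_equal(v[["rotb"]], 0)
  expect_equal(v[["net_charge"]], 0)
  expect_equal(v[["mw"]], 46.069, tolerance = 1e-3)
  expect_equal(v[["logp"]], -0.0014, tolerance = 1e-3)
})

test_that("benzene DEKOIS-style descriptors match hand counts", {
  v <- compute_properties(fixture_mol("benzene"), property_set("dekois8"))
  expect_equal(v[["aromatic_rings"]], 1)
  expect_equal(v[["hbd"]], 0)
  expect_equal(v[["hba"]], 0)
  expect_equal(v[["mw"]], 78.114, tolerance = 1e-3)
  expect_equal(v[["logp"]], 1.6866, tolerance = 1e-3)
})

test_that("property vectors are deterministic and order-invariant", {
  pset <- property_set("dekois8")
  for (nm in c("aspirin", "ibuprofen", "sulfanilamide")) {
    m <- fixture_mol(nm)
    v1 <- compute_properties(m, pset)
    expect_identical(v1, compute_properties(m, pset))
    v2 <- compute_properties(permute_molecule(m, 2), pset)
    expect_equal(unname(v2), unname(v1), info = nm)
    expect_length(v1, 8L)
    expect_true(all(is.finite(v1)))
  }
})

test_that("normalization gives location 0 / scale 1 and flags degeneracy", {
  set.seed(11)
  m <- cbind(a = rnorm(50, 5, 3), b = runif(50), const = rep(2, 50))
  expect_warning(norm <- fit_normalization(m), "degenerate")
  expect_true(norm$degenerate[["const"]])
  z <- normalize_properties(m, norm)
  expect_equal(unname(colMeans(z)[1:2]), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(apply(z, 2, sd)[1:2]), c(1, 1), tolerance = 1e-10)
  # symmetric two-point population maps to symmetric z-scores
  two <- matrix(c(0, 10), ncol = 1)
  z2 <- normalize_properties(two, fit_normalization(two))
  expect_equal(z2[1], -z2[2])
})

test_that("property_distance is a metric on normalized space", {
  set.seed(3)
  pop <- matrix(rnorm(30), 10, 3)
  norm <- fit_normalization(pop)
  v <- function(i) { x <- pop[i, ]; x }
  expect_equal(property_distance(v(1), v(1), norm), 0)
  # unit difference in exactly one normalized property
  a <- c(0, 0, 0); b <- c(norm$scale[1], 0, 0)
  expect_equal(property_distance(a, b, norm), 1)
  # 3-4-5 triangle in normalized units
  b2 <- c(3 * norm$scale[1], 4 * norm$scale[2], 0)
  expect_equal(property_distance(a, b2, norm), 5)
  # symmetry + triangle inequality over fixture triples
  for (trip in list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))) {
    d12 <- property_distance(v(trip[1]), v(trip[2]), norm)
    d21 <- property_distance(v(trip[2]), v(trip[1]), norm)
    d13 <- property_distance(v(trip[1]), v(trip[3]), norm)
    d23 <- property_distance(v(trip[2]), v(trip[3]), norm)
    expect_equal(d12, d21)
    expect_lte(d13, d12 + d23 + 1e-12)
  }
})

test_that("SA score is within range, deterministic, and ranks complexity", {
  lib <- druglike_library()
  sas <- vapply(lib[seq(1, length(lib), by = 4)], sa_score, numeric(1))
  expect_true(all(sas >= 1 & sas <= 10))
  eth <- sa_score(fixture_mol("ethanol"))
  expect_identical(eth, sa_score(fixture_mol("ethanol")))
  # fused polycyclic with several stereocenters is strictly harder
  tropane <- parse_smiles("CN1C2CCC1CC(C2)OC(=O)C(CO)c1ccccc1")
  expect_gt(sa_score(tropane), eth)
  # SA score is registered as a property
  expect_true("sa_score" %in% names(property_set("extended27")$properties))
})

test_that("property sets can be defined in a key/value config file", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("name: mini", "members:", "  - mw", "  - hbd", "  - hba"), path)
  ps <- read_property_set(path)
  expect_equal(ps$name, "mini")
  expect_equal(names(ps$properties), c("mw", "hbd", "hba"))
  v <- compute_properties(fixture_mol("ethanol"), ps)
  expect_length(v, 3L)
})

test_that("property tables round-trip through CSV", {
  mols <- lapply(FIXTURE_SMILES[1:4], parse_smiles)
  pset <- property_set("dude6")
  path <- withr::local_tempfile(fileext = ".csv")
  df <- write_property_table(mols, pset, path)
  back <- read_property_table(path)
  expect_equal(names(back), c("name", names(pset$properties)))
  expect_equal(back$mw, unname(df$mw), tolerance = 1e-9)
})
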