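# Training-pair construction: composition buckets, the three pair criteria,
# brute-force oracle equivalence, holdout splits.

test_that("bucketing partitions the library by composition", {
  eth <- parse_smiles("CCO")          # C2 O1
  dme <- parse_smiles("COC")          # C2 O1 (isomer)
  eta <- parse_smiles("CCN")          # C2 N1
  lib <- list(eth, dme, eta)
  buckets <- bucket_by_composition(lib)
  sizes <- sort(vapply(buckets, length, integer(1)))
  expect_equal(sum(sizes), 3L)
  expect_equal(unname(sizes), c(1L, 2L))
  in_same <- vapply(buckets, function(ix) all(c(1L, 2L) %in% ix), logical(1))
  expect_true(any(in_same))  # the two C2O isomers share a bucket
})

test_that("pairs respect all three criteria and both orientations appear", {
  lib <- make_library(80, atom_range = c(5L, 9L), seed = 21)
  pset <- property_set("dude6")
  cfg <- pair_config(max_similarity = 0.6, max_distance = 2,
                     property_set_name = "dude6")
  pairs <- suppressWarnings(build_pairs(lib, pset, cfg, seed = 1))
  if (nrow(pairs)) {
    expect_true(all(pairs$tanimoto <= cfg$max_similarity))
    expect_true(all(pairs$prop_distance <= cfg$max_distance))
    for (k in seq_len(min(nrow(pairs), 20))) {
      expect_equal(element_counts(lib[[pairs$a[k]]]),
                   element_counts(lib[[pairs$b[k]]]))
    }
    # both orientations present
    key <- paste(pairs$a, pairs$b)
    rev_key <- paste(pairs$b, pairs$a)
    expect_true(all(rev_key %in% key))
  }
  # identical molecules are rejected on structural similarity
  twin_lib <- list(parse_smiles("CCO"), parse_smiles("CCO"))
  expect_warning(
    none <- build_pairs(twin_lib, pset,
                        pair_config(max_similarity = 0.15, max_distance = 10,
                                    property_set_name = "dude6")),
    "no pairs")
  expect_equal(nrow(none), 0L)
  expect_equal(attr(none, "rejections")[["similarity"]], 1L)
})

test_that("build_pairs matches the brute-force all-pairs oracle", {
  lib <- make_library(120, atom_range = c(5L, 9L), seed = 33)
  pset <- property_set("dude6")
  cfg <- pair_config(max_similarity = 0.5, max_distance = 1.5,
                     property_set_name = "dude6")
  got <- suppressWarnings(build_pairs(lib, pset, cfg, seed = 1))
  want <- oracle_pairs(lib, pset, cfg)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  got_keys <- sort(unique(key(got$a, got$b)))
  want_keys <- sort(key(want$a, want$b))
  expect_equal(got_keys, want_keys)
  # recorded similarity/distance agree with the scalar recomputation
  if (nrow(want)) {
    m <- match(key(want$a, want$b), key(got$a, got$b))
    expect_equal(got$tanimoto[m], want$tanimoto, tolerance = 1e-12)
    expect_equal(got$prop_distance[m], want$prop_distance, tolerance = 1e-9)
  }
})

test_that("rejection counts account for every same-bucket candidate pair", {
  lib <- make_library(60, atom_range = c(5L, 8L), seed = 9)
  pset <- property_set("dude6")
  cfg <- pair_config(max_similarity = 0.3, max_distance = 1,
                     property_set_name = "dude6")
  pairs <- suppressWarnings(build_pairs(lib, pset, cfg, seed = 1))
  rej <- attr(pairs, "rejections")
  buckets <- bucket_by_composition(lib)
  n_candidates <- sum(vapply(buckets, function(ix) choose(length(ix), 2),
                             numeric(1)))
  expect_equal(nrow(pairs) / 2 + sum(rej), n_candidates)
})

test_that("holdout_split is disjoint, exhaustive and seed-reproducible", {
  pairs <- data.frame(a = 1:10, b = 11:20)
  sp <- holdout_split(pairs, 3, seed = 5)
  expect_equal(nrow(sp$train), 7L)
  expect_equal(nrow(sp$validation), 3L)
  expect_length(intersect(rownames(sp$train), rownames(sp$validation)), 0L)
  sp2 <- holdout_split(pairs, 3, seed = 5)
  expect_identical(sp, sp2)
  expect_equal(nrow(holdout_split(pairs, 0)$train), 10L)
  expect_error(holdout_split(pairs, 10), "smaller")
})
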