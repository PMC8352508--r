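# Candidate filtering, LADS penalty, greedy selection, decoy-set assembly.

test_that("LADS score follows the overlap contract", {
  # every active atom carries a pharmacophoric role (aromatic / donor /
  # acceptor), so a pure alkane shares no functional environment with them
  actives <- lapply(c("c1ccccc1O", "c1ccccc1N", "c1ccncc1"), parse_smiles)
  expect_equal(lads_score(parse_smiles("CCCCCC"), actives), 0)
  # a decoy identical to an active scores highest in the pool
  pool <- lapply(c("c1ccccc1O", "CCCCCC", "CCOCC"), parse_smiles)
  scores <- vapply(pool, lads_score, numeric(1), actives = actives)
  expect_equal(which.max(scores), 1L)
  expect_true(all(scores >= 0 & scores <= 1))
  # hand-computed toy case: decoy bits are scored by active prevalence
  afp <- lapply(actives, functional_fingerprint)
  dfp <- functional_fingerprint(parse_smiles("c1ccccc1O"))
  manual <- mean(vapply(dfp$bits, function(b) {
    mean(vapply(afp, function(f) b %in% f$bits, logical(1)))
  }, numeric(1)))
  expect_equal(lads_score(parse_smiles("c1ccccc1O"), actives), manual)
})

test_that("filtering relaxes thresholds until the pool is large enough", {
  active <- parse_smiles("CCCCCCCC")
  actives <- list(active)
  # candidates deliberately off-size so the strictest level fails
  cands <- lapply(c("CC", "CCC", "CCCC", "CCCCC", "CCCCCC", "CCCCCCC",
                    "CCCCCCCC", "CCCCCCCCC"), parse_smiles)
  cfg <- selection_config(min_pool = 5L, decoys_per_active = 3L,
                          max_heavy_diff = 0L, max_doppelganger = 0.9)
  res <- filter_candidates(cands, active, actives, cfg)
  expect_gte(length(res$kept), 5L)
  expect_gt(nrow(res$trace), 1L) # at least one relaxation step happened
  expect_true(all(diff(res$trace$surviving) >= 0))
  hdiff <- abs(vapply(cands[res$kept], n_atoms, integer(1)) - n_atoms(active))
  expect_true(all(hdiff <= res$final_thresholds[["max_heavy_diff"]]))
  expect_true(all(res$doppelganger[res$kept] <=
                    res$final_thresholds[["max_doppelganger"]]))

  # degenerate input: all candidates identical to the active are removed at
  # the strictest level; thresholds relax to vacuity with a warning
  twins <- lapply(1:6, function(i) parse_smiles("CCCCCCCC"))
  cfg2 <- selection_config(min_pool = 5L, decoys_per_active = 2L,
                           max_doppelganger = 0.25)
  expect_warning(res2 <- filter_candidates(twins, active, actives, cfg2),
                 "fully relaxed")
  expect_equal(res2$trace$surviving[1], 0L)  # strictest level removes all
  expect_gt(nrow(res2$trace), 1L)

  # no relaxation when enough candidates already pass the strictest level
  same_size <- lapply(c("CCCCCCCO", "CCCCCCOC", "CCCCCOCC", "CCCCOCCC",
                        "CCCOCCCC", "CCOCCCCC"), parse_smiles)
  cfg3 <- selection_config(min_pool = 5L, decoys_per_active = 2L,
                           max_heavy_diff = 0L, max_doppelganger = 0.9)
  res3 <- filter_candidates(same_size, active, actives, cfg3)
  expect_equal(nrow(res3$trace), 1L)
  expect_equal(res3$final_thresholds[["max_heavy_diff"]], 0L)
})

test_that("greedy selection takes the smallest combined scores with stable ties", {
  scored <- data.frame(combined = c(0.1, 0.5, 0.3),
                       canonical = c("CC", "CCC", "CCO"))
  expect_equal(greedy_select(scored, 2), c(1L, 3L))
  expect_equal(greedy_select(scored, 3), c(1L, 3L, 2L))
  expect_warning(sel <- greedy_select(scored, 5), "only 3")
  expect_length(sel, 3L)
  # ties broken lexicographically by canonical form, order-invariant
  tied <- data.frame(combined = c(0.2, 0.2, 0.2),
                     canonical = c("CCO", "CC", "CCC"))
  expect_equal(tied$canonical[greedy_select(tied, 2)], c("CC", "CCC"))
  shuffled <- tied[c(3, 1, 2), ]
  expect_equal(shuffled$canonical[greedy_select(shuffled, 2)], c("CC", "CCC"))
})

test_that("build_decoy_set assembles per-active decoys with provenance", {
  fx <- fixture_model()
  actives <- fx$library[1:2]
  cfg <- selection_config(candidates_per_active = 60L, min_pool = 20L,
                          decoys_per_active = 5L, property_set_name = "dude6")
  ds <- build_decoy_set(actives, fx$model, cfg, seed = 17)
  expect_s3_class(ds, "decoy_set")
  expect_length(ds$decoys, 2L)
  all_dec <- unlist(ds$decoys, recursive = FALSE)
  expect_equal(length(all_dec), 10L)
  expect_true(all(vapply(all_dec, function(m) check_valence(m)$valid,
                         logical(1))))
  # accounting: generated = failures + unique + duplicates
  for (rep in ds$report) {
    expect_equal(rep$n_generated, rep$n_failed + rep$n_unique + rep$n_duplicates)
    expect_gte(rep$n_filtered, cfg$decoys_per_active)
    # no selected decoy exceeds the recorded final doppelganger threshold
    expect_true(all(rep$selected$doppelganger <=
                      rep$final_thresholds[["max_doppelganger"]]))
  }
  ds2 <- build_decoy_set(actives, fx$model, cfg, seed = 17)
  expect_identical(
    lapply(ds$decoys, function(l) vapply(l, canonical_smiles, character(1))),
    lapply(ds2$decoys, function(l) vapply(l, canonical_smiles, character(1))))
})
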