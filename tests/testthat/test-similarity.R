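# Circular fingerprints and Tanimoto similarity.

test_that("tanimoto follows the set-overlap definition", {
  fp <- function(bits) structure(list(length = 1024L, bits = as.integer(bits),
                                      flavor = "morgan_r2_1024"),
                                 class = "fingerprint")
  expect_equal(tanimoto(fp(c(1, 5, 9)), fp(c(1, 5, 9))), 1)
  expect_equal(tanimoto(fp(1:3), fp(4:6)), 0)
  expect_equal(tanimoto(fp(1:3), fp(2:4)), 0.5) # 2 shared / 4 union
  expect_warning(expect_equal(tanimoto(fp(integer()), fp(integer())), 0),
                 "empty")
  bad <- structure(list(length = 1024L, bits = 1L,
                        flavor = "functional_fcfp6like"), class = "fingerprint")
  expect_error(tanimoto(fp(1), bad), "mismatch")
})

test_that("fingerprints are deterministic and isomorphism-invariant", {
  for (nm in c("benzene", "aspirin", "sulfanilamide")) {
    m <- fixture_mol(nm)
    for (fun in list(morgan_fingerprint, functional_fingerprint)) {
      f1 <- fun(m)
      expect_identical(f1, fun(m), info = nm)
      expect_identical(fun(permute_molecule(m, 5))$bits, f1$bits, info = nm)
      expect_true(all(f1$bits >= 0 & f1$bits < f1$length))
      expect_gt(length(f1$bits), 0)
      expect_equal(tanimoto(f1, fun(permute_molecule(m, 9))), 1, info = nm)
    }
  }
})

test_that("structurally different molecules give different bit sets", {
  methane <- parse_smiles("C")
  expect_false(identical(morgan_fingerprint(methane)$bits,
                         morgan_fingerprint(fixture_mol("benzene"))$bits))
  # phenol vs toluene differ on the functional flavor (donor role differs)
  fp_ph <- functional_fingerprint(fixture_mol("phenol"))
  fp_to <- functional_fingerprint(fixture_mol("toluene"))
  expect_false(identical(fp_ph$bits, fp_to$bits))
  expect_lt(tanimoto(fp_ph, fp_to), 1)
})

test_that("fingerprint flavors are recorded", {
  m <- fixture_mol("ethanol")
  expect_equal(morgan_fingerprint(m)$flavor, "morgan_r2_1024")
  expect_equal(functional_fingerprint(m)$flavor, "functional_fcfp6like")
  expect_equal(morgan_fingerprint(m)$length, 1024L)
})
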