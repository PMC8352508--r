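# Molecular graph model, SMILES/SDF I/O, element counts, valence rules.

test_that("SMILES parsing produces the expected graphs", {
  eth <- parse_smiles("CCO")
  expect_equal(n_atoms(eth), 3L)
  expect_equal(n_bonds(eth), 2L)
  expect_true(all(eth$bond_order == 1L))

  benz <- parse_smiles("c1ccccc1")
  expect_equal(n_atoms(benz), 6L)
  expect_equal(n_bonds(benz), 6L)
  expect_true(all(benz$aromatic))
  expect_true(all(benz$bond_order == 4L))

  expect_error(parse_smiles("C("), "unmatched")
  expect_error(parse_smiles("CC.O"), "multi-fragment")
})

test_that("element_counts reports matched elements and is order-invariant", {
  expect_equal(
    element_counts(fixture_mol("ethanol"))[c("total", "C", "O", "N", "S", "Cl", "F")],
    c(total = 3L, C = 2L, O = 1L, N = 0L, S = 0L, Cl = 0L, F = 0L))
  expect_equal(element_counts(fixture_mol("benzene"))[["C"]], 6L)
  csc <- parse_smiles("CSCl")
  expect_equal(element_counts(csc)[c("total", "C", "S", "Cl")],
               c(total = 3L, C = 1L, S = 1L, Cl = 1L))
  for (nm in names(FIXTURE_SMILES)) {
    m <- fixture_mol(nm)
    expect_equal(element_counts(permute_molecule(m, 3)), element_counts(m),
                 info = nm)
  }
})

test_that("check_valence enforces vocabulary and bond-order sums", {
  ok <- molecule(rep("C", 5), rep(1L, 4), 2:5, rep(1L, 4)) # neopentane core
  expect_true(check_valence(ok)$valid)

  over <- molecule(rep("C", 6), rep(1L, 5), 2:6, rep(1L, 5)) # 5 bonds on C
  res <- check_valence(over)
  expect_false(res$valid)
  expect_equal(nrow(res$violations), 1L)
  expect_match(res$violations$reason, "exceeds valence")

  phos <- molecule(c("P", "C"), 1L, 2L, 1L)
  res <- check_valence(phos)
  expect_false(res$valid)
  expect_match(res$violations$reason, "type not permitted")
  # a vocabulary extended with phosphorus admits it
  vocab_p <- default_vocabulary(data.frame(element = "P", charge = 0L,
                                           max_valence = 5))
  expect_true(check_valence(phos, vocab_p)$valid)
})

test_that("file round-trips preserve counts, charges and valence verdicts", {
  mols <- lapply(FIXTURE_SMILES, parse_smiles)
  for (fmt in c("smi", "sdf")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    expect_equal(write_molecules(mols, path, fmt), length(mols))
    back <- parse_molecules(path, fmt)
    expect_equal(attr(back, "n_failed"), 0L)
    expect_equal(length(back), length(mols))
    same <- vapply(seq_along(mols), function(i) {
      identical(element_counts(back[[i]]), element_counts(mols[[i]])) &&
        identical(sort(back[[i]]$charge), sort(mols[[i]]$charge)) &&
        identical(check_valence(back[[i]])$valid,
                  check_valence(mols[[i]])$valid)
    }, logical(1))
    expect_true(all(same), label = paste(fmt, "round trip"))
  }
  # empty list
  path <- withr::local_tempfile(fileext = ".smi")
  expect_equal(write_molecules(list(), path, "smi"), 0L)
})

test_that("invalid records are reported with indices, not silently dropped", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO ok1", "C( broken", "c1ccccc1 ok2"), path)
  expect_warning(res <- parse_molecules(path), "record 2")
  expect_equal(length(res), 2L)
  expect_equal(attr(res, "n_failed"), 1L)
  expect_equal(attr(res, "failures")$record, 2L)
})

test_that("canonical SMILES is invariant under atom relabelling", {
  stable <- vapply(names(FIXTURE_SMILES), function(nm) {
    m <- fixture_mol(nm)
    ref <- canonical_smiles(m)
    perms <- vapply(1:3, function(s) {
      canonical_smiles(permute_molecule(m, s))
    }, character(1))
    # invariance under relabelling, and the canonical form is a fixed point
    all(perms == ref) && identical(canonical_smiles(parse_smiles(ref)), ref)
  }, logical(1))
  expect_true(all(stable), label = paste(
    "canonical stability:", paste(names(stable)[!stable], collapse = ", ")))
})

test_that("kekulization preserves hydrogen counts and validity", {
  for (nm in c("benzene", "pyridine", "pyrrole", "naphthalene", "aspirin")) {
    m <- fixture_mol(nm)
    k <- kekulize(m)
    expect_true(all(k$bond_order != 4L), info = nm)
    expect_true(check_valence(k)$valid, info = nm)
    expect_equal(sort(decoygen:::hydrogen_count(k)), sort(decoygen:::hydrogen_count(m)), info = nm)
    # aromaticity perception recovers the aromatic system
    expect_equal(sum(perceive_aromaticity(k)$aromatic), sum(m$aromatic),
                 info = nm)
  }
})
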