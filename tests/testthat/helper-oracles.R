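# Shared fixtures and independent oracles used across the suite.

FIXTURE_SMILES <- c(
  ethanol = "CCO", benzene = "c1ccccc1", aspirin = "CC(=O)Oc1ccccc1C(=O)O",
  ibuprofen = "CC(C)Cc1ccc(cc1)C(C)C(=O)O", pyridine = "c1ccncc1",
  pyrrole = "c1cc[nH]c1", phenol = "Oc1ccccc1", toluene = "Cc1ccccc1",
  acetate = "CC(=O)[O-]", tetramethylammonium = "C[N+](C)(C)C",
  naphthalene = "c1ccc2ccccc2c1", sulfanilamide = "NS(=O)(=O)c1ccc(N)cc1"
)

fixture_mol <- function(name) parse_smiles(FIXTURE_SMILES[[name]])

# Random atom relabelling of a molecule (same graph, permuted indices).
permute_molecule <- function(mol, seed = 1L) {
  n <- n_atoms(mol)
  perm <- withr::with_seed(seed, sample.int(n))       # new order of old atoms
  inv <- match(seq_len(n), perm)
  molecule(mol$element[perm], inv[mol$bond_a], inv[mol$bond_b],
           mol$bond_order, charge = mol$charge[perm],
           aromatic = mol$aromatic[perm], hexp = mol$hexp[perm])
}

# --- independent DOE oracle -------------------------------------------
# Enumerates the ranked list per active and integrates |ROC - diagonal|
# segment-wise with the closed-form integral of an absolute linear function.
oracle_int_abs_linear <- function(c0, c1, len) {
  if (len == 0) return(0)
  if (c0 * c1 >= 0) return(len * (abs(c0) + abs(c1)) / 2)
  len * (c0^2 + c1^2) / (2 * abs(c0 - c1))
}

oracle_roc_dev <- function(pos, neg) {
  pos <- round(pos, 9); neg <- round(neg, 9)
  vals <- sort(unique(c(pos, neg)))
  x <- 0; y <- 0; total <- 0
  for (v in vals) {
    nx <- x + sum(neg == v) / length(neg)
    ny <- y + sum(pos == v) / length(pos)
    total <- total + oracle_int_abs_linear(y - x, ny - nx, nx - x)
    x <- nx; y <- ny
  }
  total
}

oracle_doe <- function(actives, decoys) {
  all_m <- rbind(actives, decoys)
  mu <- colMeans(all_m)
  sdv <- apply(all_m, 2, sd)
  sdv[sdv < 1e-12] <- 1
  z <- sweep(sweep(all_m, 2, mu), 2, sdv, "/")
  na <- nrow(actives)
  devs <- sapply(seq_len(na), function(i) {
    d <- sqrt(colSums((t(z) - z[i, ])^2))
    oracle_roc_dev(d[setdiff(seq_len(na), i)], d[(na + 1):nrow(z)])
  })
  mean(devs)
}

# --- independent pair-builder oracle ----------------------------------
# Brute-force all-pairs scan applying the three criteria with the scalar
# API (composition equality, Tanimoto, normalized property distance).
oracle_pairs <- function(library, pset, config) {
  pm <- property_matrix(library, pset)
  norm <- suppressWarnings(fit_normalization(pm))
  fps <- lapply(library, morgan_fingerprint)
  keys <- vapply(library, function(m) {
    ec <- element_counts(m)
    paste(ec[["total"]], ec[["C"]], ec[["N"]], ec[["O"]], ec[["S"]],
          ec[["Cl"]], ec[["F"]])
  }, character(1))
  out <- list()
  n <- length(library)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (keys[i] != keys[j]) next
      sim <- tanimoto(fps[[i]], fps[[j]])
      if (sim > config$max_similarity) next
      va <- pm[i, ]; attr(va, "schema") <- pset$name
      vb <- pm[j, ]; attr(vb, "schema") <- pset$name
      dd <- property_distance(va, vb, norm)
      if (dd > config$max_distance) next
      out[[length(out) + 1]] <- data.frame(a = i, b = j, tanimoto = sim,
                                           prop_distance = dd)
    }
  }
  if (!length(out)) return(data.frame(a = integer(), b = integer()))
  do.call(rbind, out)
}

# Small trained generator shared by the generator/selection/acceptance
# tests (built once per test run).
fixture_model <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    lib <- make_library(80, atom_range = c(8L, 10L), palette = c("C", "N", "O"),
                        palette_weights = c(10, 1, 1), seed = 42)
    pairs <- suppressWarnings(build_pairs(
      lib, property_set("dude6"),
      pair_config(max_similarity = 1, max_distance = 1e6,
                  property_set_name = "dude6"), seed = 1))
    pairs <- pairs[seq_len(min(60L, nrow(pairs))), ]
    model <- train_generator(pairs, lib,
                             config = generator_config(epochs = 25L,
                                                       lr = 0.03, seed = 7L))
    cache <<- list(model = model, library = lib)
    cache
  }
})
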