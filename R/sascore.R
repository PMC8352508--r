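## Synthetic accessibility score, following the fragment-contribution method:
## a frequency score over circular fragments (common substructures are easy to
## source, rare ones hard) combined with complexity penalties for size, ring
## fusion, spiro centers and macrocycles, mapped to [1, 10] where 1 is easy to
## make and 10 very difficult. The fragment frequency reference is built once,
## at first use, from the bundled drug-like library (deterministic, cached).

.sa_env <- new.env(parent = emptyenv())

# Per-atom circular environment identifiers (radii 0..2), Morgan-style.
atom_environment_ids <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (k in seq_len(n_bonds(mol))) {
    a <- mol$bond_a[k]; b <- mol$bond_b[k]; o <- mol$bond_order[k]
    adj[[a]] <- rbind(adj[[a]], c(b, o))
    adj[[b]] <- rbind(adj[[b]], c(a, o))
  }
  ids <- morgan_atom_invariants(mol)
  out <- matrix(0, n, 3L)
  out[, 1L] <- ids
  for (r in 1:2) {
    new_ids <- ids
    for (i in seq_len(n)) {
      nb <- adj[[i]]
      if (is.null(nb)) next
      env <- nb[order(nb[, 2L], ids[nb[, 1L]]), , drop = FALSE]
      new_ids[i] <- hash_ints(c(r, ids[i], t(cbind(env[, 2L], ids[env[, 1L]]))))
    }
    ids <- new_ids
    out[, r + 1L] <- ids
  }
  out
}

#' Bundled drug-like reference library
#'
#' A curated static list of common drug-like structures shipped with the
#' package, used as the fragment-frequency reference for [sa_score()] and as
#' realistic input for descriptor examples.
#'
#' @return list of `molecule` objects.
#' @export
druglike_library <- function() {
  if (!is.null(.sa_env$druglike)) return(.sa_env$druglike)
  path <- system.file("extdata", "druglike_200.smi", package = "decoygen")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "druglike_200.smi")
  mols <- suppressWarnings(parse_molecules(path, "smi"))
  .sa_env$druglike <- mols
  mols
}

# Per-radius fragment frequency tables over the reference library. Radius-0
# and radius-1 environments are well estimated by a compact reference; the
# sparser radius-2 shells carry reduced weight in the score.
sa_fragment_table <- function() {
  if (!is.null(.sa_env$fragments)) return(.sa_env$fragments)
  mols <- druglike_library()
  per_radius <- lapply(1:3, function(col) {
    ids <- unlist(lapply(mols, function(m) atom_environment_ids(m)[, col]))
    tab <- table(ids)
    counts <- as.numeric(tab)
    names(counts) <- names(tab)
    # reference count: a fragment at or above the upper-quartile count is
    # considered fully "common"
    list(counts = counts, cref = max(2, stats::quantile(counts, 0.75)))
  })
  .sa_env$fragments <- per_radius
  per_radius
}

#' Synthetic accessibility score
#'
#' Fragment-contribution synthetic accessibility estimate in \[1, 10\]
#' (1 = easy to make, 10 = very difficult). Combines the mean log-frequency of
#' the molecule's circular fragments in the bundled drug-like reference with
#' penalties for molecular size, ring fusion, spiro atoms and macrocycles.
#' Registered as a descriptor (`"sa_score"`) so it can be included in a
#' property set to unbias.
#'
#' @param mol a `molecule`.
#' @return numeric score in \[1, 10\].
#' @export
sa_score <- function(mol) {
  ref <- sa_fragment_table()
  env_ids <- atom_environment_ids(mol)
  w <- c(1, 1, 0.5)
  rar <- vapply(1:3, function(col) {
    cnt <- ref[[col]]$counts[as.character(env_ids[, col])]
    cnt[is.na(cnt)] <- 0
    # 0 for fragments at least as common as the reference count .. 1 unseen
    1 - mean(pmin(1, log1p(cnt) / log1p(ref[[col]]$cref)))
  }, numeric(1))
  rarity <- sum(w * rar) / sum(w)

  n <- n_atoms(mol)
  size_penalty <- 0.15 * n^0.8
  rings <- smallest_rings(mol)
  ring_sizes <- vapply(rings, length, integer(1))
  ring_atoms <- unlist(rings)
  shared <- if (length(rings) > 1L) sum(duplicated(ring_atoms)) else 0L
  deg <- atom_degree(mol)
  multi_ring <- as.integer(names(which(table(ring_atoms) >= 2L)))
  spiro <- sum(deg[multi_ring] >= 4L)
  fusion_penalty <- 1.2 * log10(shared + 1) + 1.5 * log10(spiro + 1)
  macro_penalty <- if (length(ring_sizes) && max(ring_sizes) > 8L) 0.5 else 0

  raw <- 6 * rarity + fusion_penalty + size_penalty + macro_penalty
  min(10, max(1, 1 + raw))
}
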