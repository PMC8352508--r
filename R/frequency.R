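## Subgraph frequency table: counts of bond-centered local environments
## (radius 1) across a training set. The generator's reweighted action loss
## uses the reciprocal relative frequency f of the environment a candidate
## action would create, so actions inducing subgraphs unseen in training are
## suppressed. Add-one smoothing keeps f finite for unseen keys.

# Canonical key of the radius-1 environment around bond (a, b) with order
# `ord` (the bond itself included in both endpoint descriptors).
bond_environment_key <- function(mol, a, b, ord, extra_a = NULL, extra_b = NULL) {
  desc <- function(i, other_ord) {
    nb <- neighbors(mol, i)
    orders <- sort(c(nb$order, other_ord))
    sprintf("%s%+d(%s)", mol$element[i], mol$charge[i],
            paste(orders, collapse = ""))
  }
  da <- desc(a, extra_a)
  db <- desc(b, extra_b)
  pair <- sort(c(da, db))
  sprintf("%d|%s|%s", ord, pair[1L], pair[2L])
}

#' Build a subgraph frequency table
#'
#' Counts every bond-centered radius-1 environment (bond order plus both
#' endpoint element/charge/incident-order descriptors) across the training
#' molecules. Deterministic.
#'
#' @param mols list of `molecule` objects.
#' @param radius environment radius (only radius 1 is implemented; the
#'   argument documents the contract).
#' @return object of class `subgraph_frequency_table`: list with `counts`
#'   (named numeric), `total`, `n_keys`.
#' @export
build_frequency_table <- function(mols, radius = 1L) {
  stopifnot(length(mols) >= 1L, radius == 1L)
  keys <- unlist(lapply(mols, function(m) {
    if (!n_bonds(m)) return(character())
    vapply(seq_len(n_bonds(m)), function(k) {
      bond_environment_key(m, m$bond_a[k], m$bond_b[k], m$bond_order[k])
    }, character(1))
  }))
  tab <- table(keys)
  counts <- as.numeric(tab)
  names(counts) <- names(tab)
  structure(list(counts = counts, total = sum(counts),
                 n_keys = length(counts)),
            class = "subgraph_frequency_table")
}

#' Reciprocal relative frequency of an environment key
#'
#' `f = 1 / p` with `p = (count + 1) / (total + n_keys + 1)` (add-one
#' smoothing), so unseen keys return the (large, finite) maximum.
#'
#' @param table a [build_frequency_table()] result.
#' @param key environment key string (or vector of keys).
#' @return numeric vector of reciprocal frequencies, all > 0.
#' @export
reciprocal_frequency <- function(table, key) {
  cnt <- table$counts[key]
  cnt[is.na(cnt)] <- 0
  p <- (cnt + 1) / (table$total + table$n_keys + 1)
  unname(1 / p)
}

#' Smoothed count for an environment key
#' @param table a [build_frequency_table()] result.
#' @param key environment key string.
#' @return count + 1 smoothing floor: at least 1 for any key.
#' @export
smoothed_count <- function(table, key) {
  cnt <- table$counts[key]
  cnt[is.na(cnt)] <- 0
  unname(cnt + 1)
}
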