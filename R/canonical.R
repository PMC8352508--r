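## Canonical atom ordering by iterative partition refinement with
## individualization on residual ties (Morgan-style with backtracking over the
## first non-singleton cell; certificate-minimal branch wins). Molecules are
## small, so the worst-case branching is never a concern in practice.

atom_invariant_strings <- function(mol) {
  hc <- hydrogen_count(mol)
  deg <- atom_degree(mol)
  sprintf("%s|%+d|%d|%d|%d", mol$element, mol$charge,
          as.integer(mol$aromatic), hc, deg)
}

refine_colors <- function(mol, colors) {
  n <- n_atoms(mol)
  nb_at <- vector("list", n)
  nb_ord <- vector("list", n)
  for (k in seq_len(n_bonds(mol))) {
    a <- mol$bond_a[k]; b <- mol$bond_b[k]; o <- mol$bond_order[k]
    nb_at[[a]] <- c(nb_at[[a]], b); nb_ord[[a]] <- c(nb_ord[[a]], o)
    nb_at[[b]] <- c(nb_at[[b]], a); nb_ord[[b]] <- c(nb_ord[[b]], o)
  }
  base <- 8L * (n + 2L) # neighbor code = order * base-ish slot + color
  repeat {
    keys <- character(n)
    for (i in seq_len(n)) {
      v <- nb_ord[[i]] * base + colors[nb_at[[i]]]
      # zero-padded color prefix keeps the new labels order-consistent with
      # the old ones, so the refinement reaches a fixed point
      keys[i] <- sprintf("%06d|%s", colors[i],
                         paste(sort.int(v), collapse = ","))
    }
    new_colors <- match(keys, sort.int(unique(keys), method = "radix"))
    if (identical(new_colors, colors)) return(colors)
    colors <- new_colors
  }
}

# Certificate string for a fixed atom permutation: relabelled atom and bond
# tables. Two orderings of isomorphic graphs agree iff the strings agree.
order_certificate <- function(mol, ord) {
  inv <- atom_invariant_strings(mol)
  pos <- match(seq_len(n_atoms(mol)), ord)
  atoms <- paste(inv[ord], collapse = ";")
  if (n_bonds(mol)) {
    a <- pos[mol$bond_a]; b <- pos[mol$bond_b]
    bonds <- sprintf("%d-%d-%d", pmin(a, b), pmax(a, b), mol$bond_order)
    bonds <- paste(sort(bonds), collapse = ";")
  } else bonds <- ""
  paste(atoms, bonds, sep = "#")
}

canonical_search <- function(mol, colors) {
  colors <- refine_colors(mol, colors)
  tab <- table(colors)
  if (all(tab == 1L)) {
    ord <- order(colors)
    return(list(ord = ord, cert = order_certificate(mol, ord)))
  }
  cell_color <- as.integer(names(tab)[tab > 1L][1L])
  members <- which(colors == cell_color)
  best <- NULL
  for (m in members) {
    c2 <- colors * 2L
    c2[m] <- c2[m] - 1L
    cand <- canonical_search(mol, match(c2, sort(unique(c2))))
    if (is.null(best) || cand$cert < best$cert) best <- cand
  }
  best
}

#' Canonical atom order
#'
#' Returns a permutation of atom indices that is invariant under graph
#' isomorphism: any relabelling of the same molecular graph yields the same
#' sequence of atoms (up to automorphism), so downstream canonical SMILES are
#' stable identifiers.
#'
#' @param mol a `molecule`.
#' @return integer vector: atom indices in canonical order.
#' @export
canonical_order <- function(mol) {
  inv <- atom_invariant_strings(mol)
  colors <- match(inv, sort(unique(inv)))
  canonical_search(mol, colors)$ord
}

# Canonical ranks: rank[i] = position of atom i in the canonical order.
canonical_ranks <- function(mol) {
  match(seq_len(n_atoms(mol)), canonical_order(mol))
}
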