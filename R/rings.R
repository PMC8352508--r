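## Ring perception: ring-bond detection, a smallest-rings set, aromaticity
## perception on kekulized input, and kekulization of aromatic systems.

# Logical vector over bonds: is the bond part of a cycle?
ring_bond_mask <- function(mol) {
  m <- n_bonds(mol)
  out <- logical(m)
  if (m == 0L) return(out)
  for (k in seq_len(m)) {
    a <- mol$bond_a[k]; b <- mol$bond_b[k]
    # connected without bond k?
    seen <- logical(n_atoms(mol)); seen[a] <- TRUE; queue <- a
    while (length(queue) && !seen[b]) {
      i <- queue[1L]; queue <- queue[-1L]
      sel <- which((mol$bond_a == i | mol$bond_b == i) & seq_len(m) != k)
      nb <- ifelse(mol$bond_a[sel] == i, mol$bond_b[sel], mol$bond_a[sel])
      nb <- nb[!seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    out[k] <- seen[b]
  }
  out
}

# Smallest rings: for every ring bond, the shortest cycle through it; unique
# atom sets returned, smallest first. Adequate for the fused systems found in
# drug-like molecules (not a strict SSSR for exotic cage graphs).
smallest_rings <- function(mol) {
  rb <- which(ring_bond_mask(mol))
  if (!length(rb)) return(list())
  rings <- list()
  for (k in rb) {
    a <- mol$bond_a[k]; b <- mol$bond_b[k]
    # BFS shortest path a -> b avoiding bond k
    n <- n_atoms(mol)
    prev <- rep(NA_integer_, n)
    seen <- logical(n); seen[a] <- TRUE; queue <- a
    while (length(queue) && !seen[b]) {
      i <- queue[1L]; queue <- queue[-1L]
      sel <- which((mol$bond_a == i | mol$bond_b == i) & seq_len(n_bonds(mol)) != k)
      nb <- ifelse(mol$bond_a[sel] == i, mol$bond_b[sel], mol$bond_a[sel])
      nb <- nb[!seen[nb]]
      seen[nb] <- TRUE
      prev[nb] <- i
      queue <- c(queue, nb)
    }
    if (!seen[b]) next
    path <- b
    while (path[1L] != a) path <- c(prev[path[1L]], path)
    rings[[length(rings) + 1L]] <- sort(path)
  }
  rings <- unique(rings)
  rings[order(vapply(rings, length, integer(1)))]
}

# Number of rings whose every atom and internal bond is aromatic.
count_aromatic_rings <- function(mol) {
  rs <- smallest_rings(mol)
  if (!length(rs)) return(0L)
  cnt <- 0L
  for (ring in rs) {
    if (!all(mol$aromatic[ring])) next
    sel <- mol$bond_a %in% ring & mol$bond_b %in% ring
    if (all(mol$bond_order[sel] == 4L)) cnt <- cnt + 1L
  }
  cnt
}

# Total smallest-ring count (ring count descriptor).
count_rings <- function(mol) length(smallest_rings(mol))

#' Kekulize aromatic bonds
#'
#' Replaces aromatic bonds with an alternating single/double assignment found
#' by backtracking matching. Atoms contributing a lone pair to the ring
#' (N with an H or three connections, O, S) take no double bond. Explicit H
#' counts are frozen on the former aromatic atoms so hydrogen counts survive
#' the change of representation.
#'
#' @param mol a `molecule`.
#' @return a kekulized `molecule` (no order-4 bonds, aromatic flags cleared).
#' @export
kekulize <- function(mol) {
  ar_bonds <- which(mol$bond_order == 4L)
  if (!length(ar_bonds)) return(mol)
  hc <- hydrogen_count(mol)
  deg <- atom_degree(mol)
  ar_atoms <- which(mol$aromatic)
  # does the atom need exactly one double bond within the aromatic system?
  plain_multi <- mol$bond_order %in% c(2L, 3L)
  exo_double <- tabulate(c(mol$bond_a[plain_multi], mol$bond_b[plain_multi]),
                         nbins = n_atoms(mol)) > 0L
  needs <- logical(n_atoms(mol))
  for (i in ar_atoms) {
    el <- mol$element[i]
    needs[i] <- if (exo_double[i]) FALSE
      else if (el == "C") TRUE
      else if (el == "N") !(hc[i] > 0L || deg[i] >= 3L || mol$charge[i] < 0L)
      else if (el == "P") !(hc[i] > 0L || deg[i] >= 3L)
      else FALSE # O, S, B contribute lone pairs / empty orbital
  }
  assign_orders <- rep(1L, length(ar_bonds))
  sat <- logical(n_atoms(mol)) # already holds its double bond
  solve <- function(b_idx) {
    if (b_idx > length(ar_bonds)) return(all(!needs[mol$aromatic] | sat[mol$aromatic]))
    k <- ar_bonds[b_idx]
    a <- mol$bond_a[k]; b <- mol$bond_b[k]
    # option 1: double here
    if (needs[a] && needs[b] && !sat[a] && !sat[b]) {
      sat[a] <<- TRUE; sat[b] <<- TRUE
      assign_orders[b_idx] <<- 2L
      if (solve(b_idx + 1L)) return(TRUE)
      sat[a] <<- FALSE; sat[b] <<- FALSE
      assign_orders[b_idx] <<- 1L
    }
    # option 2: single here — only viable if both atoms can still be satisfied
    remaining_ok <- function(i) {
      if (!needs[i] || sat[i]) return(TRUE)
      later <- ar_bonds[seq_len(length(ar_bonds)) > b_idx]
      any(mol$bond_a[later] == i | mol$bond_b[later] == i)
    }
    if (remaining_ok(a) && remaining_ok(b) && solve(b_idx + 1L)) return(TRUE)
    FALSE
  }
  if (!solve(1L)) stop("kekulization failed")
  out <- mol
  out$bond_order[ar_bonds] <- assign_orders
  out$hexp[ar_atoms] <- hc[ar_atoms]
  out$aromatic[ar_atoms] <- FALSE
  validate_molecule(out)
  out
}

#' Perceive aromaticity on a kekulized graph
#'
#' Marks 5- and 6-membered rings as aromatic when every ring atom is C, N, O
#' or S and the ring pi-electron count is six, counting one electron for each
#' atom carrying a double bond to a ring atom and two for lone-pair
#' heteroatoms. Handles benzene-, pyridine-, pyrrole-, furan- and
#' thiophene-like rings and their fused combinations; it is not a full
#' Hueckel treatment.
#'
#' @param mol a `molecule` with kekulized bonds.
#' @return the molecule with aromatic flags set on qualifying rings.
#' @export
perceive_aromaticity <- function(mol) {
  if (any(mol$bond_order == 4L)) return(mol) # already aromatic-typed
  rs <- smallest_rings(mol)
  rs <- rs[vapply(rs, length, integer(1)) %in% c(5L, 6L)]
  if (!length(rs)) return(mol)
  hc <- hydrogen_count(mol)
  deg <- atom_degree(mol)
  in_any_ring <- unique(unlist(rs))
  has_ring_double <- vapply(seq_len(n_atoms(mol)), function(i) {
    sel <- (mol$bond_a == i | mol$bond_b == i) & mol$bond_order == 2L
    if (!any(sel)) return(FALSE)
    others <- ifelse(mol$bond_a[sel] == i, mol$bond_b[sel], mol$bond_a[sel])
    any(others %in% in_any_ring)
  }, logical(1))
  arom_atoms <- logical(n_atoms(mol))
  arom_bonds <- logical(n_bonds(mol))
  for (ring in rs) {
    pi <- 0L; ok <- TRUE
    for (i in ring) {
      el <- mol$element[i]
      if (!(el %in% c("C", "N", "O", "S"))) { ok <- FALSE; break }
      if (has_ring_double[i]) {
        pi <- pi + 1L
      } else if (el %in% c("O", "S") ||
                 (el == "N" && (hc[i] > 0L || deg[i] >= 3L || mol$charge[i] < 0L))) {
        pi <- pi + 2L
      } else { ok <- FALSE; break }
    }
    if (ok && pi == 6L) {
      arom_atoms[ring] <- TRUE
      sel <- mol$bond_a %in% ring & mol$bond_b %in% ring
      arom_bonds[sel] <- TRUE
    }
  }
  if (!any(arom_atoms)) return(mol)
  out <- mol
  out$aromatic <- out$aromatic | arom_atoms
  out$hexp[arom_atoms] <- hc[arom_atoms]
  out$bond_order[arom_bonds] <- 4L
  out
}
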