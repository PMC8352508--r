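## Circular fingerprints and Tanimoto similarity.
##
## Structural flavor ("morgan_r2_1024"): iterated neighborhood hashing of
## element-based atom invariants, radius 2, folded to 1024 bits (ECFP4-like).
## Functional flavor ("functional_fcfp6like"): the same construction over
## pharmacophoric atom roles (donor / acceptor / aromatic / halogen / basic /
## acidic), radius 3 (FCFP6-like). The integer mixing hash is fixed and
## versioned (hash_ints, v1) so bit patterns are stable across runs and
## platforms.

FP_BITS_DEFAULT <- 1024L

morgan_atom_invariants <- function(mol) {
  hc <- hydrogen_count(mol)
  deg <- atom_degree(mol)
  el_code <- match(mol$element, c("C", "N", "O", "S", "F", "Cl", "Br", "I",
                                  "P", "B", "Se", "Si"))
  el_code[is.na(el_code)] <- 99L
  vapply(seq_len(n_atoms(mol)), function(i) {
    hash_ints(c(1L, el_code[i], mol$charge[i] + 10L,
                as.integer(mol$aromatic[i]), hc[i], deg[i]))
  }, numeric(1))
}

functional_atom_invariants <- function(mol) {
  hc <- hydrogen_count(mol)
  roles <- atom_pharmacophore_roles(mol, hc)
  vapply(seq_len(n_atoms(mol)), function(i) {
    hash_ints(c(2L, roles[i, ]))
  }, numeric(1))
}

# Pharmacophoric role bits per atom: donor, acceptor, aromatic, halogen,
# basic (protonatable N), acidic (deprotonatable O / charged acid).
atom_pharmacophore_roles <- function(mol, hc = hydrogen_count(mol)) {
  n <- n_atoms(mol)
  el <- mol$element
  donor <- (el %in% c("N", "O", "S")) & hc > 0L
  acceptor <- (el %in% c("N", "O")) & mol$charge <= 0L
  halogen <- el %in% c("F", "Cl", "Br", "I")
  basic <- logical(n)
  acidic <- logical(n)
  for (i in seq_len(n)) {
    if (el[i] == "N" && !mol$aromatic[i]) {
      nb <- neighbors(mol, i)
      # amine-like: no multiple bonds, not adjacent to carbonyl carbon (amide)
      amide <- any(vapply(nb$atom, function(j) {
        if (mol$element[j] != "C") return(FALSE)
        nj <- neighbors(mol, j)
        any(nj$order == 2L & mol$element[nj$atom] == "O")
      }, logical(1)))
      basic[i] <- mol$charge[i] > 0L || (all(nb$order == 1L) && !amide)
    }
    if (el[i] == "O") {
      if (mol$charge[i] < 0L) acidic[i] <- TRUE
      else if (hc[i] > 0L) {
        nb <- neighbors(mol, i)
        # hydroxyl on a carbon that also bears =O (carboxyl / sulfonic-like)
        acidic[i] <- any(vapply(nb$atom, function(j) {
          nj <- neighbors(mol, j)
          any(nj$order == 2L & mol$element[nj$atom] == "O")
        }, logical(1)))
      }
    }
  }
  cbind(donor = as.integer(donor), acceptor = as.integer(acceptor),
        aromatic = as.integer(mol$aromatic), halogen = as.integer(halogen),
        basic = as.integer(basic), acidic = as.integer(acidic))
}

circular_fingerprint <- function(mol, invariants, radius, nbits, flavor) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (k in seq_len(n_bonds(mol))) {
    a <- mol$bond_a[k]; b <- mol$bond_b[k]; o <- mol$bond_order[k]
    adj[[a]] <- rbind(adj[[a]], c(b, o))
    adj[[b]] <- rbind(adj[[b]], c(a, o))
  }
  ids <- invariants
  all_ids <- ids
  for (r in seq_len(radius)) {
    new_ids <- ids
    for (i in seq_len(n)) {
      nb <- adj[[i]]
      if (is.null(nb)) next
      env <- nb[order(nb[, 2L], ids[nb[, 1L]]), , drop = FALSE]
      new_ids[i] <- hash_ints(c(r, ids[i], t(cbind(env[, 2L], ids[env[, 1L]]))))
    }
    ids <- new_ids
    all_ids <- c(all_ids, ids)
  }
  bits <- sort(unique(as.integer(floor(all_ids)) %% nbits))
  structure(list(length = nbits, bits = bits, flavor = flavor),
            class = "fingerprint")
}

#' Morgan (circular) structural fingerprint
#'
#' Radius-2 circular environments hashed and folded to 1024 bits; invariant
#' under atom relabelling.
#'
#' @param mol a `molecule`.
#' @param nbits bit length (default 1024).
#' @return a `fingerprint`: list with `length`, sorted 0-based `bits`, `flavor`.
#' @export
morgan_fingerprint <- function(mol, nbits = FP_BITS_DEFAULT) {
  circular_fingerprint(mol, morgan_atom_invariants(mol), 2L, nbits,
                       "morgan_r2_1024")
}

#' Functional (pharmacophoric) circular fingerprint
#'
#' FCFP6-like: radius-3 circular environments over pharmacophoric atom roles
#' (donor, acceptor, aromatic, halogen, basic, acidic) folded to 1024 bits.
#'
#' @inheritParams morgan_fingerprint
#' @return a `fingerprint`.
#' @export
functional_fingerprint <- function(mol, nbits = FP_BITS_DEFAULT) {
  circular_fingerprint(mol, functional_atom_invariants(mol), 3L, nbits,
                       "functional_fcfp6like")
}

#' Tanimoto similarity of two fingerprints
#'
#' \eqn{|A \cap B| / |A \cup B|} over set bits. Two empty fingerprints have
#' similarity 0 (with a warning).
#'
#' @param a,b `fingerprint` objects of the same flavor and length.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (!identical(a$flavor, b$flavor) || a$length != b$length)
    stop("fingerprint flavor/length mismatch")
  if (!length(a$bits) && !length(b$bits)) {
    warning("both fingerprints empty; Tanimoto defined as 0")
    return(0)
  }
  inter <- length(intersect(a$bits, b$bits))
  inter / (length(a$bits) + length(b$bits) - inter)
}

# Dense logical matrix (molecules x bits) for bulk Tanimoto computations.
fp_matrix <- function(fps) {
  nbits <- fps[[1L]]$length
  m <- matrix(FALSE, length(fps), nbits)
  for (i in seq_along(fps)) m[i, fps[[i]]$bits + 1L] <- TRUE
  m
}

# All-pairs Tanimoto between rows of two fingerprint matrices.
tanimoto_matrix <- function(ma, mb) {
  inter <- ma %*% t(mb)
  ca <- rowSums(ma); cb <- rowSums(mb)
  uni <- outer(ca, cb, "+") - inter
  out <- inter / uni
  out[uni == 0] <- 0
  out
}
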