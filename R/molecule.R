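## Heavy-atom molecular graph model.
##
## A `molecule` is a flat list of parallel vectors (fast to copy and mutate,
## which the bond-by-bond generator relies on):
##   element  character, element symbols ("C", "Cl", ...)
##   charge   integer, formal charges
##   aromatic logical, per-atom aromatic flag
##   hexp     integer, explicit hydrogen count from input ([nH] etc.), NA = implicit
##   bond_a, bond_b  integer atom indices (1-based)
##   bond_order      integer code: 1, 2, 3 single/double/triple, 4 aromatic
## Hydrogens are implicit throughout; all counts are heavy-atom only.

BOND_VALENCE <- c(1, 2, 3, 1.5) # valence contribution per bond-order code

#' Construct a molecule
#'
#' Builds a heavy-atom molecular graph from atom and bond tables and validates
#' its structural invariants (index ranges, no duplicate or self bonds).
#'
#' @param element character vector of element symbols.
#' @param bond_a,bond_b integer vectors of 1-based bond endpoint indices.
#' @param bond_order integer vector of bond-order codes (1, 2, 3, or 4 for
#'   aromatic).
#' @param charge integer vector of formal charges (default 0).
#' @param aromatic logical vector of per-atom aromatic flags.
#' @param hexp integer vector of explicit hydrogen counts; `NA` means implicit.
#' @param name optional molecule name.
#' @return An object of class `molecule`.
#' @export
molecule <- function(element, bond_a = integer(), bond_b = integer(),
                     bond_order = integer(), charge = NULL, aromatic = NULL,
                     hexp = NULL, name = NULL) {
  n <- length(element)
  m <- length(bond_a)
  stopifnot(length(bond_b) == m, length(bond_order) == m)
  mol <- structure(list(
    element = as.character(element),
    charge = as.integer(charge %||% rep(0L, n)),
    aromatic = as.logical(aromatic %||% rep(FALSE, n)),
    hexp = as.integer(hexp %||% rep(NA_integer_, n)),
    bond_a = as.integer(bond_a),
    bond_b = as.integer(bond_b),
    bond_order = as.integer(bond_order),
    name = name
  ), class = "molecule")
  validate_molecule(mol)
  mol
}

validate_molecule <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0L) stop("molecule must have at least one atom")
  a <- mol$bond_a; b <- mol$bond_b
  if (length(a) && (any(a < 1L | a > n) || any(b < 1L | b > n)))
    stop("bond endpoint out of range")
  if (any(a == b)) stop("self-bond not permitted")
  if (length(a)) {
    key <- paste(pmin(a, b), pmax(a, b))
    if (anyDuplicated(key)) stop("duplicate bond")
  }
  if (!all(mol$bond_order %in% 1:4)) stop("bond order must be 1, 2, 3 or 4")
  invisible(mol)
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule>", if (!is.null(x$name)) x$name else "", "\n")
  cat("  atoms:", n_atoms(x), " bonds:", n_bonds(x), "\n")
  smi <- tryCatch(write_smiles(x), error = function(e) "<unwritable>")
  cat("  smiles:", smi, "\n")
  invisible(x)
}

#' Number of heavy atoms / bonds in a molecule
#' @param mol a `molecule`.
#' @return integer count.
#' @export
n_atoms <- function(mol) length(mol$element)

#' @rdname n_atoms
#' @export
n_bonds <- function(mol) length(mol$bond_a)

# Per-atom sum of bond-order valence contributions. Aromatic systems follow
# the kekulized accounting: an atom with k aromatic bonds contributes k + 1
# when it takes a double bond in any kekule structure (C; N without H, a third
# connection or negative charge) and k when it donates a lone pair (O, S,
# pyrrole-type N).
bond_order_sum <- function(mol) {
  n <- n_atoms(mol)
  s <- numeric(n)
  if (!n_bonds(mol)) return(s)
  plain <- mol$bond_order != 4L
  if (any(plain)) {
    v <- BOND_VALENCE[mol$bond_order[plain]]
    s <- s + tabulate2(mol$bond_a[plain], v, n) +
      tabulate2(mol$bond_b[plain], v, n)
  }
  if (any(!plain)) {
    nar <- tabulate(c(mol$bond_a[!plain], mol$bond_b[!plain]), nbins = n)
    deg <- atom_degree(mol)
    exo_double <- tabulate(c(mol$bond_a[plain & mol$bond_order >= 2L],
                             mol$bond_b[plain & mol$bond_order >= 2L]),
                           nbins = n) > 0L
    for (i in which(nar > 0L)) {
      el <- mol$element[i]
      lone_pair <- el %in% c("O", "S") || exo_double[i] ||
        (el == "N" && (isTRUE(mol$hexp[i] > 0L) || deg[i] >= 3L || mol$charge[i] < 0L))
      s[i] <- s[i] + nar[i] + if (lone_pair) 0 else 1
    }
  }
  s
}

tabulate2 <- function(idx, w, n) {
  out <- numeric(n)
  for (i in seq_along(idx)) out[idx[i]] <- out[idx[i]] + w[i]
  out
}

# Per-atom heavy-neighbor degree.
atom_degree <- function(mol) {
  tabulate(c(mol$bond_a, mol$bond_b), nbins = n_atoms(mol))
}

# Standard valence levels used to infer implicit hydrogens (SMILES convention).
VALENCE_LEVELS <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

# Charge-adjusted default valence used for implicit-H inference.
charged_default_valence <- function(element, charge) {
  base <- VALENCE_LEVELS[[element]]
  if (is.null(base)) return(NULL)
  if (charge == 0L) return(base)
  adj <- switch(paste0(element, charge),
    "N1" = 4, "N-1" = 2, "O-1" = 1, "O1" = 3, "S-1" = 1, "S1" = 3,
    "C1" = 3, "C-1" = 3, "B-1" = 4, "P1" = 4,
    NULL
  )
  adj %||% max(base)
}

# Resolved hydrogen count per atom: explicit where given, otherwise the gap to
# the smallest standard valence level that accommodates the bond-order sum.
hydrogen_count <- function(mol) {
  bs <- bond_order_sum(mol)
  h <- integer(n_atoms(mol))
  for (i in seq_len(n_atoms(mol))) {
    if (!is.na(mol$hexp[i])) { h[i] <- mol$hexp[i]; next }
    lev <- charged_default_valence(mol$element[i], mol$charge[i])
    if (is.null(lev)) { h[i] <- 0L; next }
    fit <- lev[lev >= bs[i] - 1e-9]
    h[i] <- if (length(fit)) as.integer(floor(min(fit) - bs[i] + 1e-9)) else 0L
  }
  h
}

# Neighbor list: for atom i, matrix-free vectors of (neighbor, bond order code).
neighbors <- function(mol, i) {
  sel_a <- mol$bond_a == i
  sel_b <- mol$bond_b == i
  list(
    atom = c(mol$bond_b[sel_a], mol$bond_a[sel_b]),
    order = c(mol$bond_order[sel_a], mol$bond_order[sel_b])
  )
}

adjacency_list <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer()
  for (k in seq_len(n_bonds(mol))) {
    a <- mol$bond_a[k]; b <- mol$bond_b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

is_connected <- function(mol) {
  n <- n_atoms(mol)
  if (n == 1L) return(TRUE)
  adj <- adjacency_list(mol)
  seen <- logical(n); seen[1L] <- TRUE; queue <- 1L
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[i]][!seen[adj[[i]]]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Element counts of a molecule
#'
#' Heavy-atom composition: total count plus per-element counts. Counts for
#' C, N, O, S, Cl and F are always present (zero allowed); other elements are
#' appended when present.
#'
#' @param mol a `molecule`.
#' @return named integer vector with `total` first.
#' @export
element_counts <- function(mol) {
  base <- c("C", "N", "O", "S", "Cl", "F")
  tab <- table(mol$element)
  out <- stats::setNames(integer(length(base)), base)
  out[intersect(names(tab), base)] <- as.integer(tab[intersect(names(tab), base)])
  extra <- setdiff(names(tab), base)
  if (length(extra)) out <- c(out, stats::setNames(as.integer(tab[extra]), extra))
  c(total = n_atoms(mol), out)
}

# Key identifying the composition bucket used by the pair builder: total heavy
# atoms plus the matched-element counts.
composition_key <- function(mol, elements = c("C", "N", "O", "S", "Cl", "F")) {
  ec <- element_counts(mol)
  cnt <- vapply(elements, function(e) if (e %in% names(ec)) ec[[e]] else 0L, integer(1))
  paste(c(ec[["total"]], cnt), collapse = "/")
}

#' Default atom vocabulary
#'
#' The permitted (element, formal charge) types and their maximum valences.
#' The default covers the common organic elements C, N, O, F, S, Cl, Br, I
#' together with their usual charged variants; rarer elements (e.g. phosphorus)
#' can be admitted by passing a custom table wherever a vocabulary is accepted.
#'
#' @param extra optional data.frame with columns `element`, `charge`,
#'   `max_valence` appended to the default table.
#' @return data.frame of class `atom_vocabulary`.
#' @export
default_vocabulary <- function(extra = NULL) {
  v <- data.frame(
    element = c("C", "N", "N", "N", "O", "O", "F", "S", "Cl", "Br", "I"),
    charge = c(0L, 0L, 1L, -1L, 0L, -1L, 0L, 0L, 0L, 0L, 0L),
    max_valence = c(4, 3, 4, 2, 2, 1, 1, 6, 1, 1, 1),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) v <- rbind(v, extra[, c("element", "charge", "max_valence")])
  if (anyDuplicated(paste(v$element, v$charge))) stop("duplicate vocabulary entries")
  class(v) <- c("atom_vocabulary", "data.frame")
  v
}

#' Check valence rules against an atom vocabulary
#'
#' An atom passes when its (element, charge) type is in the vocabulary and its
#' bond-order sum (aromatic bonds counting 1.5) does not exceed the permitted
#' maximum valence. Violations are reported, never thrown.
#'
#' @param mol a `molecule`.
#' @param vocab an atom vocabulary (see [default_vocabulary()]).
#' @return list with `valid` (logical) and `violations` (data.frame with
#'   columns `atom`, `reason`).
#' @export
check_valence <- function(mol, vocab = default_vocabulary()) {
  bs <- bond_order_sum(mol)
  viol <- list()
  key <- paste(vocab$element, vocab$charge)
  for (i in seq_len(n_atoms(mol))) {
    k <- paste(mol$element[i], mol$charge[i])
    j <- match(k, key)
    if (is.na(j)) {
      viol[[length(viol) + 1L]] <- data.frame(
        atom = i, reason = sprintf("type not permitted: %s charge %+d",
                                   mol$element[i], mol$charge[i]))
    } else if (bs[i] > vocab$max_valence[j] + 1e-9) {
      viol[[length(viol) + 1L]] <- data.frame(
        atom = i, reason = sprintf("bond-order sum %.1f exceeds valence %d",
                                   bs[i], as.integer(vocab$max_valence[j])))
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(atom = integer(), reason = character())
  list(valid = nrow(violations) == 0L, violations = violations)
}
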