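## SMILES reading and writing.
##
## Supported dialect: the organic subset (B C N O P S F Cl Br I, aromatic
## b c n o p s), bracket atoms with charge and explicit H, branches, ring
## closures (digits and %nn), bond symbols - = # :. Stereo markers (/ \ @) are
## accepted and ignored (stereochemistry is a non-goal); multi-fragment
## records ('.') are rejected.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_OK <- c("B", "C", "N", "O", "P", "S")

#' Parse a single SMILES string
#'
#' @param smiles a SMILES string.
#' @param name optional molecule name.
#' @return a `molecule`.
#' @export
parse_smiles <- function(smiles, name = NULL) {
  s <- gsub("[/\\\\]", "", smiles) # drop cis/trans markers
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  if (n == 0L) stop("empty SMILES")

  element <- character(); charge <- integer(); aromatic <- logical()
  hexp <- integer()
  bond_a <- integer(); bond_b <- integer(); bond_order <- integer()
  prev <- NA_integer_
  stack <- integer()
  pending <- NA_integer_ # explicit bond symbol awaiting next atom
  rings <- list()        # ring-closure label -> list(atom, order)

  add_atom <- function(el, chg, arom, h) {
    element[length(element) + 1L] <<- el
    charge[length(charge) + 1L] <<- chg
    aromatic[length(aromatic) + 1L] <<- arom
    hexp[length(hexp) + 1L] <<- h
    idx <- length(element)
    if (!is.na(prev)) {
      ord <- pending
      if (is.na(ord)) ord <- if (arom && aromatic[prev]) 4L else 1L
      bond_a[length(bond_a) + 1L] <<- prev
      bond_b[length(bond_b) + 1L] <<- idx
      bond_order[length(bond_order) + 1L] <<- ord
    }
    pending <<- NA_integer_
    prev <<- idx
  }

  close_ring <- function(label) {
    ord <- pending; pending <<- NA_integer_
    if (is.null(rings[[label]])) {
      rings[[label]] <<- list(atom = prev, order = ord)
    } else {
      open <- rings[[label]]
      rings[[label]] <<- NULL
      ord <- if (!is.na(ord)) ord else if (!is.na(open$order)) open$order
             else if (aromatic[prev] && aromatic[open$atom]) 4L else 1L
      if (open$atom == prev) stop("ring closure to self")
      bond_a[length(bond_a) + 1L] <<- open$atom
      bond_b[length(bond_b) + 1L] <<- prev
      bond_order[length(bond_order) + 1L] <<- ord
    }
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket atom")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      at <- parse_bracket_atom(body)
      add_atom(at$element, at$charge, at$aromatic, at$h)
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      add_atom(paste0(ch, chars[i + 1L]), 0L, FALSE, NA_integer_)
      i <- i + 2L
    } else if (ch %in% ORGANIC_SUBSET) {
      add_atom(ch, 0L, FALSE, NA_integer_)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(toupper(ch), 0L, TRUE, NA_integer_)
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) stop("branch with no preceding atom")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == "-") { pending <- 1L; i <- i + 1L
    } else if (ch == "=") { pending <- 2L; i <- i + 1L
    } else if (ch == "#") { pending <- 3L; i <- i + 1L
    } else if (ch == ":") { pending <- 4L; i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("truncated %nn ring label")
      close_ring(paste(chars[(i + 1L):(i + 2L)], collapse = ""))
      i <- i + 3L
    } else if (grepl("[0-9]", ch)) {
      if (is.na(prev)) stop("ring closure with no preceding atom")
      close_ring(ch)
      i <- i + 1L
    } else if (ch == ".") {
      stop("multi-fragment SMILES not supported")
    } else {
      stop(sprintf("unexpected character '%s' at position %d", ch, i))
    }
  }
  if (length(stack)) stop("unmatched '('")
  if (length(rings)) stop("unclosed ring bond(s)")
  if (!length(element)) stop("no atoms parsed")
  mol <- molecule(element, bond_a, bond_b, bond_order,
                  charge = charge, aromatic = aromatic, hexp = hexp, name = name)
  if (!is_connected(mol)) stop("disconnected molecule")
  mol
}

parse_bracket_atom <- function(body) {
  m <- regexec(
    "^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H([0-9]*))?(([+-])([0-9]*)|(\\+\\+)|(--))?$",
    body)
  g <- regmatches(body, m)[[1]]
  if (!length(g)) stop(sprintf("cannot parse bracket atom [%s]", body))
  sym <- g[3]
  arom <- sym %in% c("b", "c", "n", "o", "p", "s", "se", "as")
  el <- if (arom) paste0(toupper(substr(sym, 1, 1)), substring(sym, 2)) else sym
  if (arom && !(el %in% AROMATIC_OK)) stop("unsupported aromatic element")
  h <- if (g[5] == "") 0L else if (g[6] == "") 1L else as.integer(g[6])
  chg <- 0L
  if (g[10] == "++") chg <- 2L
  else if (g[11] == "--") chg <- -2L
  else if (g[8] %in% c("+", "-")) {
    mag <- if (g[9] == "") 1L else as.integer(g[9])
    chg <- if (g[8] == "+") mag else -mag
  }
  list(element = el, charge = chg, aromatic = arom, h = h)
}

## ---- writing ----------------------------------------------------------

#' Write a molecule as SMILES
#'
#' With `canonical = TRUE` atoms are traversed in the canonical order of
#' [canonical_order()], so isomorphic graphs yield identical strings.
#'
#' @param mol a `molecule`.
#' @param canonical traverse in canonical order?
#' @return a SMILES string.
#' @export
write_smiles <- function(mol, canonical = TRUE) {
  ord <- if (canonical) canonical_order(mol) else seq_len(n_atoms(mol))
  pos <- match(seq_len(n_atoms(mol)), ord) # pos[i] = priority of atom i
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (k in seq_len(n_bonds(mol))) {
    a <- mol$bond_a[k]; b <- mol$bond_b[k]
    adj[[a]] <- rbind(adj[[a]], c(b, mol$bond_order[k]))
    adj[[b]] <- rbind(adj[[b]], c(a, mol$bond_order[k]))
  }
  hc <- hydrogen_count(mol)

  visited <- logical(n)
  ring_label <- 0L
  ring_open <- vector("list", n) # atom -> vector of labels to emit
  tree_child <- vector("list", n)
  ring_bond_order <- list()      # "a|b" -> order

  # DFS over the canonical order to classify tree vs ring-closure bonds.
  root <- ord[1L]
  parent <- integer(n)
  parent[root] <- 0L
  visited[root] <- TRUE
  dfs <- function(u) {
    nb <- adj[[u]]
    if (is.null(nb)) return(invisible())
    nbr <- nb[order(pos[nb[, 1L]]), , drop = FALSE]
    for (r in seq_len(nrow(nbr))) {
      v <- nbr[r, 1L]; o <- nbr[r, 2L]
      if (!visited[v]) {
        visited[v] <<- TRUE
        parent[v] <<- u
        tree_child[[u]] <<- c(tree_child[[u]], v)
        dfs(v)
      } else if (v != parent[u]) {
        key <- paste(min(u, v), max(u, v))
        if (is.null(ring_bond_order[[key]])) {
          ring_label <<- ring_label + 1L
          ring_bond_order[[key]] <<- c(ring_label, o)
          ring_open[[v]] <<- rbind(ring_open[[v]], c(ring_label, o, u))
          ring_open[[u]] <<- rbind(ring_open[[u]], c(ring_label, o, v))
        }
      }
    }
  }
  dfs(root)
  if (!all(visited)) stop("cannot write disconnected molecule")

  bond_sym <- function(o, u, v) {
    if (o == 1L) {
      # explicit single needed between two aromatic atoms (e.g. biphenyl)
      if (mol$aromatic[u] && mol$aromatic[v]) "-" else ""
    } else if (o == 2L) "=" else if (o == 3L) "#" else ""
  }

  atom_token <- function(i) {
    el <- mol$element[i]
    sym <- if (mol$aromatic[i]) tolower(el) else el
    # would a bare symbol re-parse with the right H count?
    plain_ok <- el %in% ORGANIC_SUBSET && mol$charge[i] == 0L &&
      (!mol$aromatic[i] || el %in% AROMATIC_OK)
    if (plain_ok) {
      # simulate how a fresh parse (hexp unknown) would infer hydrogens
      probe <- charged_default_valence(el, 0L)
      sel <- mol$bond_a == i | mol$bond_b == i
      ords <- mol$bond_order[sel]
      k_ar <- sum(ords == 4L)
      bs <- sum(BOND_VALENCE[ords[ords != 4L]])
      if (k_ar > 0L) {
        deg_i <- sum(sel)
        lone_pair <- el %in% c("O", "S") || any(ords %in% c(2L, 3L)) ||
          (el == "N" && deg_i >= 3L)
        bs <- bs + k_ar + if (lone_pair) 0 else 1
      }
      fit <- probe[probe >= bs - 1e-9]
      h_implied <- if (length(fit)) as.integer(floor(min(fit) - bs + 1e-9)) else 0L
      if (h_implied == hc[i]) return(sym)
    }
    chg <- mol$charge[i]
    chg_s <- if (chg == 0L) "" else if (chg == 1L) "+" else if (chg == -1L) "-"
             else sprintf("%+d", chg)
    h_s <- if (hc[i] == 0L) "" else if (hc[i] == 1L) "H" else paste0("H", hc[i])
    paste0("[", sym, h_s, chg_s, "]")
  }

  emit <- function(u) {
    out <- atom_token(u)
    ro <- ring_open[[u]]
    if (!is.null(ro)) {
      ro <- ro[order(ro[, 1L]), , drop = FALSE]
      for (r in seq_len(nrow(ro))) {
        lab <- ro[r, 1L]; o <- ro[r, 2L]; other <- ro[r, 3L]
        sym <- bond_sym(o, u, other)
        lab_s <- if (lab > 9L) paste0("%", sprintf("%02d", lab)) else as.character(lab)
        out <- paste0(out, sym, lab_s)
      }
    }
    kids <- tree_child[[u]]
    if (length(kids)) {
      for (k in seq_along(kids)) {
        v <- kids[k]
        o <- bond_order_between(mol, u, v)
        seg <- paste0(bond_sym(o, u, v), emit(v))
        out <- if (k < length(kids)) paste0(out, "(", seg, ")")
               else paste0(out, seg)
      }
    }
    out
  }
  emit(root)
}

bond_order_between <- function(mol, u, v) {
  sel <- (mol$bond_a == u & mol$bond_b == v) | (mol$bond_a == v & mol$bond_b == u)
  mol$bond_order[sel][1L]
}

#' Canonical SMILES of a molecule
#' @param mol a `molecule`.
#' @return a SMILES string, identical for isomorphic graphs.
#' @export
canonical_smiles <- function(mol) write_smiles(mol, canonical = TRUE)
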