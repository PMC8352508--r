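## Octanol/water partition coefficient by an atom-contribution method:
## a reduced Wildman-Crippen typing scheme (heavy-atom types plus hydrogen
## types, contributions from the published table). The method identifier
## "wildman_crippen_reduced_v1" is recorded in bias-report metadata.

LOGP_METHOD <- "wildman_crippen_reduced_v1"

logp_contribution <- function(mol, i, hc, deg) {
  el <- mol$element[i]
  nb <- neighbors(mol, i)
  nb_el <- mol$element[nb$atom]
  nb_arom <- mol$aromatic[nb$atom]
  has_double_het <- any(nb$order == 2L & nb_el %in% c("N", "O", "S"))
  het_nb <- any(nb_el %in% c("N", "O", "S", "P", "F", "Cl", "Br", "I"))
  if (el == "C") {
    if (mol$aromatic[i]) {
      if (hc[i] > 0L) return(0.1581)
      sub <- nb$atom[!nb_arom | nb$order != 4L]
      if (!length(sub)) return(0.2955)               # fused / bridgehead
      s_el <- mol$element[sub[1L]]
      return(switch(s_el, C = if (mol$aromatic[sub[1L]]) 0.2955 else 0.1360,
                    O = 0.5437, N = 0.4619, S = 0.1893, F = 0.2450,
                    Cl = 0.1893, Br = 0.1893, I = 0.1893, 0.1360))
    }
    if (any(nb$order == 3L)) return(0.0017)          # sp carbon
    if (any(nb$order == 2L)) {
      return(if (has_double_het) -0.2783 else 0.1551) # carbonyl-like vs alkene
    }
    if (het_nb) return(if (hc[i] >= 2L) -0.2035 else -0.2051)
    if (any(nb_arom)) return(if (hc[i] >= 2L) -0.0516 else 0.1193)
    return(if (hc[i] >= 2L) 0.1441 else 0.0000)
  }
  if (el == "N") {
    if (mol$aromatic[i]) return(-0.3239)
    if (any(nb$order == 3L)) return(0.0151)          # nitrile
    if (mol$charge[i] > 0L) return(-0.3396)
    return(-1.0190)
  }
  if (el == "O") {
    if (mol$charge[i] < 0L) return(-1.3260)
    if (mol$aromatic[i]) return(0.1552)
    if (any(nb$order == 2L)) {                       # =O
      if (any(nb_el == "S")) return(-0.3339)
      partner <- nb$atom[nb$order == 2L][1L]
      pn <- neighbors(mol, partner)
      acid <- any(mol$element[pn$atom] == "O" & pn$order == 1L &
                    hc[pn$atom] > 0L)
      return(if (acid) 0.1129 else -0.1526)
    }
    if (hc[i] > 0L) return(-0.2893)                  # hydroxyl
    # ether: conjugated (aromatic or acyl neighbor) vs aliphatic
    acylic <- any(vapply(nb$atom, function(j) {
      nj <- neighbors(mol, j)
      any(nj$order == 2L & mol$element[nj$atom] == "O")
    }, logical(1)))
    return(if (any(nb_arom) || acylic) -0.4195 else -0.0684)
  }
  if (el == "S") {
    if (mol$aromatic[i]) return(0.6237)
    if (any(nb$order == 2L & nb_el == "O")) return(-0.0024)
    return(0.6482)
  }
  switch(el, F = 0.4202, Cl = 0.6895, Br = 0.8456, I = 0.8857,
         P = 0.8612, B = -0.3187, 0)
}

logp_hydrogen_contribution <- function(mol, i, hc) {
  if (hc[i] == 0L) return(0)
  el <- mol$element[i]
  per_h <- if (el == "C") 0.1230
    else if (el == "N") 0.2142
    else if (el == "S") -0.2677
    else if (el == "O") {
      nb <- neighbors(mol, i)
      acid <- any(vapply(nb$atom, function(j) {
        nj <- neighbors(mol, j)
        any(nj$order == 2L & mol$element[nj$atom] %in% c("O", "S"))
      }, logical(1)))
      if (acid) 0.2980 else -0.2677
    } else 0.1125
  hc[i] * per_h
}

#' Atom-contribution logP
#'
#' Crippen-style octanol/water partition estimate: each heavy atom and its
#' hydrogens contribute a typed increment; the sum is the estimate.
#'
#' @param mol a `molecule`.
#' @return numeric logP estimate.
#' @export
logp <- function(mol) {
  hc <- hydrogen_count(mol)
  deg <- atom_degree(mol)
  sum(vapply(seq_len(n_atoms(mol)), function(i) {
    logp_contribution(mol, i, hc, deg) + logp_hydrogen_contribution(mol, i, hc)
  }, numeric(1)))
}
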