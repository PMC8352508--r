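## Deterministic fixtures: random valence-respecting molecule assembly and
## synthetic property populations with controllable class separation. These
## drive every test without any external download; they emulate descriptor
## and graph diversity, not bioactivity.

#' Generate a random library of valid small molecules
#'
#' Molecules are assembled by random tree growth over a weighted element
#' palette followed by optional ring closures; every bond respects the
#' element's maximum valence, so all outputs pass [check_valence()] by
#' construction. Aromaticity is then perceived on qualifying rings.
#' Bit-reproducible under `seed`.
#'
#' @param n number of molecules.
#' @param atom_range integer range (min, max) of heavy atoms per molecule.
#' @param palette character vector of element symbols (must be a subset of the
#'   default vocabulary).
#' @param palette_weights sampling weights (default favors carbon).
#' @param ring_prob probability of attempting a ring closure per molecule.
#' @param double_prob probability that a new bond is a double bond (valence
#'   permitting).
#' @param seed integer seed.
#' @return list of `molecule` objects named `fix_<i>`.
#' @export
make_library <- function(n, atom_range = c(5L, 14L),
                         palette = c("C", "N", "O", "S", "Cl", "F"),
                         palette_weights = NULL, ring_prob = 0.6,
                         double_prob = 0.12, seed = 1L) {
  vocab <- default_vocabulary()
  if (!all(palette %in% vocab$element))
    stop("palette outside default vocabulary")
  if (atom_range[1L] < 1L) stop("infeasible atom range")
  if (is.null(palette_weights)) {
    palette_weights <- ifelse(palette == "C", 8, 1)
  }
  maxval <- vapply(palette, function(e)
    vocab$max_valence[vocab$element == e & vocab$charge == 0L][1L], numeric(1))
  # halogens and other valence-1 types cannot carry growth on their own
  if (all(maxval[palette_weights > 0] <= 1) && atom_range[2L] > 2L)
    stop("infeasible spec: palette cannot grow molecules of requested size")
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      size <- sample(atom_range[1L]:atom_range[2L], 1L)
      mol <- grow_molecule(size, palette, palette_weights, maxval,
                           ring_prob, double_prob)
      mol$name <- sprintf("fix_%03d", i)
      mol
    })
  })
}

grow_molecule <- function(size, palette, weights, maxval, ring_prob,
                          double_prob) {
  # grow a tree: attach each new atom to an existing atom with free valence
  pick <- function(k) sample(seq_along(palette), k, replace = TRUE,
                             prob = weights)
  repeat {
    first <- pick(1L)
    if (size == 1L || maxval[first] >= 1) break
  }
  element <- palette[first]
  free <- maxval[first]
  bond_a <- integer(); bond_b <- integer(); bond_order <- integer()
  while (length(element) < size) {
    open <- which(free >= 1)
    if (!length(open)) break # all valence consumed; accept a smaller molecule
    t <- pick(1L)
    host <- if (length(open) == 1L) open else sample(open, 1L)
    ord <- if (stats::runif(1) < double_prob && free[host] >= 2 &&
                 maxval[t] >= 2) 2L else 1L
    element <- c(element, palette[t])
    free <- c(free - 0, maxval[t] - ord)
    free[host] <- free[host] - ord
    bond_a <- c(bond_a, host)
    bond_b <- c(bond_b, length(element))
    bond_order <- c(bond_order, ord)
  }
  mol <- molecule(element, bond_a, bond_b, bond_order)
  # optional ring closure between distant atoms with spare valence
  if (n_atoms(mol) >= 5L && stats::runif(1) < ring_prob) {
    cand <- which(free >= 1)
    if (length(cand) >= 2L) {
      d <- graph_distances(mol, cand[1L])
      # prefer closures making 5- or 6-membered rings
      for (target_d in c(4L, 5L, 3L)) {
        partners <- cand[d[cand] == target_d]
        if (length(partners)) {
          mol <- molecule(mol$element, c(mol$bond_a, cand[1L]),
                          c(mol$bond_b, partners[1L]),
                          c(mol$bond_order, 1L))
          break
        }
      }
    }
  }
  perceive_aromaticity(mol)
}

graph_distances <- function(mol, from) {
  n <- n_atoms(mol)
  adj <- adjacency_list(mol)
  d <- rep(NA_integer_, n)
  d[from] <- 0L
  queue <- from
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[i]][is.na(d[adj[[i]]])]
    d[nb] <- d[i] + 1L
    queue <- c(queue, nb)
  }
  d
}

#' Synthetic property populations with controllable separation
#'
#' Draws `n_active` active and `n_decoy` decoy property vectors in `k`
#' dimensions: both classes are Gaussian clouds whose centers are
#' `separation` apart in property space, with the offset spread evenly over
#' all `k` axes (so the separation survives per-property z-scoring).
#' `separation = 0` gives one common distribution; large separations give
#' disjoint clusters (the complete-separation limit of the DOE score).
#'
#' @param n_active,n_decoy class sizes.
#' @param k number of properties.
#' @param separation distance between class centers.
#' @param noise_sd within-class standard deviation (0 = point clusters).
#' @param seed integer seed.
#' @return list with matrices `actives` (`n_active` x `k`) and `decoys`.
#' @export
make_separable_sets <- function(n_active, n_decoy, k, separation,
                                noise_sd = 1, seed = 1L) {
  stopifnot(k >= 1L)
  with_seed(seed, {
    actives <- matrix(stats::rnorm(n_active * k, 0, noise_sd), n_active, k)
    decoys <- matrix(stats::rnorm(n_decoy * k, 0, noise_sd), n_decoy, k)
    decoys <- decoys + separation / sqrt(k)
    colnames(actives) <- colnames(decoys) <- paste0("p", seq_len(k))
    list(actives = actives, decoys = decoys)
  })
}
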