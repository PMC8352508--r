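## Training-pair construction: pairs of molecules with (i) identical heavy
## atom count and matched-element counts, (ii) high property-space similarity
## (Euclidean distance between z-normalized property vectors below a
## threshold) and (iii) low structural similarity (Morgan/Tanimoto below a
## threshold). Criterion (i) is an exact equality, so bucketing molecules by
## composition makes the all-pairs scan lossless and tractable.

#' Pair-building configuration
#'
#' @param max_similarity maximum permitted structural Tanimoto (default 0.15).
#' @param max_distance maximum normalized property distance (0.20 for the
#'   high-dimensional run, 0.07 for the eight-property run).
#' @param property_set_name property set used for criterion (ii).
#' @param matched_elements elements whose counts must match exactly.
#' @param max_pairs_per_molecule cap on pair multiplicity per molecule
#'   (`Inf` = unlimited); excess pruned keeping smallest property distances.
#' @return list of class `pair_config`.
#' @export
pair_config <- function(max_similarity = 0.15, max_distance = 0.20,
                        property_set_name = "dekois8",
                        matched_elements = c("C", "N", "O", "S", "Cl", "F"),
                        max_pairs_per_molecule = Inf) {
  stopifnot(max_similarity > 0, max_similarity <= 1, max_distance > 0)
  structure(list(max_similarity = max_similarity, max_distance = max_distance,
                 property_set_name = property_set_name,
                 matched_elements = matched_elements,
                 max_pairs_per_molecule = max_pairs_per_molecule),
            class = "pair_config")
}

#' Bucket molecules by composition
#'
#' Partitions a library by the signature (total heavy atoms, counts of the
#' matched elements). Only same-bucket pairs can satisfy the exact-composition
#' pair criterion.
#'
#' @param library list of `molecule` objects.
#' @param matched_elements element symbols in the signature.
#' @return named list: signature -> integer indices into `library`.
#' @export
bucket_by_composition <- function(library,
                                  matched_elements = c("C", "N", "O", "S",
                                                       "Cl", "F")) {
  keys <- vapply(library, composition_key, character(1),
                 elements = matched_elements)
  split(seq_along(library), keys)
}

#' Build training pairs from a library
#'
#' Scans every same-composition pair and keeps those whose structural
#' Tanimoto (Morgan radius 2, 1024 bits) is at most `config$max_similarity`
#' and whose normalized property distance is at most `config$max_distance`.
#' The normalization population is the input library. Both orientations of
#' each accepted pair are emitted as training examples. Deterministic given
#' `seed`.
#'
#' @param library list of `molecule` objects (valence-valid).
#' @param pset a [property_set()].
#' @param config a [pair_config()].
#' @param seed integer seed (ordering/pruning determinism).
#' @return data.frame of class `molecule_pairs` with columns `a`, `b`
#'   (indices), `smiles_a`, `smiles_b`, `tanimoto`, `prop_distance`;
#'   attributes `rejections` (named counts) and `norm` (the normalization
#'   model).
#' @export
build_pairs <- function(library, pset, config = pair_config(), seed = 1L) {
  pm <- property_matrix(library, pset)
  norm <- fit_normalization(pm)
  z <- normalize_properties(pm, norm)
  fpm <- fp_matrix(lapply(library, morgan_fingerprint))
  buckets <- bucket_by_composition(library, config$matched_elements)

  acc_a <- integer(); acc_b <- integer()
  acc_sim <- numeric(); acc_dist <- numeric()
  rej <- c(similarity = 0L, property = 0L)
  for (idx in buckets) {
    if (length(idx) < 2L) next
    sim <- tanimoto_matrix(fpm[idx, , drop = FALSE], fpm[idx, , drop = FALSE])
    dst <- as.matrix(stats::dist(z[idx, , drop = FALSE]))
    for (i in seq_len(length(idx) - 1L)) {
      for (j in (i + 1L):length(idx)) {
        if (sim[i, j] > config$max_similarity) {
          rej["similarity"] <- rej["similarity"] + 1L
        } else if (dst[i, j] > config$max_distance) {
          rej["property"] <- rej["property"] + 1L
        } else {
          acc_a <- c(acc_a, idx[i]); acc_b <- c(acc_b, idx[j])
          acc_sim <- c(acc_sim, sim[i, j]); acc_dist <- c(acc_dist, dst[i, j])
        }
      }
    }
  }
  ord <- order(acc_dist, acc_a, acc_b)
  acc_a <- acc_a[ord]; acc_b <- acc_b[ord]
  acc_sim <- acc_sim[ord]; acc_dist <- acc_dist[ord]

  if (is.finite(config$max_pairs_per_molecule)) {
    used <- integer(length(library))
    keep <- logical(length(acc_a))
    for (k in seq_along(acc_a)) {
      if (used[acc_a[k]] < config$max_pairs_per_molecule &&
          used[acc_b[k]] < config$max_pairs_per_molecule) {
        keep[k] <- TRUE
        used[acc_a[k]] <- used[acc_a[k]] + 1L
        used[acc_b[k]] <- used[acc_b[k]] + 1L
      }
    }
    acc_a <- acc_a[keep]; acc_b <- acc_b[keep]
    acc_sim <- acc_sim[keep]; acc_dist <- acc_dist[keep]
  }

  if (!length(acc_a)) {
    warning(sprintf(
      "no pairs found (rejected: %d structural similarity, %d property distance)",
      rej["similarity"], rej["property"]), call. = FALSE)
  }
  smiles <- vapply(library, canonical_smiles, character(1))
  # both orientations are training examples
  out <- data.frame(
    a = c(acc_a, acc_b), b = c(acc_b, acc_a),
    smiles_a = c(smiles[acc_a], smiles[acc_b]),
    smiles_b = c(smiles[acc_b], smiles[acc_a]),
    tanimoto = c(acc_sim, acc_sim),
    prop_distance = c(acc_dist, acc_dist)
  )
  attr(out, "rejections") <- rej
  attr(out, "norm") <- norm
  class(out) <- c("molecule_pairs", "data.frame")
  out
}

#' Split pairs into training and validation sets
#'
#' @param pairs a `molecule_pairs` data.frame.
#' @param n_validation number of validation pairs.
#' @param seed integer seed; the same seed always reproduces the same split.
#' @return list with `train` and `validation` data.frames (disjoint).
#' @export
holdout_split <- function(pairs, n_validation, seed = 1L) {
  n <- nrow(pairs)
  if (n_validation >= n) stop("n_validation must be smaller than the pair count")
  if (n_validation == 0L) return(list(train = pairs, validation = pairs[0L, ]))
  idx <- with_seed(seed, sample.int(n, n_validation))
  list(train = pairs[-idx, , drop = FALSE],
       validation = pairs[idx, , drop = FALSE])
}
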