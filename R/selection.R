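## Final decoy-set assembly: deduplicate raw candidates, filter iteratively
## on heavy-atom-count difference and doppelganger score until a minimum pool
## survives, then pick the final decoys greedily by the sum of normalized
## property difference and LADS score.

#' Selection configuration
#'
#' @param candidates_per_active raw candidates generated per active (1000 in
#'   the benchmark protocol; smaller for desk-scale runs).
#' @param min_pool minimum candidate pool after filtering (default 100).
#' @param decoys_per_active final decoys per active (30 in the
#'   DEKOIS-style protocol, 50 in the original DUD-E convention).
#' @param property_set_name property set for the property difference.
#' @param max_heavy_diff initial maximum heavy-atom-count difference.
#' @param max_doppelganger initial maximum doppelganger score.
#' @param heavy_step,dopp_step relaxation increments (alternating).
#' @return list of class `selection_config`.
#' @export
selection_config <- function(candidates_per_active = 1000L, min_pool = 100L,
                             decoys_per_active = 30L,
                             property_set_name = "dekois8",
                             max_heavy_diff = 0L, max_doppelganger = 0.25,
                             heavy_step = 1L, dopp_step = 0.05) {
  stopifnot(min_pool >= decoys_per_active, max_doppelganger > 0)
  structure(list(candidates_per_active = as.integer(candidates_per_active),
                 min_pool = as.integer(min_pool),
                 decoys_per_active = as.integer(decoys_per_active),
                 property_set_name = property_set_name,
                 max_heavy_diff = as.integer(max_heavy_diff),
                 max_doppelganger = max_doppelganger,
                 heavy_step = as.integer(heavy_step), dopp_step = dopp_step),
            class = "selection_config")
}

#' Latent-actives-in-decoy-set (LADS) score
#'
#' Penalty for decoys whose substructural environments are prevalent among
#' the actives: the mean, over the decoy's functional-fingerprint bits, of
#' the fraction of actives containing that bit. 0 when the decoy shares no
#' environment with any active; maximal for a decoy identical to an active.
#'
#' @param decoy a `molecule` (or its precomputed `fingerprint`).
#' @param actives list of active `molecule`s (or their fingerprints).
#' @return score in \[0, 1\].
#' @export
lads_score <- function(decoy, actives) {
  stopifnot(length(actives) >= 1L)
  dfp <- if (inherits(decoy, "fingerprint")) decoy else
    functional_fingerprint(decoy)
  afps <- lapply(actives, function(a) {
    if (inherits(a, "fingerprint")) a else functional_fingerprint(a)
  })
  if (!length(dfp$bits)) return(0)
  # prevalence of each bit among the actives
  prev <- numeric(dfp$length)
  for (fp in afps) prev[fp$bits + 1L] <- prev[fp$bits + 1L] + 1 / length(afps)
  mean(prev[dfp$bits + 1L])
}

#' Iteratively filter candidate decoys
#'
#' Candidates (deduplicated by canonical form) are filtered by heavy-atom
#' count difference to their active and by doppelganger score (maximum
#' functional-fingerprint Tanimoto to any active). Starting at the strictest
#' thresholds, the allowed heavy-atom difference and doppelganger threshold
#' are relaxed alternately until at least `min_pool` candidates survive; the
#' full relaxation trace is returned so the schedule can be audited.
#'
#' @param candidates list of deduplicated, valence-valid `molecule`s.
#' @param active the active `molecule` they were generated for.
#' @param actives all actives of the target (doppelganger reference).
#' @param config a [selection_config()].
#' @return list with `kept` (indices into `candidates`), `doppelganger`
#'   (per-candidate scores), `trace` (data.frame: step, max_heavy_diff,
#'   max_doppelganger, surviving), `final_thresholds`.
#' @export
filter_candidates <- function(candidates, active, actives, config) {
  if (!length(candidates)) stop("no candidates to filter")
  hdiff <- abs(vapply(candidates, n_atoms, integer(1)) - n_atoms(active))
  afps <- lapply(actives, functional_fingerprint)
  dopp <- vapply(candidates, function(m) {
    fp <- functional_fingerprint(m)
    max(vapply(afps, function(a) tanimoto(fp, a), numeric(1)))
  }, numeric(1))

  hd <- config$max_heavy_diff
  dm <- config$max_doppelganger
  trace <- list()
  step <- 0L
  relax_heavy <- TRUE
  repeat {
    keep <- which(hdiff <= hd & dopp <= dm)
    step <- step + 1L
    trace[[step]] <- data.frame(step = step, max_heavy_diff = hd,
                                max_doppelganger = dm,
                                surviving = length(keep))
    if (length(keep) >= min(config$min_pool, length(candidates))) break
    if (hd >= max(hdiff) && dm >= 1) break # fully relaxed
    if (relax_heavy && hd < max(hdiff)) {
      hd <- hd + config$heavy_step
    } else {
      dm <- min(1, dm + config$dopp_step)
    }
    relax_heavy <- !relax_heavy
  }
  if (length(keep) < config$min_pool) {
    warning(sprintf(
      "only %d of %d candidates survive even fully relaxed thresholds",
      length(keep), length(candidates)), call. = FALSE)
  } else if (dm >= 1) {
    warning("doppelganger threshold fully relaxed to 1: surviving candidates",
            " are unconstrained in similarity to the actives", call. = FALSE)
  }
  list(kept = keep, doppelganger = dopp,
       trace = do.call(rbind, trace),
       final_thresholds = c(max_heavy_diff = hd, max_doppelganger = dm))
}

#' Greedy final selection
#'
#' Returns the `n` candidates with the smallest combined score (normalized
#' property difference + LADS score); ties are broken by canonical-form
#' lexicographic order, so the result is deterministic and invariant to the
#' input ordering.
#'
#' @param scored data.frame with columns `combined` and `canonical` (one row
#'   per candidate).
#' @param n number of decoys to select.
#' @return integer row indices of the selected candidates.
#' @export
greedy_select <- function(scored, n) {
  stopifnot(nrow(scored) >= 1L)
  if (nrow(scored) < n) {
    warning(sprintf("only %d candidates for %d requested decoys",
                    nrow(scored), n), call. = FALSE)
    n <- nrow(scored)
  }
  ord <- order(scored$combined, scored$canonical)
  ord[seq_len(n)]
}

#' Build the final decoy set for a list of actives
#'
#' Orchestrates generation, deduplication, iterative filtering, scoring and
#' greedy selection per active; per-active failures are recorded and the
#' pipeline continues. The normalization model for the property difference is
#' fitted on the target's actives together with the candidate decoys.
#'
#' @param actives list of active `molecule`s.
#' @param model a trained `decoy_generator`.
#' @param config a [selection_config()].
#' @param seed integer seed; identical seeds give identical decoy sets.
#' @param pset property set object (defaults to
#'   `property_set(config$property_set_name)`).
#' @return object of class `decoy_set`: list with `decoys` (per-active lists
#'   of molecules), `report` (per-active provenance: candidate counts,
#'   duplicates, relaxation trace, final thresholds, scores).
#' @export
build_decoy_set <- function(actives, model, config = selection_config(),
                            seed = 1L, pset = NULL) {
  pset <- pset %||% property_set(config$property_set_name)
  decoys <- vector("list", length(actives))
  report <- vector("list", length(actives))
  for (i in seq_along(actives)) {
    res <- tryCatch(
      select_for_active(actives[[i]], actives, model, config, pset,
                        derive_seed(seed, paste0("active", i))),
      error = function(e) e)
    if (inherits(res, "error")) {
      report[[i]] <- list(active = i, error = conditionMessage(res))
      decoys[[i]] <- list()
    } else {
      decoys[[i]] <- res$decoys
      report[[i]] <- res$report
    }
  }
  structure(list(decoys = decoys, report = report, config = config),
            class = "decoy_set")
}

select_for_active <- function(active, actives, model, config, pset, seed) {
  raw <- suppressWarnings(
    generate_decoys(model, active, config$candidates_per_active, seed = seed))
  n_failed <- attr(raw, "n_failed")
  smis <- attr(raw, "smiles")
  dup <- duplicated(smis)
  cand <- raw[!dup]
  smis <- smis[!dup]
  if (!length(cand)) stop("no unique candidates generated")

  filt <- filter_candidates(cand, active, actives, config)
  pool <- cand[filt$kept]
  pool_smis <- smis[filt$kept]
  if (!length(pool)) stop("no candidates survive filtering")

  norm <- suppressWarnings(
    fit_normalization(property_matrix(c(actives, pool), pset)))
  va <- compute_properties(active, pset)
  afps <- lapply(actives, functional_fingerprint)
  scored <- data.frame(
    canonical = pool_smis,
    prop_diff = vapply(pool, function(m) {
      property_distance(compute_properties(m, pset), va, norm)
    }, numeric(1)),
    lads = vapply(pool, function(m) lads_score(m, afps), numeric(1)),
    doppelganger = filt$doppelganger[filt$kept]
  )
  scored$combined <- scored$prop_diff + scored$lads
  sel <- suppressWarnings(greedy_select(scored, config$decoys_per_active))
  list(decoys = pool[sel],
       report = list(
         n_generated = length(raw) + n_failed, n_failed = n_failed,
         n_duplicates = sum(dup), n_unique = length(cand),
         n_filtered = length(pool), trace = filt$trace,
         final_thresholds = filt$final_thresholds,
         selected = scored[sel, , drop = FALSE]))
}

#' @export
print.decoy_set <- function(x, ...) {
  n <- vapply(x$decoys, length, integer(1))
  cat(sprintf("<decoy_set> %d actives, %d decoys total (%s per active)\n",
              length(x$decoys), sum(n), paste(unique(n), collapse = "/")))
  invisible(x)
}
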