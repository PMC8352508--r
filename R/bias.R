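## Bias assessment suite: DOE score (deviation from optimal embedding),
## doppelganger score, AVE (asymmetric validation embedding) and
## machine-learning separability over all property subsets. All metrics work
## in z-normalized property space fitted on the target's actives and decoys
## together, so each target is assessed in isolation.

# Exact absolute deviation of a piecewise-linear ROC curve from the diagonal.
# pos/neg: distances of positives/negatives from the query; ranking is by
# ascending distance; tied distances advance TPR and FPR jointly (a linear
# segment). The integral of |curve - diagonal| over FPR is computed exactly,
# splitting segments where the curve crosses the diagonal.
roc_deviation <- function(pos, neg) {
  # mathematically tied distances can differ by rounding after
  # normalization; merge them so ties interpolate as intended
  pos <- signif(pos, 9)
  neg <- signif(neg, 9)
  vals <- sort(unique(c(pos, neg)))
  np <- length(pos); nn <- length(neg)
  tp <- cumsum(vapply(vals, function(v) sum(pos == v), numeric(1))) / np
  fp <- cumsum(vapply(vals, function(v) sum(neg == v), numeric(1))) / nn
  xs <- c(0, fp); ys <- c(0, tp)
  dev <- 0
  for (i in seq_len(length(xs) - 1L)) {
    x0 <- xs[i]; x1 <- xs[i + 1L]
    if (x1 == x0) next # vertical segment: no FPR mass
    y0 <- ys[i]; y1 <- ys[i + 1L]
    m <- (y1 - y0) / (x1 - x0)
    # g(x) = curve - diagonal, linear on the segment
    g0 <- y0 - x0
    g1 <- y1 - x1
    if (g0 * g1 >= 0) {
      dev <- dev + abs(g0 + g1) / 2 * (x1 - x0)
    } else {
      xc <- x0 + g0 / (g0 - g1) * (x1 - x0) # crossing point
      dev <- dev + abs(g0) / 2 * (xc - x0) + abs(g1) / 2 * (x1 - xc)
    }
  }
  dev
}

#' DOE score: deviation from optimal embedding
#'
#' For each active, all other actives (positives) and all decoys (negatives)
#' are ranked by ascending Euclidean distance in z-normalized property space;
#' tied distances are interpolated linearly. The per-active score is the
#' integrated absolute deviation of that ROC curve from the diagonal, and the
#' DOE score is the mean over actives. 0 for an optimal embedding (actives
#' and decoys property-identical); 0.5 for complete separation.
#'
#' @param actives numeric matrix of active property vectors (rows).
#' @param decoys numeric matrix of decoy property vectors.
#' @return numeric DOE in \[0, 0.5\] with attribute `per_active`.
#' @export
doe_score <- function(actives, decoys) {
  actives <- as.matrix(actives); decoys <- as.matrix(decoys)
  if (nrow(actives) < 2L)
    stop("DOE score needs at least 2 actives (one is the query, the rest positives)")
  if (nrow(decoys) < 1L) stop("DOE score needs at least 1 decoy")
  all_m <- rbind(actives, decoys)
  norm <- suppressWarnings(fit_normalization(all_m))
  z <- normalize_properties(all_m, norm)
  na <- nrow(actives)
  d <- as.matrix(stats::dist(z))
  per_active <- vapply(seq_len(na), function(i) {
    pos <- d[i, setdiff(seq_len(na), i)]
    neg <- d[i, (na + 1L):nrow(z)]
    roc_deviation(pos, neg)
  }, numeric(1))
  structure(mean(per_active), per_active = per_active)
}

#' Doppelganger scores
#'
#' Per-decoy maximum functional-fingerprint Tanimoto similarity to any
#' active, with the summary mean and maximum over decoys.
#'
#' @param decoys,actives lists of `molecule`s (or precomputed functional
#'   `fingerprint`s).
#' @return list with `scores` (per decoy), `mean`, `max`.
#' @export
doppelganger_scores <- function(decoys, actives) {
  stopifnot(length(decoys) >= 1L, length(actives) >= 1L)
  as_fp <- function(x) if (inherits(x, "fingerprint")) x else
    functional_fingerprint(x)
  afps <- lapply(actives, as_fp)
  scores <- vapply(decoys, function(m) {
    fp <- as_fp(m)
    max(vapply(afps, function(a) tanimoto(fp, a), numeric(1)))
  }, numeric(1))
  list(scores = scores, mean = mean(scores), max = max(scores))
}

# Threshold-averaged nearest-neighbor hit function: for each validation
# point, the fraction of grid thresholds exceeded by its nearest-neighbor
# distance to the training set, averaged over validation points.
ave_hit <- function(valid, train, grid) {
  if (!nrow(valid) || !nrow(train)) return(NA_real_)
  nn <- vapply(seq_len(nrow(valid)), function(i) {
    min(sqrt(colSums((t(train) - valid[i, ])^2)))
  }, numeric(1))
  mean(vapply(nn, function(d) mean(d < grid), numeric(1)))
}

#' AVE: asymmetric validation embedding bias
#'
#' \deqn{AVE = [H(VA,TA) - H(VA,TD)] + [H(VD,TD) - H(VD,TA)]}
#' where H is the threshold-averaged nearest-neighbor hit function between a
#' validation class and a training class, computed on z-normalized property
#' vectors over a uniform threshold grid, averaged over cross-validation
#' folds. Near 0 when actives and decoys are drawn from one distribution;
#' near its maximum for fully separated clusters.
#'
#' @param actives,decoys numeric property matrices.
#' @param n_folds number of cross-validation folds (default 3).
#' @param grid_size number of distance thresholds (default 50), uniform on
#'   \[0, max pairwise distance\].
#' @param seed integer seed for the fold assignment.
#' @param folds optional explicit fold assignment: list with integer vectors
#'   `actives` and `decoys` (overrides the seeded assignment).
#' @return AVE value in \[-2, 2\] with attribute `per_fold`.
#' @export
ave_bias <- function(actives, decoys, n_folds = 3L, grid_size = 50L,
                     seed = 1L, folds = NULL) {
  actives <- as.matrix(actives); decoys <- as.matrix(decoys)
  all_m <- rbind(actives, decoys)
  norm <- suppressWarnings(fit_normalization(all_m))
  za <- normalize_properties(actives, norm)
  zd <- normalize_properties(decoys, norm)
  dmax <- max(stats::dist(rbind(za, zd)))
  grid <- seq(0, dmax, length.out = grid_size)
  if (!is.null(folds)) {
    fa <- folds$actives; fd <- folds$decoys
    n_folds <- max(c(fa, fd))
  } else {
    fa <- with_seed(seed, sample(rep(seq_len(n_folds), length.out = nrow(za))))
    fd <- with_seed(derive_seed(seed, "decoy-folds"),
                    sample(rep(seq_len(n_folds), length.out = nrow(zd))))
  }
  per_fold <- vapply(seq_len(n_folds), function(k) {
    va <- za[fa == k, , drop = FALSE]; ta <- za[fa != k, , drop = FALSE]
    vd <- zd[fd == k, , drop = FALSE]; td <- zd[fd != k, , drop = FALSE]
    if (!nrow(va) || !nrow(vd) || !nrow(ta) || !nrow(td)) {
      warning("fold with an empty class skipped", call. = FALSE)
      return(NA_real_)
    }
    (ave_hit(va, ta, grid) - ave_hit(va, td, grid)) +
      (ave_hit(vd, td, grid) - ave_hit(vd, ta, grid))
  }, numeric(1))
  structure(mean(per_fold, na.rm = TRUE), per_fold = per_fold)
}

#' Machine-learning property-bias assessment
#'
#' Trains a classifier to separate actives from decoys using every non-empty
#' subset of the properties (2^k - 1 subsets) under stratified
#' cross-validation, reporting the ROC AUC per subset. High AUC on properties
#' deemed non-informative for binding indicates residual property bias. The
#' 1NN model scores each test point by the continuous difference between its
#' nearest-decoy and nearest-active training distances; the RF model uses
#' 100 trees (fixed) and class-probability scores.
#'
#' @param actives,decoys numeric property matrices with column names.
#' @param model `"1NN"` or `"RF"`.
#' @param n_folds folds for stratified CV (default 10; reduced with a warning
#'   when a class is smaller than the fold count).
#' @param seed integer seed.
#' @return data.frame with columns `model`, `subset`, `k`, `auc`.
#' @export
ml_bias_assessment <- function(actives, decoys, model = c("1NN", "RF"),
                               n_folds = 10L, seed = 1L) {
  model <- match.arg(model)
  actives <- as.matrix(actives); decoys <- as.matrix(decoys)
  k <- ncol(actives)
  if (k > 12L) stop("subset enumeration limited to 12 properties")
  if (is.null(colnames(actives)))
    colnames(actives) <- colnames(decoys) <- paste0("p", seq_len(k))
  nmin <- min(nrow(actives), nrow(decoys))
  if (nmin < n_folds) {
    warning(sprintf("fold count reduced from %d to %d (smallest class)",
                    n_folds, nmin), call. = FALSE)
    n_folds <- nmin
  }
  x <- rbind(actives, decoys)
  y <- c(rep(TRUE, nrow(actives)), rep(FALSE, nrow(decoys)))
  norm <- suppressWarnings(fit_normalization(x))
  z <- normalize_properties(x, norm)
  folds <- integer(length(y))
  with_seed(seed, {
    folds[y] <- sample(rep(seq_len(n_folds), length.out = sum(y)))
    folds[!y] <- sample(rep(seq_len(n_folds), length.out = sum(!y)))
  })

  subsets <- property_subsets(colnames(actives))
  rows <- lapply(subsets, function(cols) {
    aucs <- vapply(seq_len(n_folds), function(fd) {
      tr <- folds != fd; te <- !tr
      ztr <- z[tr, cols, drop = FALSE]; zte <- z[te, cols, drop = FALSE]
      score <- if (model == "1NN") {
        one_nn_scores(ztr, y[tr], zte)
      } else {
        rf_scores(ztr, y[tr], zte, seed = derive_seed(seed, paste(
          "rf", fd, paste(cols, collapse = "."))))
      }
      rank_auc(score, y[te])
    }, numeric(1))
    data.frame(model = model, subset = paste(cols, collapse = "+"),
               k = length(cols), auc = mean(aucs, na.rm = TRUE))
  })
  do.call(rbind, rows)
}

property_subsets <- function(nms) {
  k <- length(nms)
  out <- list()
  for (size in seq_len(k)) {
    cmb <- utils::combn(nms, size, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

one_nn_scores <- function(ztr, ytr, zte) {
  vapply(seq_len(nrow(zte)), function(i) {
    d <- sqrt(colSums((t(ztr) - zte[i, ])^2))
    da <- if (any(ytr)) min(d[ytr]) else Inf
    dd <- if (any(!ytr)) min(d[!ytr]) else Inf
    dd - da # larger = more active-like
  }, numeric(1))
}

rf_scores <- function(ztr, ytr, zte, seed) {
  # zero-variance predictors carry no signal and can stall the forest fit
  keep <- apply(ztr, 2L, function(v) diff(range(v)) > 1e-12)
  if (!any(keep)) return(rep(0.5, nrow(zte)))
  ztr <- ztr[, keep, drop = FALSE]
  zte <- zte[, keep, drop = FALSE]
  with_seed(seed, {
    fit <- randomForest::randomForest(
      x = as.data.frame(ztr), y = factor(ytr, levels = c(FALSE, TRUE)),
      ntree = 100L)
    stats::predict(fit, as.data.frame(zte), type = "prob")[, "TRUE"]
  })
}

#' Compile a per-target bias report
#'
#' Runs the full assessment suite and returns a versioned report; individual
#' metric failures are recorded as `NULL` with a reason and the report is
#' still emitted. With `path` the report is written as JSON (byte-identical
#' under identical inputs and seed).
#'
#' @param target_name label for the target.
#' @param actives,decoys lists of `molecule`s.
#' @param pset a [property_set()].
#' @param n_folds folds for the ML assessment and AVE.
#' @param seed integer seed.
#' @param path optional JSON output path.
#' @return list of class `bias_report`.
#' @export
compile_report <- function(target_name, actives, decoys, pset,
                           n_folds = 10L, seed = 1L, path = NULL) {
  pa <- property_matrix(actives, pset)
  pd <- property_matrix(decoys, pset)
  try_metric <- function(expr) {
    tryCatch(expr, error = function(e) {
      warning(conditionMessage(e), call. = FALSE)
      list(value = NULL, reason = conditionMessage(e))
    })
  }
  doe <- try_metric(as.numeric(doe_score(pa, pd)))
  dopp <- try_metric(doppelganger_scores(decoys, actives)[c("mean", "max")])
  ave <- try_metric(as.numeric(
    ave_bias(pa, pd, n_folds = min(n_folds, 3L), seed = seed)))
  auc_tab <- try_metric(rbind(
    ml_bias_assessment(pa, pd, "1NN", n_folds = n_folds, seed = seed),
    ml_bias_assessment(pa, pd, "RF", n_folds = n_folds, seed = seed)))
  report <- list(
    schema_version = 1L,
    target = target_name,
    n_actives = length(actives), n_decoys = length(decoys),
    doe_score = doe,
    doppelganger = dopp,
    ave = ave,
    subset_auc = auc_tab,
    metadata = list(property_set = pset$name,
                    n_properties = length(pset$properties),
                    normalization = "z-score on actives + decoys",
                    fingerprint = "functional_fcfp6like",
                    logp_method = LOGP_METHOD,
                    seed = seed)
  )
  class(report) <- "bias_report"
  if (!is.null(path)) {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = 10, dataframe = "rows")
  }
  report
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf("<bias_report> target %s (%d actives, %d decoys)\n",
              x$target, x$n_actives, x$n_decoys))
  fmt <- function(v) if (is.numeric(v)) sprintf("%.4f", v) else "failed"
  cat("  DOE score:        ", fmt(x$doe_score), "\n")
  if (is.list(x$doppelganger) && !is.null(x$doppelganger$mean)) {
    cat(sprintf("  doppelganger:      mean %.4f, max %.4f\n",
                x$doppelganger$mean, x$doppelganger$max))
  }
  cat("  AVE:              ", fmt(x$ave), "\n")
  if (is.data.frame(x$subset_auc)) {
    full <- x$subset_auc[x$subset_auc$k == max(x$subset_auc$k), ]
    for (i in seq_len(nrow(full))) {
      cat(sprintf("  %s AUC (all props): %.4f\n", full$model[i], full$auc[i]))
    }
  }
  invisible(x)
}
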