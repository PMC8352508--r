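#' @keywords internal
"_PACKAGE"

# Deterministic scoped RNG: run `expr` under `seed`, restore caller RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stage label (stable fan-out).
derive_seed <- function(seed, label) {
  h <- hash_ints(c(as.integer(seed), utf8ToInt(as.character(label))))
  as.integer(h %% 2147483587)
}

# Stable integer mixing hash, versioned (v1). Kept in doubles; all intermediate
# values stay below 2^53 so arithmetic is exact.
hash_ints <- function(x) {
  h <- 5381
  for (v in as.numeric(x)) {
    h <- (h * 33 + (v %% 2147483647)) %% 2147483647
  }
  h
}

# Mann-Whitney AUC of `score` for binary `label` (TRUE = positive), tie-aware.
rank_auc <- function(score, label) {
  label <- as.logical(label)
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
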