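## Training (Adam on exact gradients of the linear readouts / action head)
## and bond-by-bond decoding. The fitted model is the classic S3 object with
## print / summary / coef / plot / simulate / predict methods.

#' Train the decoy generator
#'
#' Fits the graph-to-graph variational model on molecule pairs: each pair
#' (A -> B) is trained to reconstruct B's bond-by-bond assembly sequence from
#' the encoding of A combined with a latent sample from the posterior of B.
#' The action term of the reconstruction loss is the
#' subgraph-frequency-reweighted cross-entropy (see
#' [reweighted_action_loss()]); the atom-type term scores the multiset of
#' target atom types; the KL term regularizes the posterior toward the prior
#' with weight `lambda_kl` (linear warm-up over the first half of training).
#'
#' @param pairs a `molecule_pairs` data.frame (see [build_pairs()]).
#' @param library the molecule list the pair indices refer to.
#' @param validation optional validation pairs (same library).
#' @param config a [generator_config()].
#' @return object of class `decoy_generator` with the trained parameters,
#'   vocabulary, subgraph frequency table, config snapshot and per-epoch loss
#'   history (`history`: data.frame with train/validation `LossBreakdown`
#'   columns).
#' @export
train_generator <- function(pairs, library, validation = NULL,
                            config = generator_config()) {
  if (!nrow(pairs)) stop("no training pairs")
  model <- structure(list(
    config = config, vocab = config$vocab,
    fixed = init_fixed_weights(config),
    params = init_params(config),
    freq_table = NULL, history = NULL, version = 1L
  ), class = "decoy_generator")

  train_mols <- unique(c(pairs$a, pairs$b))
  model$freq_table <- assembly_frequency_table(library[train_mols],
                                               config$vocab)

  prep <- function(df) {
    lapply(seq_len(nrow(df)), function(k) {
      a <- df$a[k]; b <- df$b[k]
      seqs <- target_action_sequence(library[[b]], config$vocab,
                                     model$freq_table)
      list(g_a = graph_embedding(model, library[[a]]),
           g_b = graph_embedding(model, library[[b]]),
           steps = seqs$steps, types = seqs$types)
    })
  }
  train_ex <- prep(pairs)
  valid_ex <- if (!is.null(validation) && nrow(validation)) prep(validation)

  d <- config$latent_dim
  nt <- n_types(config$vocab)
  adam <- adam_state(model$params)
  history <- list()
  last_good <- model$params

  for (epoch in seq_len(config$epochs)) {
    lambda <- config$lambda_kl *
      min(1, epoch / max(1, floor(config$epochs / 2)))
    eps_mat <- with_seed(derive_seed(config$seed, paste0("epoch", epoch)),
                         matrix(stats::rnorm(length(train_ex) * d),
                                length(train_ex), d))
    grads <- zero_like(model$params)
    tot <- c(action = 0, type = 0, kl = 0)
    for (k in seq_along(train_ex)) {
      r <- pair_pass(model$params, train_ex[[k]], eps_mat[k, ], lambda, nt, d,
                     with_grad = TRUE)
      tot <- tot + c(r$L_action, r$L_type, r$L_kl)
      grads <- add_grads(grads, r$grads)
    }
    np <- length(train_ex)
    grads <- lapply(grads, function(g) g / np)
    upd <- adam_step(adam, model$params, grads, config$lr)
    adam <- upd$state
    new_params <- upd$params
    L_recon <- (tot[["action"]] + tot[["type"]]) / np
    L_kl <- tot[["kl"]] / np
    L_total <- L_recon + lambda * L_kl
    if (!is.finite(L_total)) {
      warning("training diverged (non-finite loss); keeping last checkpoint",
              call. = FALSE)
      model$params <- last_good
      break
    }
    model$params <- new_params
    last_good <- new_params
    vrow <- c(NA_real_, NA_real_)
    if (!is.null(valid_ex)) {
      vt <- c(action = 0, type = 0, kl = 0)
      for (ex in valid_ex) {
        r <- pair_pass(model$params, ex, rep(0, d), lambda, nt, d,
                       with_grad = FALSE)
        vt <- vt + c(r$L_action, r$L_type, r$L_kl)
      }
      vt <- vt / length(valid_ex)
      vrow <- c(vt[["action"]] + vt[["type"]],
                vt[["action"]] + vt[["type"]] + lambda * vt[["kl"]])
    }
    history[[epoch]] <- data.frame(
      epoch = epoch, lambda_kl = lambda, L_total = L_total,
      L_recon = L_recon, L_action = tot[["action"]] / np,
      L_type = tot[["type"]] / np, L_kl = L_kl,
      val_L_recon = vrow[1L], val_L_total = vrow[2L])
  }
  model$history <- do.call(rbind, history)
  model
}

# One pair: forward (and optionally backward) pass. Returns loss components
# and parameter gradients.
pair_pass <- function(params, ex, eps, lambda, nt, d, with_grad = TRUE) {
  g_a <- ex$g_a; g_b <- ex$g_b
  mu <- drop(params$W_mu %*% g_b) + params$b_mu
  ls <- drop(params$W_ls %*% g_b) + params$b_ls
  sigma <- exp(0.5 * ls)
  z <- mu + sigma * eps
  cc <- c(g_a, z)
  L_kl <- 0.5 * sum(mu^2 + sigma^2 - 1 - ls)

  # atom-type term: multiset of target types scored from the conditioning
  t_logits <- drop(params$U_type %*% cc) + params$b_type
  t_lse <- log_sum_exp(t_logits)
  counts <- tabulate(ex$types, nbins = nt)
  n_b <- sum(counts)
  L_type <- -(sum(t_logits * counts) - n_b * t_lse)

  L_action <- 0
  gc_vec <- numeric(length(cc))
  grads <- if (with_grad) zero_like(params)
  for (stp in ex$steps) {
    s <- drop(stp$Phi %*% (params$w_act + params$W_act %*% cc))
    u <- s + log(stp$f)
    lse <- log_sum_exp(u)
    fbar <- mean(stp$f)
    L_action <- L_action + (-fbar * (u[stp$j] - lse))
    if (with_grad) {
      q <- exp(u - lse)
      gs <- fbar * q
      gs[stp$j] <- gs[stp$j] - fbar
      pg <- drop(crossprod(stp$Phi, gs)) # p-vector
      grads$w_act <- grads$w_act + pg
      grads$W_act <- grads$W_act + tcrossprod(pg, cc)
      gc_vec <- gc_vec + drop(crossprod(params$W_act, pg))
    }
  }
  if (with_grad) {
    pt <- exp(t_logits - t_lse)
    gtl <- n_b * pt - counts
    grads$U_type <- grads$U_type + tcrossprod(gtl, cc)
    grads$b_type <- grads$b_type + gtl
    gc_vec <- gc_vec + drop(crossprod(params$U_type, gtl))
    h <- length(g_a)
    gz <- gc_vec[(h + 1L):(h + d)]
    dmu <- gz + lambda * mu
    dls <- gz * eps * 0.5 * sigma + lambda * 0.5 * (sigma^2 - 1)
    grads$W_mu <- grads$W_mu + tcrossprod(dmu, g_b)
    grads$b_mu <- grads$b_mu + dmu
    grads$W_ls <- grads$W_ls + tcrossprod(dls, g_b)
    grads$b_ls <- grads$b_ls + dls
  }
  list(L_action = L_action, L_type = L_type, L_kl = L_kl, grads = grads)
}

zero_like <- function(params) lapply(params, function(p) p * 0)
add_grads <- function(a, b) Map(`+`, a, b)

adam_state <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(state, params, grads, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * grads[[nm]]
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

## ---- decoding ---------------------------------------------------------

#' Decode a molecule from a latent sample and an atom budget
#'
#' Builds a molecule bond-by-bond, breadth-first, from a pool of atoms given
#' by `budget` (an [element_counts()] vector), under hard valence masking:
#' the output is always connected, valence-valid, uses only pool atoms and
#' has at most the budgeted heavy-atom count. Deterministic under `seed`.
#'
#' @param model a `decoy_generator`.
#' @param cond conditioning vector (graph embedding of the active followed by
#'   a latent sample), as built internally by [generate_decoys()].
#' @param budget named element-count vector (`total`, `C`, `N`, ...).
#' @param seed integer seed.
#' @param greedy take argmax actions instead of sampling (used in tests).
#' @param seed_graph optional `molecule` used as the initial partial graph
#'   (its atoms are drawn from the budget; generation continues from it).
#' @return a `molecule`.
#' @export
decode <- function(model, cond, budget, seed = 1L, greedy = FALSE,
                   seed_graph = NULL) {
  vocab <- model$config$vocab
  elements <- setdiff(names(budget), "total")
  elements <- elements[budget[elements] > 0]
  pool <- unlist(lapply(elements, function(e) {
    rep(type_index(vocab, e), budget[[e]])
  }))
  if (!length(pool)) stop("empty atom budget")
  if (length(pool) > model$config$max_atoms)
    stop("budget exceeds configured maximum heavy-atom count")
  with_seed(seed, {
    st <- new_state(pool, vocab)
    if (is.null(seed_graph)) {
      t_logits <- drop(model$params$U_type %*% cond) + model$params$b_type
      first_scores <- t_logits[pool]
      first <- if (greedy) which.max(first_scores) else
        sample.int(length(pool), 1L, prob = softmax(first_scores))
      st <- state_place_atom(st, pool[first])
    } else {
      st <- seed_state_from_molecule(st, kekulize(seed_graph))
    }
    while (length(st$queue)) {
      enum <- enumerate_actions(st, model$freq_table)
      s <- drop(enum$Phi %*%
                  (model$params$w_act + model$params$W_act %*% cond))
      j <- if (greedy) which.max(s) else
        sample.int(length(s), 1L, prob = softmax(s))
      st <- apply_action(st, enum, j)
    }
    state_to_molecule(st)
  })
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Pre-place a partial substructure into a fresh decoder state, consuming the
# matching pool atoms; generation then continues from its atoms.
seed_state_from_molecule <- function(st, frag) {
  types <- type_index(st$vocab, frag$element, frag$charge)
  for (tt in types) {
    if (!tt %in% st$pool)
      stop("seed substructure exceeds the atom budget")
    st <- state_place_atom(st, tt)
  }
  for (k in seq_len(n_bonds(frag))) {
    st <- state_add_bond(st, frag$bond_a[k], frag$bond_b[k],
                         min(frag$bond_order[k], 3L))
  }
  if (any(st$rv < 0)) stop("seed substructure violates valence")
  st
}

#' Generate candidate decoys for an active molecule
#'
#' Encodes the active, then decodes `n` candidates, each conditioned on the
#' active's graph embedding combined with fresh standard-normal latent noise.
#' The atom pool defaults to the active's exact element counts, so generated
#' candidates match its composition by construction (an optional `budget`
#' overrides this). Duplicates are permitted at this stage and flagged.
#'
#' @param model a trained `decoy_generator`.
#' @param active a `molecule`.
#' @param n number of candidates.
#' @param seed integer seed; the full output list is reproducible.
#' @param budget optional element-count override.
#' @return list of molecules with attributes `n_failed` (decode failures) and
#'   `duplicated` (logical vector by canonical form).
#' @export
generate_decoys <- function(model, active, n, seed = 1L, budget = NULL) {
  if (n == 0L) return(structure(list(), n_failed = 0L, duplicated = logical()))
  g_a <- graph_embedding(model, active)
  budget <- budget %||% element_counts(active)
  d <- model$config$latent_dim
  zs <- with_seed(derive_seed(seed, "latent"),
                  matrix(stats::rnorm(n * d), n, d))
  out <- vector("list", n)
  failed <- 0L
  for (i in seq_len(n)) {
    mol <- tryCatch(
      decode(model, c(g_a, zs[i, ]), budget,
             seed = derive_seed(seed, paste0("decode", i))),
      error = function(e) NULL)
    if (is.null(mol)) failed <- failed + 1L else out[[i]] <- mol
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (failed > 0L)
    warning(sprintf("%d of %d decodes failed", failed, n), call. = FALSE)
  smis <- vapply(out, canonical_smiles, character(1))
  structure(out, n_failed = failed, smiles = smis,
            duplicated = duplicated(smis))
}

## ---- S3 methods -------------------------------------------------------

#' @export
print.decoy_generator <- function(x, ...) {
  cat("<decoy_generator>\n")
  cat(sprintf("  latent dim %d, hidden dim %d, %d message-passing steps\n",
              x$config$latent_dim, x$config$hidden_dim, x$config$mp_steps))
  cat(sprintf("  vocabulary: %d atom types; frequency table: %d keys\n",
              n_types(x$vocab), x$freq_table$n_keys))
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs; final L_total %.4f (recon %.4f, KL %.4f)\n",
                nrow(x$history), last$L_total, last$L_recon, last$L_kl))
  } else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.decoy_generator <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    cat("\nLoss history (first/last epochs):\n")
    h <- object$history
    print(h[unique(c(1L, nrow(h))), c("epoch", "L_total", "L_recon", "L_kl")],
          row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.decoy_generator <- function(object, ...) object$params

#' @export
plot.decoy_generator <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$L_recon, h$L_kl), type = "l", lty = 1,
                    xlab = "epoch", ylab = "loss",
                    main = "training loss", ...)
  graphics::legend("topright", legend = c("L_recon", "L_KL"), col = 1:2,
                   lty = 1, bty = "n")
  invisible(x)
}

#' Simulate decoys from a fitted generator
#'
#' @param object a `decoy_generator`.
#' @param nsim number of molecules to generate.
#' @param seed integer seed.
#' @param active the active `molecule` to condition on.
#' @param ... passed to [generate_decoys()].
#' @return list of molecules (see [generate_decoys()]).
#' @export
simulate.decoy_generator <- function(object, nsim = 1, seed = 1L,
                                     active, ...) {
  generate_decoys(object, active, n = nsim, seed = seed, ...)
}

#' Predict method: latent encoding of molecules
#'
#' @param object a `decoy_generator`.
#' @param newdata a `molecule` or list of molecules.
#' @param ... unused.
#' @return for a single molecule the [encode()] list; otherwise a matrix of
#'   latent means.
#' @export
predict.decoy_generator <- function(object, newdata, ...) {
  if (inherits(newdata, "molecule")) return(encode(object, newdata))
  t(vapply(newdata, function(m) encode(object, m)$mean,
           numeric(object$config$latent_dim)))
}

#' Save / load a generator checkpoint
#'
#' Single-archive checkpoint (parameters, vocabulary, frequency table,
#' config, format version); loading restores bit-identical generation under
#' a fixed seed.
#'
#' @param model a `decoy_generator`.
#' @param path checkpoint path.
#' @return `save_model`: the path, invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "decoy_generator")) stop("not a decoy_generator checkpoint")
  model
}
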