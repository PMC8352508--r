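## Graph-to-graph generative model for property-matched decoys.
##
## An active molecule is encoded with fixed random-projection message passing
## (gated-graph style updates with frozen weights acting as random graph
## features); trainable linear readouts give the latent Gaussian, and a
## trainable linear action head scores bond-by-bond construction steps of the
## decoder. Molecules are built breadth-first from a pool of atoms under hard
## valence masking, so every generated molecule is chemically valid by
## construction. Training follows the variational objective
## L_total = L_recon + lambda_KL * L_KL, where the action part of L_recon is
## the subgraph-frequency-reweighted cross-entropy
## L = -f_bar * log( p(x_j) f(x_j) / sum_i p(x_i) f(x_i) ),
## with f the reciprocal training-set frequency of the local subgraph each
## permitted action would create and f_bar the mean of f over permitted
## actions. With all f equal this reduces exactly to the standard
## cross-entropy.

#' Generator configuration
#'
#' Desk-scale defaults: the architecture is deliberately small so that
#' training and generation run comfortably on one CPU.
#'
#' @param latent_dim latent dimension (default 8).
#' @param hidden_dim node-embedding dimension (default 16).
#' @param mp_steps message-passing steps (default 2).
#' @param lambda_kl weight of the KL term (default 1) with linear warm-up
#'   over the first half of training.
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param max_atoms maximum heavy atoms a decode may place.
#' @param vocab atom vocabulary (see [default_vocabulary()]).
#' @param seed integer seed controlling the frozen projections and training
#'   randomness.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(latent_dim = 8L, hidden_dim = 16L, mp_steps = 2L,
                             lambda_kl = 1, lr = 0.05, epochs = 30L,
                             max_atoms = 40L, vocab = default_vocabulary(),
                             seed = 1L) {
  structure(list(latent_dim = as.integer(latent_dim),
                 hidden_dim = as.integer(hidden_dim),
                 mp_steps = as.integer(mp_steps), lambda_kl = lambda_kl,
                 lr = lr, epochs = as.integer(epochs),
                 max_atoms = as.integer(max_atoms), vocab = vocab,
                 seed = as.integer(seed)),
            class = "generator_config")
}

type_index <- function(vocab, element, charge = 0L) {
  j <- match(paste(element, charge), paste(vocab$element, vocab$charge))
  if (anyNA(j)) {
    bad <- element[is.na(j)][1L]
    stop(sprintf("atom type not in vocabulary: %s", bad))
  }
  j
}

n_types <- function(vocab) nrow(vocab)

# Frozen random projections, reproducible from the config seed.
init_fixed_weights <- function(config) {
  nt <- n_types(config$vocab)
  h <- config$hidden_dim
  nfeat <- nt + 2L
  with_seed(derive_seed(config$seed, "fixed"), {
    rand <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, 1 / sqrt(nc)), nr, nc)
    list(W_emb = rand(h, nfeat), W_self = rand(h, h),
         W_ord = list(rand(h, h), rand(h, h), rand(h, h)))
  })
}

init_params <- function(config) {
  nt <- n_types(config$vocab)
  h <- config$hidden_dim; d <- config$latent_dim
  p <- action_feature_dim(nt)
  list(W_mu = matrix(0, d, h), b_mu = numeric(d),
       W_ls = matrix(0, d, h), b_ls = numeric(d),
       w_act = numeric(p), W_act = matrix(0, p, h + d),
       U_type = matrix(0, nt, h + d), b_type = numeric(nt))
}

# Node embeddings and mean-pooled graph embedding via fixed message passing.
graph_embedding <- function(model, mol) {
  mol <- kekulize(mol)
  vocab <- model$config$vocab
  types <- type_index(vocab, mol$element, mol$charge)
  nt <- n_types(vocab)
  n <- n_atoms(mol)
  X <- matrix(0, nt + 2L, n)
  X[cbind(types, seq_len(n))] <- 1
  X[nt + 1L, ] <- atom_degree(mol) / 4
  X[nt + 2L, ] <- bond_order_sum(mol) / 4
  H <- tanh(model$fixed$W_emb %*% X)
  for (step in seq_len(model$config$mp_steps)) {
    M <- matrix(0, nrow(H), n)
    for (k in seq_len(n_bonds(mol))) {
      a <- mol$bond_a[k]; b <- mol$bond_b[k]
      o <- min(mol$bond_order[k], 3L)
      M[, a] <- M[, a] + model$fixed$W_ord[[o]] %*% H[, b]
      M[, b] <- M[, b] + model$fixed$W_ord[[o]] %*% H[, a]
    }
    H <- tanh(model$fixed$W_self %*% H + M)
  }
  rowMeans(H)
}

#' Encode a molecule to its latent distribution
#'
#' @param model a `decoy_generator`.
#' @param mol a `molecule` whose atoms are all in the model vocabulary.
#' @return list with `mean` and `scale` (length `latent_dim`); `scale` is 1
#'   everywhere for a freshly initialized (zero readout) model.
#' @export
encode <- function(model, mol) {
  g <- graph_embedding(model, mol)
  mu <- drop(model$params$W_mu %*% g) + model$params$b_mu
  ls <- drop(model$params$W_ls %*% g) + model$params$b_ls
  list(mean = mu, scale = exp(0.5 * ls))
}

## ---- action space -----------------------------------------------------

action_feature_dim <- function(nt) 2L * nt + 11L

# Decoder state over a partially built molecule.
new_state <- function(pool_types, vocab) {
  list(types = integer(), rv = numeric(), inc_orders = list(),
       bond_a = integer(), bond_b = integer(), bond_order = integer(),
       queue = integer(), pool = pool_types,
       total = length(pool_types), vocab = vocab)
}

state_place_atom <- function(st, ttype, from = NA_integer_, ord = NA_integer_) {
  st$types <- c(st$types, ttype)
  st$rv <- c(st$rv, st$vocab$max_valence[ttype])
  st$inc_orders <- c(st$inc_orders, list(integer()))
  idx <- length(st$types)
  st$queue <- c(st$queue, idx)
  st$pool <- st$pool[-match(ttype, st$pool)]
  if (!is.na(from)) st <- state_add_bond(st, from, idx, ord)
  st
}

state_add_bond <- function(st, a, b, ord) {
  st$bond_a <- c(st$bond_a, a); st$bond_b <- c(st$bond_b, b)
  st$bond_order <- c(st$bond_order, ord)
  st$rv[a] <- st$rv[a] - ord; st$rv[b] <- st$rv[b] - ord
  st$inc_orders[[a]] <- c(st$inc_orders[[a]], ord)
  st$inc_orders[[b]] <- c(st$inc_orders[[b]], ord)
  st
}

state_distances <- function(st, from) {
  n <- length(st$types)
  d <- rep(NA_integer_, n); d[from] <- 0L
  queue <- from
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    nb <- c(st$bond_b[st$bond_a == i], st$bond_a[st$bond_b == i])
    nb <- nb[is.na(d[nb])]
    d[nb] <- d[i] + 1L
    queue <- c(queue, nb)
  }
  d
}

state_env_key <- function(st, focus, ord, ttype = NULL, target = NULL) {
  vocab <- st$vocab
  desc <- function(el, chg, orders) {
    sprintf("%s%+d(%s)", el, chg, paste(sort(orders), collapse = ""))
  }
  df <- desc(vocab$element[st$types[focus]], vocab$charge[st$types[focus]],
             c(st$inc_orders[[focus]], ord))
  dt <- if (!is.null(ttype)) {
    desc(vocab$element[ttype], vocab$charge[ttype], ord)
  } else {
    desc(vocab$element[st$types[target]], vocab$charge[st$types[target]],
         c(st$inc_orders[[target]], ord))
  }
  pair <- sort(c(df, dt))
  sprintf("%d|%s|%s", ord, pair[1L], pair[2L])
}

# Enumerate permitted actions at the current focus: stop (kind 1), attach a
# pool atom by type (kind 2), or close a ring to an unbonded placed atom
# (kind 3). Vectorized: returns parallel action vectors, the feature matrix
# and reciprocal frequencies. Stop induces no subgraph, so it takes the
# geometric-mean f of the competing bond actions (scale-neutral: the
# reweighting then only shifts probability among bond actions).
enumerate_actions <- function(st, freq_table) {
  focus <- st$queue[1L]
  vocab <- st$vocab
  nt <- nrow(vocab)
  n_placed <- length(st$types)
  placed_frac <- n_placed / st$total
  pool_frac <- length(st$pool) / st$total
  rvf <- st$rv[focus]
  el_f <- vocab$element[st$types[focus]]
  chg_f <- vocab$charge[st$types[focus]]
  inc_f <- st$inc_orders[[focus]]

  kind <- 1L; ordv <- 0L; ttv <- 0L; tgt <- 0L
  keys <- "<stop>"; rvt <- 0; dfeat <- 0

  pool_types <- unique(st$pool)
  max_ord <- min(3L, floor(rvf))
  for (o in seq_len(max_ord)) {
    df <- sprintf("%s%+d(%s)", el_f, chg_f,
                  paste(sort(c(inc_f, o)), collapse = ""))
    tt <- pool_types[vocab$max_valence[pool_types] >= o]
    if (length(tt)) {
      dt <- sprintf("%s%+d(%d)", vocab$element[tt], vocab$charge[tt], o)
      kind <- c(kind, rep(2L, length(tt)))
      ordv <- c(ordv, rep(o, length(tt)))
      ttv <- c(ttv, tt); tgt <- c(tgt, rep(0L, length(tt)))
      rvt <- c(rvt, vocab$max_valence[tt] / 4)
      dfeat <- c(dfeat, rep(0, length(tt)))
      keys <- c(keys, sprintf("%d|%s|%s", o, pmin(df, dt), pmax(df, dt)))
    }
    if (n_placed > 1L) {
      bonded <- c(st$bond_b[st$bond_a == focus], st$bond_a[st$bond_b == focus])
      ws <- setdiff(which(st$rv >= o), c(focus, bonded))
      if (length(ws)) {
        dist <- state_distances(st, focus)
        dw <- vapply(ws, function(w) {
          sprintf("%s%+d(%s)", vocab$element[st$types[w]],
                  vocab$charge[st$types[w]],
                  paste(sort(c(st$inc_orders[[w]], o)), collapse = ""))
        }, character(1))
        kind <- c(kind, rep(3L, length(ws)))
        ordv <- c(ordv, rep(o, length(ws)))
        ttv <- c(ttv, st$types[ws]); tgt <- c(tgt, ws)
        rvt <- c(rvt, st$rv[ws] / 4)
        dfeat <- c(dfeat, pmin(dist[ws], 6L) / 6 + ws / st$total)
        keys <- c(keys, sprintf("%d|%s|%s", o, pmin(df, dw), pmax(df, dw)))
      }
    }
  }

  n_act <- length(kind)
  Phi <- matrix(0, n_act, action_feature_dim(nt))
  Phi[kind == 1L, 1L] <- 1
  Phi[, 1L + st$types[focus]] <- 1
  has_t <- which(ttv > 0L)
  Phi[cbind(has_t, 1L + nt + ttv[has_t])] <- 1
  has_o <- which(ordv > 0L)
  Phi[cbind(has_o, 1L + 2L * nt + ordv[has_o])] <- 1
  base <- 2L * nt + 4L
  Phi[, base + 1L] <- as.numeric(kind == 2L)
  Phi[, base + 2L] <- as.numeric(kind == 3L)
  Phi[kind != 1L, base + 3L] <- rvf / 4
  Phi[, base + 4L] <- rvt
  Phi[, base + 5L] <- placed_frac
  Phi[, base + 6L] <- pool_frac
  Phi[, base + 7L] <- dfeat

  f <- reciprocal_frequency(freq_table, keys)
  f[1L] <- if (n_act > 1L) exp(mean(log(f[-1L]))) else 1
  list(kind = kind, ord = ordv, ttype = ttv, target = tgt,
       keys = keys, Phi = Phi, f = f)
}

apply_action <- function(st, enum, j) {
  focus <- st$queue[1L]
  k <- enum$kind[j]
  if (k == 1L) {
    st$queue <- st$queue[-1L]
  } else if (k == 2L) {
    st <- state_place_atom(st, enum$ttype[j], from = focus, ord = enum$ord[j])
  } else {
    st <- state_add_bond(st, focus, enum$target[j], enum$ord[j])
  }
  st
}

state_to_molecule <- function(st, name = NULL) {
  vocab <- st$vocab
  mol <- molecule(vocab$element[st$types], st$bond_a, st$bond_b,
                  st$bond_order, charge = vocab$charge[st$types], name = name)
  perceive_aromaticity(mol)
}

## ---- loss -------------------------------------------------------------

#' Subgraph-frequency-reweighted action loss
#'
#' \deqn{L = -\bar f \log\left(\frac{p(x_j) f(x_j)}{\sum_i p(x_i) f(x_i)}\right)}
#' where the sum runs over permitted actions, `f` are reciprocal subgraph
#' frequencies and \eqn{\bar f} their mean. With all `f` equal this is
#' exactly the standard cross-entropy \eqn{-\log p(x_j)}.
#'
#' @param p probabilities over permitted actions (must sum to 1).
#' @param f reciprocal frequencies (> 0), same length as `p`.
#' @param j index of the chosen action.
#' @return non-negative loss value.
#' @export
reweighted_action_loss <- function(p, f, j) {
  stopifnot(length(p) == length(f), j >= 1L, j <= length(p), all(f > 0))
  if (abs(sum(p) - 1) > 1e-6) stop("p must be normalized over permitted actions")
  pj <- p[j]
  if (pj <= 0) {
    warning("p(x_j) = 0 clamped to epsilon")
    pj <- 1e-12
  }
  fbar <- mean(f)
  -fbar * log(pj * f[j] / sum(p * f))
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

## ---- ground-truth action sequences ------------------------------------

# Reconstruction order for a target molecule: breadth-first from the
# canonical root, neighbors visited in canonical-rank order. Returns the
# sequence of (state, truth action) needed to rebuild the molecule exactly.
target_action_sequence <- function(mol, vocab, freq_table) {
  mol <- kekulize(mol)
  ranks <- canonical_ranks(mol)
  types <- type_index(vocab, mol$element, mol$charge)
  n <- n_atoms(mol)
  root <- which.min(ranks)
  st <- new_state(types, vocab)
  st <- state_place_atom(st, types[root])
  placed_of <- rep(NA_integer_, n) # molecule atom -> state index
  placed_of[root] <- 1L
  steps <- list()
  repeat {
    if (!length(st$queue)) break
    focus_state <- st$queue[1L]
    focus_mol <- which(placed_of == focus_state)
    nb <- neighbors(mol, focus_mol)
    ordering <- order(ranks[nb$atom])
    truth <- NULL
    for (r in ordering) {
      v <- nb$atom[r]; o <- min(nb$order[r], 3L)
      if (is.na(placed_of[v])) {
        truth <- list(kind = "attach", ord = o, ttype = types[v], vmol = v)
        break
      }
      already <- any((st$bond_a == focus_state & st$bond_b == placed_of[v]) |
                       (st$bond_b == focus_state & st$bond_a == placed_of[v]))
      if (!already) {
        truth <- list(kind = "ring", ord = o, target = placed_of[v])
        break
      }
    }
    enum <- enumerate_actions(st, freq_table)
    j <- find_truth_index(enum, truth)
    steps[[length(steps) + 1L]] <- list(Phi = enum$Phi, f = enum$f, j = j)
    st <- apply_action(st, enum, j)
    if (!is.null(truth) && truth$kind == "attach") {
      placed_of[truth$vmol] <- length(st$types)
    }
  }
  list(steps = steps, types = types)
}

# Assembly-time frequency table: counts the radius-1 environment of every
# bond at the moment it is created during the canonical breadth-first
# reconstruction of each training molecule (plus one <stop> event per atom).
# These are exactly the keys the decoder looks up while building a partial
# graph, so generation-time reciprocal frequencies are meaningful.
assembly_frequency_table <- function(mols, vocab) {
  keys <- character()
  for (mol in mols) {
    mol <- kekulize(mol)
    ranks <- canonical_ranks(mol)
    types <- type_index(vocab, mol$element, mol$charge)
    n <- n_atoms(mol)
    root <- which.min(ranks)
    st <- new_state(types, vocab)
    st <- state_place_atom(st, types[root])
    placed_of <- rep(NA_integer_, n)
    placed_of[root] <- 1L
    while (length(st$queue)) {
      focus_state <- st$queue[1L]
      focus_mol <- which(placed_of == focus_state)
      nb <- neighbors(mol, focus_mol)
      truth <- NULL
      for (r in order(ranks[nb$atom])) {
        v <- nb$atom[r]; o <- min(nb$order[r], 3L)
        if (is.na(placed_of[v])) {
          truth <- list(kind = "attach", ord = o, ttype = types[v], vmol = v)
          break
        }
        already <- any((st$bond_a == focus_state & st$bond_b == placed_of[v]) |
                         (st$bond_b == focus_state & st$bond_a == placed_of[v]))
        if (!already) {
          truth <- list(kind = "ring", ord = o, target = placed_of[v])
          break
        }
      }
      if (is.null(truth)) {
        st$queue <- st$queue[-1L]
      } else if (truth$kind == "attach") {
        keys <- c(keys, state_env_key(st, focus_state, truth$ord,
                                      ttype = truth$ttype))
        st <- state_place_atom(st, truth$ttype, from = focus_state,
                               ord = truth$ord)
        placed_of[truth$vmol] <- length(st$types)
      } else {
        keys <- c(keys, state_env_key(st, focus_state, truth$ord,
                                      target = truth$target))
        st <- state_add_bond(st, focus_state, truth$target, truth$ord)
      }
    }
  }
  tab <- table(keys)
  counts <- as.numeric(tab)
  names(counts) <- names(tab)
  structure(list(counts = counts, total = sum(counts),
                 n_keys = length(counts)),
            class = "subgraph_frequency_table")
}

find_truth_index <- function(enum, truth) {
  j <- if (is.null(truth)) {
    which(enum$kind == 1L)[1L]
  } else if (truth$kind == "attach") {
    which(enum$kind == 2L & enum$ord == truth$ord &
            enum$ttype == truth$ttype)[1L]
  } else {
    which(enum$kind == 3L & enum$ord == truth$ord &
            enum$target == truth$target)[1L]
  }
  if (is.na(j)) stop("ground-truth action not in permitted set")
  j
}
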