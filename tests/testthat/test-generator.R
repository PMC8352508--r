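# Generative model: frequency table, reweighted loss, encoding, decoding,
# training behavior, checkpointing.

test_that("frequency table counts bond environments with symmetry", {
  ethane <- parse_smiles("CC")
  ft <- build_frequency_table(list(ethane))
  expect_s3_class(ft, "subgraph_frequency_table")
  expect_equal(ft$n_keys, 1L)   # a single C-C environment
  expect_equal(unname(ft$counts), 1)

  benz <- fixture_mol("benzene")
  ftb <- build_frequency_table(list(benz))
  expect_equal(ftb$n_keys, 1L)  # one aromatic environment by symmetry
  expect_equal(unname(ftb$counts), 6)

  # unseen keys get the smoothed minimum, reciprocal frequency stays finite
  expect_equal(smoothed_count(ftb, "no-such-key"), 1)
  f_unseen <- reciprocal_frequency(ftb, "no-such-key")
  expect_true(is.finite(f_unseen) && f_unseen > 0)
  expect_gt(f_unseen, reciprocal_frequency(ftb, names(ftb$counts)[1]))
})

test_that("reweighted loss reduces to cross-entropy for uniform frequencies", {
  set.seed(42)
  worst <- 0
  for (rep in 1:200) {
    k <- sample(2:8, 1)
    p <- runif(k); p <- p / sum(p)
    j <- sample(k, 1)
    worst <- max(worst,
                 abs(reweighted_action_loss(p, rep(1, k), j) + log(p[j])))
    # constant f = c scales the cross-entropy by c (f-bar), ratio unchanged
    cst <- runif(1, 0.1, 10)
    worst <- max(worst,
                 abs(reweighted_action_loss(p, rep(cst, k), j) +
                       cst * log(p[j])))
  }
  expect_lt(worst, 1e-12)
  # printed-formula example: p = (1/2, 1/2), f = (1, 3), chosen j = 2
  expect_equal(reweighted_action_loss(c(0.5, 0.5), c(1, 3), 2),
               2 * log(4 / 3), tolerance = 1e-12)
  # single permitted action
  expect_equal(reweighted_action_loss(1, 7, 1), 0)
  # p_j = 0 is clamped with a warning
  expect_warning(l <- reweighted_action_loss(c(1, 0), c(1, 1), 2), "clamped")
  expect_true(is.finite(l))
})

test_that("encoding is deterministic with unit scale at initialization", {
  cfg <- generator_config(seed = 3L)
  model <- structure(list(config = cfg, vocab = cfg$vocab,
                          fixed = decoygen:::init_fixed_weights(cfg),
                          params = decoygen:::init_params(cfg)),
                     class = "decoy_generator")
  m <- fixture_mol("aspirin")
  e1 <- encode(model, m)
  expect_identical(e1, encode(model, m))
  expect_length(e1$mean, cfg$latent_dim)
  expect_equal(e1$scale, rep(1, cfg$latent_dim)) # zero-initialized readout
  expect_error(encode(model, parse_smiles("CCP")), "vocabulary")
})

test_that("training reduces reconstruction loss and is seed-reproducible", {
  lib <- make_library(40, atom_range = c(5L, 8L), seed = 11)
  pairs <- suppressWarnings(build_pairs(
    lib, property_set("dude6"),
    pair_config(max_similarity = 1, max_distance = 1e6,
                property_set_name = "dude6"), seed = 1))
  pairs <- pairs[seq_len(min(20L, nrow(pairs))), ]
  sp <- holdout_split(pairs, 4L, seed = 2)
  cfg <- generator_config(epochs = 5L, lr = 0.05, seed = 13L)
  model <- train_generator(sp$train, lib, validation = sp$validation,
                           config = cfg)
  h <- model$history
  expect_equal(nrow(h), 5L)
  expect_lt(h$L_recon[5], h$L_recon[1])
  expect_true(all(is.finite(h$L_total)))
  expect_true(all(h$L_kl >= 0))
  expect_true(all(is.finite(h$val_L_recon)))
  # identical seeds give identical loss histories
  model2 <- train_generator(sp$train, lib, validation = sp$validation,
                            config = cfg)
  expect_identical(model$history, model2$history)
  # lambda_kl = 0 makes L_total equal L_recon exactly
  cfg0 <- generator_config(epochs = 3L, lambda_kl = 0, seed = 13L)
  m0 <- train_generator(sp$train, lib, config = cfg0)
  expect_equal(m0$history$L_total, m0$history$L_recon)
})

test_that("a single pair can be overfit with lambda_kl = 0", {
  lib <- list(parse_smiles("CCOC"), parse_smiles("CC(C)O"))
  pairs <- data.frame(a = 1L, b = 2L)
  cfg <- generator_config(epochs = 150L, lr = 0.1, lambda_kl = 0, seed = 5L)
  model <- train_generator(pairs, lib, config = cfg)
  h <- model$history
  expect_lt(h$L_action[nrow(h)], 0.05 * h$L_action[1])
})

test_that("decoding respects budget, valence, and determinism", {
  fx <- fixture_model()
  model <- fx$model
  active <- fx$library[[1]]
  dec <- generate_decoys(model, active, 25, seed = 31)
  expect_lte(length(dec), 25L)
  for (m in dec) {
    expect_true(check_valence(m)$valid)
    expect_lte(n_atoms(m), n_atoms(active))
    expect_true(decoygen:::is_connected(m))
  }
  # composition stays within the active's element budget
  ec_a <- element_counts(active)
  for (m in dec[1:5]) {
    ec <- element_counts(m)
    shared <- intersect(names(ec), names(ec_a))
    expect_true(all(ec[shared] <= ec_a[shared]))
  }
  dec2 <- generate_decoys(model, active, 25, seed = 31)
  expect_identical(vapply(dec, canonical_smiles, character(1)),
                   vapply(dec2, canonical_smiles, character(1)))
  expect_length(generate_decoys(model, active, 0, seed = 1), 0L)
})

test_that("a partial substructure can seed the decode", {
  fx <- fixture_model()
  active <- fx$library[[1]]
  frag <- parse_smiles("CC")
  cond <- c(decoygen:::graph_embedding(fx$model, active),
            rep(0, fx$model$config$latent_dim))
  m <- decode(fx$model, cond, element_counts(active), seed = 8,
              seed_graph = frag)
  expect_true(check_valence(m)$valid)
  expect_gte(n_atoms(m), 2L)
  # the seeded atoms and their bond are part of the output
  expect_equal(m$element[1:2], c("C", "C"))
  expect_true(any((m$bond_a == 1L & m$bond_b == 2L) |
                    (m$bond_a == 2L & m$bond_b == 1L)))
  # a fragment outside the budget is rejected
  expect_error(decode(fx$model, cond, c(total = 2L, C = 2L), seed = 1,
                      seed_graph = parse_smiles("CCO")), "budget")
})

test_that("a one-carbon budget can only produce methane", {
  fx <- fixture_model()
  budget <- c(total = 1L, C = 1L)
  m <- decode(fx$model, c(decoygen:::graph_embedding(fx$model, fx$library[[1]]),
                          rep(0, fx$model$config$latent_dim)),
              budget, seed = 4)
  expect_equal(n_atoms(m), 1L)
  expect_equal(m$element, "C")
})

test_that("checkpoints restore bit-identical generation", {
  fx <- fixture_model()
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_model(fx$model, path)
  loaded <- load_model(path)
  a <- generate_decoys(fx$model, fx$library[[2]], 10, seed = 77)
  b <- generate_decoys(loaded, fx$library[[2]], 10, seed = 77)
  expect_identical(vapply(a, canonical_smiles, character(1)),
                   vapply(b, canonical_smiles, character(1)))
})

test_that("fitted-model methods behave like a classic model object", {
  fx <- fixture_model()
  expect_output(print(fx$model), "decoy_generator")
  expect_output(summary(fx$model), "Loss history")
  expect_named(coef(fx$model),
               c("W_mu", "b_mu", "W_ls", "b_ls", "w_act", "W_act",
                 "U_type", "b_type"))
  sims <- simulate(fx$model, nsim = 5, seed = 2, active = fx$library[[1]])
  expect_lte(length(sims), 5L)
  enc <- predict(fx$model, fx$library[[1]])
  expect_length(enc$mean, fx$model$config$latent_dim)
  lat <- predict(fx$model, fx$library[1:3])
  expect_equal(dim(lat), c(3L, fx$model$config$latent_dim))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fx$model))
})
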