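## End-to-end pipeline: pair building -> training -> generation/selection ->
## bias assessment, driven by a flat key/value run configuration that is
## serialized alongside every output so any run can be reproduced exactly.

#' Run configuration
#'
#' Flat list of paths, thresholds, seeds and model hyperparameters. A single
#' global `seed` fans out deterministically to per-stage seeds.
#'
#' @param library_path SMILES/SDF file with the training library (for
#'   fixture-driven runs, leave `NULL` and set `fixture_n`).
#' @param actives_path SMILES/SDF file with the target's actives (default:
#'   first `n_actives` library molecules).
#' @param out_dir output directory.
#' @param property_set property set name.
#' @param max_similarity,max_distance pair-building thresholds.
#' @param epochs,latent_dim,hidden_dim generator hyperparameters.
#' @param candidates_per_active,min_pool,decoys_per_active selection settings.
#' @param n_actives number of actives when taken from the library.
#' @param fixture_n,fixture_seed fixture library size/seed when no
#'   `library_path` is given.
#' @param seed global seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(library_path = NULL, actives_path = NULL,
                       out_dir = tempfile("decoygen_run_"),
                       property_set = "dude6", max_similarity = 0.15,
                       max_distance = 0.20, epochs = 30L, latent_dim = 8L,
                       hidden_dim = 16L, candidates_per_active = 200L,
                       min_pool = 50L, decoys_per_active = 10L,
                       n_actives = 2L, fixture_n = 50L, fixture_seed = 7L,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration (flat YAML key/value file)
#'
#' @param cfg a [run_config()].
#' @param path file path.
#' @return `write_run_config`: path invisibly; `read_run_config`: the config.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  cfg <- do.call(run_config, vals[names(vals) %in% names(formals(run_config))])
  cfg
}

#' Run the full decoy-generation pipeline
#'
#' Stages: load or synthesize the library, build training pairs, train the
#' generator, generate and select decoys for the actives, and assess the
#' final set. Outputs (decoys, report, config echo, model checkpoint) are
#' written under `cfg$out_dir`; identical configs and seeds give identical
#' artifacts. A stage failure halts the pipeline with the stage name; partial
#' outputs are preserved.
#'
#' @param cfg a [run_config()].
#' @param quiet suppress progress messages.
#' @return list with `decoy_set`, `bias_report`, `model`, `paths`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    say("[%s] done in %.1fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    res
  }
  write_run_config(cfg, file.path(cfg$out_dir, "config.yaml"))

  library_mols <- stage("library", {
    if (!is.null(cfg$library_path)) {
      if (!file.exists(cfg$library_path))
        stop(sprintf("missing input: %s", cfg$library_path))
      parse_molecules(cfg$library_path)
    } else {
      # compact palette and size range so composition buckets are dense
      # enough for pair building at fixture scale
      make_library(cfg$fixture_n, atom_range = c(7L, 10L),
                   palette = c("C", "N", "O"), palette_weights = c(10, 1, 1),
                   seed = cfg$fixture_seed)
    }
  })
  actives <- stage("actives", {
    if (!is.null(cfg$actives_path)) {
      if (!file.exists(cfg$actives_path))
        stop(sprintf("missing input: %s", cfg$actives_path))
      parse_molecules(cfg$actives_path)
    } else {
      library_mols[seq_len(min(cfg$n_actives, length(library_mols)))]
    }
  })
  pset <- property_set(cfg$property_set)

  pairs <- stage("make-pairs", {
    pc <- pair_config(max_similarity = cfg$max_similarity,
                      max_distance = cfg$max_distance,
                      property_set_name = cfg$property_set)
    p <- suppressWarnings(build_pairs(library_mols, pset, pc,
                                      seed = derive_seed(cfg$seed, "pairs")))
    if (!nrow(p)) {
      # fixture libraries can be too diverse for the strict thresholds;
      # fall back to composition-matched pairs so training has signal
      p <- suppressWarnings(build_pairs(
        library_mols, pset,
        pair_config(max_similarity = 1, max_distance = 1e6,
                    property_set_name = cfg$property_set),
        seed = derive_seed(cfg$seed, "pairs")))
    }
    p
  })
  model <- stage("train", {
    gcfg <- generator_config(latent_dim = cfg$latent_dim,
                             hidden_dim = cfg$hidden_dim,
                             epochs = cfg$epochs,
                             seed = derive_seed(cfg$seed, "train"))
    train_generator(pairs, library_mols, config = gcfg)
  })
  save_model(model, file.path(cfg$out_dir, "model.ckpt"))

  dset <- stage("select", {
    scfg <- selection_config(candidates_per_active = cfg$candidates_per_active,
                             min_pool = cfg$min_pool,
                             decoys_per_active = cfg$decoys_per_active,
                             property_set_name = cfg$property_set)
    build_decoy_set(actives, model, scfg,
                    seed = derive_seed(cfg$seed, "select"), pset = pset)
  })
  all_decoys <- unlist(dset$decoys, recursive = FALSE)
  decoy_path <- file.path(cfg$out_dir, "decoys.smi")
  write_molecules(all_decoys, decoy_path, "smi")

  report <- stage("evaluate", {
    compile_report("pipeline", actives, all_decoys, pset,
                   n_folds = 3L, seed = derive_seed(cfg$seed, "evaluate"),
                   path = file.path(cfg$out_dir, "bias_report.json"))
  })
  list(decoy_set = dset, bias_report = report, model = model,
       paths = list(out_dir = cfg$out_dir, decoys = decoy_path,
                    report = file.path(cfg$out_dir, "bias_report.json"),
                    model = file.path(cfg$out_dir, "model.ckpt"),
                    config = file.path(cfg$out_dir, "config.yaml")))
}
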