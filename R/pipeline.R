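#' Assemble a full pipeline configuration
#'
#' One nested list holds every stage's parameters; the whole object is
#' serialised as YAML into each run directory, so a run is reproducible from
#' its config and seed alone. Either file paths (`edges_path`,
#' `communities_path`) or in-memory objects (`graph`, `known`) may supply
#' the inputs.
#'
#' @param edges_path,communities_path input files (edge list; one community
#'   per line).
#' @param graph,known in-memory alternatives to the paths.
#' @param weight_cutoff edge weight cutoff applied at load.
#' @param merge_j Jaccard threshold for merging similar known communities.
#' @param train_frac train fraction of the community split.
#' @param neg_scale,neg_distribution,j_neg negative-sampling controls.
#' @param fitness_backend `"grid"`, `"automl"`, or `"density"` (the
#'   model-free density baseline; no training stage).
#' @param cv_folds cross-validation folds for model selection.
#' @param seed_mode,n_random seed selection (see [select_seeds()]).
#' @param search a [search_params()]; its `max_steps` is overridden when
#'   `max_steps = "auto"`.
#' @param max_steps `"auto"` (from known sizes via [max_steps_smart()]) or
#'   an integer.
#' @param merge a [merge_params()].
#' @param qi_t binary-match threshold used in evaluation.
#' @param eval_against `"test"` (held-out known communities; the honest
#'   benchmark when the fitness function was trained) or `"all"` (every
#'   known community; appropriate for validation runs such as the
#'   disconnected-clique toy where nothing is trained).
#' @param n_workers forked workers for the search stage.
#' @param rng_seed global seed; all stage seeds derive from it.
#' @param out_dir run directory (default: a fresh temporary directory).
#' @return a `run_config` list.
#' @export
run_config <- function(edges_path = NULL, communities_path = NULL,
                       graph = NULL, known = NULL, weight_cutoff = 0,
                       merge_j = 0.6, train_frac = 0.7, neg_scale = 1.1,
                       neg_distribution = "uniform", j_neg = 0.5,
                       fitness_backend = c("grid", "automl", "density"),
                       cv_folds = 5, seed_mode = "all_nodes", n_random = NULL,
                       search = search_params(), max_steps = "auto",
                       merge = merge_params(), qi_t = 0.5,
                       eval_against = c("test", "all"), n_workers = 1,
                       rng_seed = 1, out_dir = NULL) {
  fitness_backend <- match.arg(fitness_backend)
  eval_against <- match.arg(eval_against)
  structure(
    list(edges_path = edges_path, communities_path = communities_path,
         graph = graph, known = known, weight_cutoff = weight_cutoff,
         merge_j = merge_j, train_frac = train_frac, neg_scale = neg_scale,
         neg_distribution = neg_distribution, j_neg = j_neg,
         fitness_backend = fitness_backend, cv_folds = cv_folds,
         seed_mode = seed_mode, n_random = n_random, search = search,
         max_steps = max_steps, merge = merge, qi_t = qi_t,
         eval_against = eval_against,
         n_workers = n_workers, rng_seed = rng_seed,
         out_dir = out_dir %||% tempfile("commfit_run_")),
    class = "run_config"
  )
}

#' Load a pipeline configuration from a YAML file
#'
#' Flat or nested keys matching the [run_config()] arguments; `search` and
#' `merge` sub-maps are passed to [search_params()] / [merge_params()].
#'
#' @param path YAML file.
#' @param ... overrides applied on top of the file's values.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$search)) vals$search <- do.call(search_params, vals$search)
  if (!is.null(vals$merge)) vals$merge <- do.call(merge_params, vals$merge)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full detection pipeline
#'
#' Executes prepare (load, clean, merge, split, negatives), feature
#' extraction, fitness-function training, candidate search, overlap merging,
#' and evaluation against the held-out known communities. Every intermediate
#' artifact is written into the run directory together with the serialised
#' config and a manifest of seeds, versions and per-stage counts; partial
#' artifacts are retained when a stage fails.
#'
#' @param config a [run_config()].
#' @return a list with the run directory and all in-memory artifacts
#'   (`graph`, `known`, `split`, `model`, `fitness_eval`, `candidates`,
#'   `learned`, `report`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(feature_version = FEATURE_VERSION,
                   rng_seed = config$rng_seed, counts = list(),
                   timings = list())
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- stage(name, expr)
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }
  save_config(config, file.path(config$out_dir, "config.yaml"))

  graph <- timed("load_graph", {
    config$graph %||% load_graph(config$edges_path, config$weight_cutoff)
  })
  known_raw <- timed("load_communities", {
    config$known %||% read_communities(config$communities_path)
  })
  known <- timed("prepare", {
    clean_communities(known_raw, graph) |> merge_similar(j = config$merge_j)
  })
  manifest$counts$known_raw <- nrow(known_raw)
  manifest$counts$known_clean <- nrow(known)
  write_communities(known, file.path(config$out_dir, "known_clean.txt"),
                    with_score = FALSE)

  split <- timed("split", {
    split_train_test(known, graph, train_frac = config$train_frac,
                     rng_seed = config$rng_seed)
  })
  write_communities(split$train, file.path(config$out_dir, "known_train.txt"),
                    with_score = FALSE)
  write_communities(split$test, file.path(config$out_dir, "known_test.txt"),
                    with_score = FALSE)

  model <- NULL
  fitness_eval <- NULL
  if (config$fitness_backend == "density") {
    model <- density_model()
  } else {
    negatives <- timed("negatives", {
      suppressMessages(
        sample_negatives(graph, known, scale_factor = config$neg_scale,
                         distribution = config$neg_distribution,
                         rng_seed = config$rng_seed) |>
          filter_negatives(known, j_neg = config$j_neg)
      )
    })
    manifest$counts$negatives <- nrow(negatives)
    if (nrow(negatives) < 2) {
      abort("pipeline stage 'negatives' failed: too few negatives survived filtering")
    }
    idx <- with_seed(config$rng_seed, sample.int(nrow(negatives)))
    n_tr <- max(1L, min(nrow(negatives) - 1L,
                        round(config$train_frac * nrow(negatives))))
    train_feat <- timed("features", {
      build_feature_matrix(split$train, negatives[sort(idx[seq_len(n_tr)]), ], graph)
    })
    test_feat <- stage("features", {
      build_feature_matrix(split$test, negatives[sort(idx[-seq_len(n_tr)]), ], graph)
    })
    write_feature_matrix(train_feat, file.path(config$out_dir, "train_features.tsv"))
    write_feature_matrix(test_feat, file.path(config$out_dir, "test_features.tsv"))
    model <- timed("train", {
      train_fitness(train_feat, cv_folds = config$cv_folds,
                    backend = config$fitness_backend,
                    rng_seed = config$rng_seed)
    })
    fitness_eval <- stage("train", evaluate_fitness(model, test_feat, train_feat))
    save_fitness_model(model, file.path(config$out_dir, "model.rds"))
  }

  sp <- config$search
  sp$rng_seed <- config$rng_seed
  if (identical(config$max_steps, "auto")) {
    sp$max_steps <- max_steps_smart(known)
  } else if (is.numeric(config$max_steps)) {
    sp$max_steps <- as.integer(config$max_steps)
  }
  seeds <- timed("seeds", {
    select_seeds(graph, mode = config$seed_mode, known = known,
                 n_random = config$n_random, rng_seed = config$rng_seed)
  })
  candidates <- timed("search", {
    run_search(graph, model, seeds, sp, n_workers = config$n_workers)
  })
  manifest$counts$candidates <- nrow(candidates)
  write_communities(candidates, file.path(config$out_dir, "candidates.txt"))

  learned <- timed("merge", {
    remove_small(candidates) |>
      merge_learned(model, graph, params = config$merge)
  })
  manifest$counts$learned <- nrow(learned)
  write_communities(learned, file.path(config$out_dir, "learned.txt"))

  reference <- if (config$eval_against == "all") known else split$test
  report <- timed("evaluate", {
    evaluate_communities(learned, reference, qi_t = config$qi_t)
  })
  write_report(report, file.path(config$out_dir, "report.tsv"))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))

  list(out_dir = config$out_dir, graph = graph, known = known, split = split,
       model = model, fitness_eval = fitness_eval, candidates = candidates,
       learned = learned, report = report, manifest = manifest)
}

save_config <- function(config, path) {
  serializable <- config
  serializable$graph <- if (!is.null(config$graph)) "<in-memory graph>" else NULL
  serializable$known <- if (!is.null(config$known)) "<in-memory communities>" else NULL
  serializable$search <- unclass(config$search)
  serializable$merge <- unclass(config$merge)
  yaml::write_yaml(unclass(serializable), path)
}

#' Sweep search / merge parameters, selecting by binary-match F1
#'
#' Prepares the data and trains the fitness model once, then reruns the
#' search + merge + evaluate stages for every row of the parameter grid.
#' Failed grid points are recorded and the sweep continues.
#'
#' @param config a [run_config()] providing the fixed stages.
#' @param grid a data frame whose columns are any of `epsilon`, `k_accept`,
#'   `T0`, `alpha`, `heuristic`, `max_steps`, `merge_threshold`,
#'   `merge_measure`; one sweep run per row.
#' @return a list with `table` (one row per grid point, all headline
#'   measures, sorted by descending binary-match F1), `best` (the winning
#'   grid row), and `base` (the shared prepared pipeline state).
#' @export
parameter_sweep <- function(config, grid) {
  if (nrow(grid) == 0) abort("parameter_sweep: empty grid")
  base_config <- config
  base_config$out_dir <- file.path(config$out_dir, "base")
  base <- run_pipeline(base_config)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, , drop = FALSE]
    sp <- config$search
    for (nm in intersect(names(g), c("epsilon", "k_accept", "T0", "alpha",
                                     "heuristic", "max_steps"))) {
      sp[[nm]] <- g[[nm]]
    }
    sp$rng_seed <- config$rng_seed
    if (is.null(g$max_steps) && identical(config$max_steps, "auto")) {
      sp$max_steps <- max_steps_smart(base$known)
    }
    mp <- config$merge
    if (!is.null(g$merge_threshold)) mp$threshold <- g$merge_threshold
    if (!is.null(g$merge_measure)) mp$measure <- g$merge_measure
    out <- tryCatch({
      seeds <- select_seeds(base$graph, mode = config$seed_mode,
                            known = base$known, n_random = config$n_random,
                            rng_seed = config$rng_seed)
      cands <- run_search(base$graph, base$model, seeds, sp,
                          n_workers = config$n_workers)
      learned <- remove_small(cands) |>
        merge_learned(base$model, base$graph, params = mp)
      reference <- if (config$eval_against == "all") base$known else base$split$test
      glance(evaluate_communities(learned, reference, qi_t = config$qi_t))
    }, error = function(e) {
      tibble(qi_f1 = NA_real_, error = conditionMessage(e))
    })
    bind_cols(as_tibble(g), out)
  })
  table <- bind_rows(rows) |> arrange(desc(.data$qi_f1))
  list(table = table, best = table[1, ], base = base)
}
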