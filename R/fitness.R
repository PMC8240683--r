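#' Train the community fitness function
#'
#' Learns a binary classifier that maps a community's 18-feature topological
#' embedding to a probability of being a genuine community — the community
#' fitness function used to steer candidate growth. The default `"grid"`
#' backend fits a fixed candidate set (L2-regularised logistic regression,
#' random forest, gradient boosting, each behind a standardising scaler),
#' scores each by stratified k-fold cross-validated average precision, and
#' refits the winner on the full training matrix. Class imbalance introduced
#' by negative over-sampling is handled with inverse-frequency class
#' weights. The `"automl"` backend delegates model search to an external
#' AutoML engine when one is available; in this build none is bundled, so it
#' falls back to the grid with a warning.
#'
#' @param train a feature tibble from [build_feature_matrix()] containing
#'   both classes.
#' @param cv_folds number of cross-validation folds (default 5).
#' @param backend `"grid"` or `"automl"`.
#' @param rng_seed integer seed controlling fold assignment and the
#'   stochastic learners.
#' @return a `commfit_fitness` object: the fitted pipeline, its scaler, the
#'   per-candidate CV table, `cv_score` (the winner's mean CV average
#'   precision) and the versioned feature-name manifest.
#' @export
train_fitness <- function(train, cv_folds = 5, backend = c("grid", "automl"),
                          rng_seed = 1) {
  backend <- match.arg(backend)
  if (backend == "automl") {
    warn("no AutoML engine available; falling back to the grid backend")
    backend <- "grid"
  }
  xy <- split_features(train)
  if (length(unique(xy$y)) < 2) abort("train_fitness: need both classes in training data")
  scaler <- fit_scaler(xy$x)
  xs <- apply_scaler(scaler, xy$x)
  folds <- stratified_folds(xy$y, cv_folds, rng_seed)
  cands <- candidate_learners()
  cv_tbl <- purrr::map(names(cands), function(nm) {
    aps <- vapply(seq_len(cv_folds), function(k) {
      tr <- folds != k
      fit <- cands[[nm]]$fit(xs[tr, , drop = FALSE], xy$y[tr], rng_seed)
      sc <- cands[[nm]]$predict(fit, xs[!tr, , drop = FALSE])
      if (length(unique(xy$y[!tr])) < 2) return(NA_real_)
      average_precision(sc, xy$y[!tr])
    }, 0)
    tibble(candidate = nm, cv_ap = mean(aps, na.rm = TRUE),
           cv_ap_sd = stats::sd(aps, na.rm = TRUE))
  }) |> bind_rows()
  best <- cv_tbl$candidate[which.max(cv_tbl$cv_ap)]
  fit <- cands[[best]]$fit(xs, xy$y, rng_seed)
  structure(
    list(
      type = "classifier", backend = backend, candidate = best, fit = fit,
      scaler = scaler, cv_score = max(cv_tbl$cv_ap), cv_table = cv_tbl,
      feature_names = feature_names(), feature_version = FEATURE_VERSION,
      rng_seed = rng_seed
    ),
    class = "commfit_fitness"
  )
}

#' Density-baseline fitness model
#'
#' A model-free scoring function with the same interface as a trained
#' classifier: the density fitness (intra- minus inter-cluster density),
#' clipped to \[0, 1\]. Useful as a baseline and on datasets where every
#' subgraph topology is degenerate (e.g. disconnected cliques, where all
#' connected subgraphs are cliques and a classifier has no signal).
#'
#' @return a `commfit_fitness` object of type `"density"`.
#' @export
density_model <- function() {
  structure(
    list(type = "density", candidate = "density_baseline", cv_score = NA_real_,
         feature_names = feature_names(), feature_version = FEATURE_VERSION),
    class = "commfit_fitness"
  )
}

#' @export
print.commfit_fitness <- function(x, ...) {
  if (x$type == "density") {
    cat("<commfit_fitness> density baseline (intra - inter density, clipped to [0,1])\n")
  } else {
    cat("<commfit_fitness>", x$candidate,
        sprintf("(CV average precision %.3f)\n", x$cv_score))
  }
  invisible(x)
}

split_features <- function(features) {
  stopifnot(all(feature_names() %in% names(features)), "label" %in% names(features))
  list(
    x = as.matrix(features[, feature_names()]),
    y = as.integer(features$label)
  )
}

fit_scaler <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_scaler <- function(scaler, x) {
  scale(x, center = scaler$center, scale = scaler$scale)[, , drop = FALSE]
}

stratified_folds <- function(y, k, rng_seed) {
  folds <- integer(length(y))
  with_seed(rng_seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

class_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * tab[as.character(y)])
  as.numeric(w)
}

candidate_learners <- function() {
  list(
    logistic_ridge = list(
      fit = function(x, y, seed) {
        glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = 0.01,
                       weights = class_weights(y))
      },
      predict = function(fit, x) {
        as.numeric(stats::predict(fit, newx = x, type = "response"))
      }
    ),
    random_forest = list(
      fit = function(x, y, seed) {
        ranger::ranger(
          x = as.data.frame(x), y = factor(y, levels = c(0, 1)),
          probability = TRUE, num.trees = 500, seed = seed,
          num.threads = 1, case.weights = class_weights(y)
        )
      },
      predict = function(fit, x) {
        stats::predict(fit, data = as.data.frame(x),
                       num.threads = 1)$predictions[, "1"]
      }
    ),
    gradient_boosting = list(
      fit = function(x, y, seed) {
        n1 <- sum(y == 1)
        xgboost::xgb.train(
          params = list(objective = "binary:logistic", max_depth = 3,
                        eta = 0.1, nthread = 1, seed = seed,
                        scale_pos_weight = (length(y) - n1) / n1),
          data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
          nrounds = 100, verbose = 0
        )
      },
      predict = function(fit, x) {
        as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(x, nthread = 1)))
      }
    )
  )
}

# batch scores for a plain feature matrix (rows in feature_names() order)
score_embeddings <- function(model, x) {
  stopifnot(inherits(model, "commfit_fitness"))
  if (model$type == "density") {
    abort("density model scores communities, not embeddings")
  }
  xs <- apply_scaler(model$scaler, x)
  candidate_learners()[[model$candidate]]$predict(model$fit, xs)
}

# score one node set under either model type
score_node_set <- function(model, graph, nodes) {
  if (model$type == "density") {
    min(1, max(0, density_fitness(graph, nodes)))
  } else {
    x <- matrix(community_embedding(graph, nodes), nrow = 1,
                dimnames = list(NULL, feature_names()))
    score_embeddings(model, x)
  }
}

#' Score communities with a fitness model
#'
#' @param comms a community tibble.
#' @param model a `commfit_fitness` object.
#' @param graph a `weighted_graph`.
#' @return `comms` with the `score` column filled in (positive-class
#'   probability for a classifier; clipped density fitness for the
#'   baseline).
#' @export
score_communities <- function(comms, model, graph) {
  comms$score <- vapply(comms$nodes, function(ns) {
    score_node_set(model, graph, ns)
  }, 0)
  comms
}

#' Evaluate a fitness model on a held-out feature matrix
#'
#' @param model a trained `commfit_fitness` classifier.
#' @param test a feature tibble with both classes.
#' @param train optional training feature tibble; when supplied, the same
#'   metrics are computed on it for over/underfit inspection.
#' @return a `commfit_eval` object: average precision, PR curve points,
#'   precision/recall/F1/accuracy at the 0.5 threshold, and accuracy binned
#'   by community size (bins partition all rows).
#' @export
evaluate_fitness <- function(model, test, train = NULL) {
  report_one <- function(features) {
    xy <- split_features(features)
    if (length(unique(xy$y)) < 2) abort("evaluate_fitness: need both classes")
    sc <- score_embeddings(model, xy$x)
    pred <- as.integer(sc >= 0.5)
    tp <- sum(pred == 1 & xy$y == 1)
    prec <- if (sum(pred) > 0) tp / sum(pred) else 0
    rec <- tp / sum(xy$y)
    sizes <- features$n_nodes
    size_bins <- tibble(size = sizes, correct = pred == xy$y) |>
      group_by(.data$size) |>
      summarise(n = dplyr::n(), accuracy = mean(.data$correct), .groups = "drop")
    list(
      average_precision = average_precision(sc, xy$y),
      pr_curve = pr_curve_points(sc, xy$y),
      precision = prec, recall = rec, f1 = harmonic_mean(prec, rec),
      accuracy = mean(pred == xy$y),
      size_accuracy = size_bins,
      n = length(xy$y)
    )
  }
  out <- list(test = report_one(test),
              train = if (!is.null(train)) report_one(train))
  structure(out, class = "commfit_eval")
}

#' @export
print.commfit_eval <- function(x, ...) {
  cat(sprintf(
    "<commfit_eval> test AP %.3f | P %.3f R %.3f F1 %.3f | accuracy %.3f (n=%d)\n",
    x$test$average_precision, x$test$precision, x$test$recall, x$test$f1,
    x$test$accuracy, x$test$n))
  if (!is.null(x$train)) {
    cat(sprintf("               train AP %.3f | accuracy %.3f (n=%d)\n",
                x$train$average_precision, x$train$accuracy, x$train$n))
  }
  invisible(x)
}

#' Persist a fitness model
#'
#' Writes a single versioned artifact embedding the feature-name manifest;
#' [load_fitness_model()] refuses artifacts whose manifest disagrees with
#' this package's feature definition.
#'
#' @param model a `commfit_fitness` object.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
save_fitness_model <- function(model, path) {
  stopifnot(inherits(model, "commfit_fitness"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_fitness_model
#' @export
load_fitness_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "commfit_fitness")) abort("not a fitness model artifact")
  if (!identical(model$feature_version, FEATURE_VERSION) ||
      !identical(model$feature_names, feature_names())) {
    abort("model artifact feature manifest does not match this package's feature set")
  }
  model
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-candidate cross-validation table of a fitness model
#' @param x a `commfit_fitness` object.
#' @param ... unused.
#' @return a tibble with one row per candidate learner.
#' @export
tidy.commfit_fitness <- function(x, ...) {
  if (x$type == "density") {
    return(tibble(candidate = "density_baseline", cv_ap = NA_real_,
                  cv_ap_sd = NA_real_, selected = TRUE))
  }
  x$cv_table |> mutate(selected = .data$candidate == x$candidate)
}

#' One-row summary of a fitness model
#' @param x a `commfit_fitness` object.
#' @param ... unused.
#' @return a one-row tibble.
#' @export
glance.commfit_fitness <- function(x, ...) {
  tibble(type = x$type, candidate = x$candidate, cv_score = x$cv_score,
         n_features = length(x$feature_names),
         feature_version = x$feature_version)
}

#' Tidy the PR curve of a fitness evaluation
#' @param x a `commfit_eval` object.
#' @param ... unused.
#' @return the test-set PR curve points as a tibble.
#' @export
tidy.commfit_eval <- function(x, ...) x$test$pr_curve

#' One-row summary of a fitness evaluation
#' @param x a `commfit_eval` object.
#' @param ... unused.
#' @return a one-row tibble of headline test metrics.
#' @export
glance.commfit_eval <- function(x, ...) {
  tibble(
    average_precision = x$test$average_precision,
    precision = x$test$precision, recall = x$test$recall, f1 = x$test$f1,
    accuracy = x$test$accuracy, n = x$test$n,
    train_average_precision = if (!is.null(x$train)) x$train$average_precision else NA_real_
  )
}
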