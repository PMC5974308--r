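#' Candidate regressors for the dynamics-learning search space
#'
#' Each candidate is a small pipeline (optional feature standardisation +
#' one regressor family) competing to model one metabolite's derivative as
#' a function of the concatenated metabolite and protein concentrations.
#' Available families:
#' * `cand_lm()` - ordinary least squares;
#' * `cand_ridge(lambda)` - ridge regression (glmnet, `alpha = 0`);
#' * `cand_knn(k)` - k-nearest-neighbour regression on standardised
#'   features (caret);
#' * `cand_rf(num_trees)` - random forest (ranger).
#'
#' @param lambda Ridge penalty.
#' @param k Neighbour count.
#' @param num_trees Number of trees.
#' @return A `pathdyn_candidate` object.
#' @name candidates
NULL

new_candidate <- function(id, family, n_steps, n_hyper, fit, predict) {
  structure(list(id = id, family = family, n_steps = n_steps,
                 n_hyper = n_hyper, fit = fit, predict = predict),
            class = "pathdyn_candidate")
}

#' @rdname candidates
#' @export
cand_lm <- function() {
  new_candidate(
    "lm", "linear", n_steps = 1, n_hyper = 0,
    fit = function(X, y, seed) {
      cf <- stats::lm.fit(cbind(1, X), y)$coefficients
      cf[is.na(cf)] <- 0
      list(coef = cf)
    },
    predict = function(obj, X) drop(cbind(1, X) %*% obj$coef)
  )
}

#' @rdname candidates
#' @export
cand_ridge <- function(lambda = 0.01) {
  new_candidate(
    paste0("ridge(", lambda, ")"), "ridge", n_steps = 1, n_hyper = 1,
    fit = function(X, y, seed) {
      glmnet::glmnet(X, y, alpha = 0, lambda = lambda, standardize = TRUE)
    },
    predict = function(obj, X) drop(predict(obj, X))
  )
}

#' @rdname candidates
#' @export
cand_knn <- function(k = 5) {
  new_candidate(
    paste0("knn(", k, ")"), "knn", n_steps = 2, n_hyper = 1,
    fit = function(X, y, seed) {
      ctr <- colMeans(X)
      scl <- apply(X, 2, sd)
      scl[scl < 1e-12] <- 1
      Xs <- scale(X, center = ctr, scale = scl)
      list(fit = caret::knnreg(Xs, y, k = min(k, nrow(X))),
           center = ctr, scale = scl)
    },
    predict = function(obj, X) {
      predict(obj$fit, scale(X, center = obj$center, scale = obj$scale))
    }
  )
}

#' @rdname candidates
#' @export
cand_rf <- function(num_trees = 200) {
  new_candidate(
    paste0("rf(", num_trees, ")"), "random_forest", n_steps = 1, n_hyper = 1,
    fit = function(X, y, seed) {
      ranger::ranger(x = as.data.frame(X), y = y, num.trees = num_trees,
                     seed = seed, num.threads = 1)
    },
    predict = function(obj, X) {
      predict(obj, data = as.data.frame(X), num.threads = 1)$predictions
    }
  )
}

#' Model search spaces
#'
#' A search space bundles the candidate pipelines, the cross-validation fold
#' count and the seed controlling fold assignment and any stochastic
#' learners. [select_model()] evaluates every candidate by k-fold
#' cross-validated RMSE and keeps the winner, so enlarging a space can only
#' improve (never worsen) the winning score.
#'
#' `default_search_space()` covers linear, ridge, nearest-neighbour and
#' random-forest families. `compact_search_space()` is the fast subset
#' (linear, ridge, two nearest-neighbour settings) used by the repeated
#' ranking and scaling experiments, where hundreds of model fits and
#' trajectory integrations must stay tractable.
#'
#' @param candidates List of [candidates] objects, at least one.
#' @param folds Cross-validation fold count (10 by default; reduced
#'   automatically when there are fewer rows than folds).
#' @param seed Integer seed.
#' @return A `search_space` object.
#' @export
search_space <- function(candidates, folds = 10, seed = 1) {
  if (length(candidates) < 1) {
    abort("A search space needs at least one candidate.",
          class = "pathdyn_configuration_error")
  }
  stopifnot(all(map_lgl(candidates, inherits, "pathdyn_candidate")))
  structure(list(candidates = candidates, folds = folds, seed = seed),
            class = "search_space")
}

#' @rdname search_space
#' @export
default_search_space <- function(folds = 10, seed = 1) {
  search_space(list(cand_lm(), cand_ridge(0.01), cand_ridge(1),
                    cand_knn(5), cand_knn(10), cand_rf(200)),
               folds = folds, seed = seed)
}

#' @rdname search_space
#' @export
compact_search_space <- function(folds = 10, seed = 1) {
  search_space(list(cand_lm(), cand_ridge(0.01), cand_knn(5), cand_rf(100)),
               folds = folds, seed = seed)
}

# Fold ids for n rows. Folds are grouped by strain whenever more than one
# strain is present (all rows of a strain fall on the same fold side), so
# cross-validation measures cross-strain generalisation: augmented rows of
# one strain are strongly correlated, and splitting them across folds would
# reward trajectory memorisation. With a single strain, plain shuffled
# row-level folds are used.
fold_ids <- function(strain, folds, seed) {
  n <- length(strain)
  strains <- unique(strain)
  withr::with_seed(seed, {
    if (length(strains) >= 2) {
      k <- min(folds, length(strains))
      grp <- setNames(sample(rep_len(seq_len(k), length(strains))), strains)
      unname(grp[strain])
    } else {
      sample(rep_len(seq_len(min(folds, n)), n))
    }
  })
}

#' Select the best regressor for one metabolite's derivative
#'
#' Scores every candidate in the search space by k-fold cross-validated
#' root-mean-squared error on the metabolite's derivative target, picks the
#' candidate with the lowest mean CV RMSE (ties broken by fewer pipeline
#' steps, then fewer hyperparameters, then declaration order) and refits it
#' on all training rows. Folds split rows by their (strain, time)
#' provenance, so no training example appears on both sides of a fold.
#'
#' @param train A [build_training_set()] table.
#' @param metabolite Metabolite name (without the `dmdt:` prefix).
#' @param space A [search_space()].
#' @return A `sub_model` list: `metabolite`, `candidate_id`, `cv_rmse`,
#'   fitted `model`, and the per-candidate `scores` tibble.
#' @export
select_model <- function(train, metabolite, space = default_search_space()) {
  X <- feature_matrix(train)
  ycol <- paste0("dmdt:", metabolite)
  if (!ycol %in% names(train)) {
    abort(paste0("No derivative target for metabolite '", metabolite, "'."),
          class = "pathdyn_schema_error")
  }
  y <- train[[ycol]]
  n <- nrow(X)
  n_strains <- length(unique(train$strain))
  k <- if (n_strains >= 2) min(space$folds, n_strains) else min(space$folds, n)
  if (k < space$folds) {
    inform(paste0("Reducing CV folds to ", k, " (", n_strains, " strain(s), ",
                  n, " rows)."))
  }
  ids <- fold_ids(train$strain, k, space$seed)
  scores <- map_dbl(space$candidates, function(cand) {
    se <- 0
    for (fold in seq_len(k)) {
      hold <- ids == fold
      fit <- cand$fit(X[!hold, , drop = FALSE], y[!hold], space$seed)
      pred <- cand$predict(fit, X[hold, , drop = FALSE])
      se <- se + sum((pred - y[hold])^2)
    }
    sqrt(se / n)
  })
  ord <- order(scores,
               map_dbl(space$candidates, "n_steps"),
               map_dbl(space$candidates, "n_hyper"),
               seq_along(space$candidates))
  best <- space$candidates[[ord[1]]]
  structure(
    list(metabolite = metabolite,
         candidate_id = best$id,
         candidate = best,
         cv_rmse = scores[ord[1]],
         model = best$fit(X, y, space$seed),
         scores = tibble(candidate = map_chr(space$candidates, "id"),
                         cv_rmse = scores)),
    class = "sub_model"
  )
}

#' Learn the metabolite vector field dm/dt = f(m, p)
#'
#' Solves the supervised dynamics-learning problem: for every metabolite,
#' [select_model()] picks and refits the regressor with the lowest
#' cross-validated RMSE mapping the concatenated metabolite and protein
#' concentrations to that metabolite's time derivative. The fitted
#' per-metabolite sub-models together form the learned vector field used by
#' [predict_trajectory()].
#'
#' @inheritParams select_model
#' @return A `dynamics_model` with one sub-model per metabolite; supports
#'   `predict()`, [tidy()] and [glance()].
#' @export
fit_dynamics <- function(train, space = default_search_space()) {
  mets <- sub("^dmdt:", "", target_cols(train))
  if (length(mets) == 0) {
    abort("Training set has no derivative targets.",
          class = "pathdyn_schema_error")
  }
  subs <- list()
  failures <- character()
  for (m in mets) {
    res <- tryCatch(select_model(train, m, space), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0(m, ": ", conditionMessage(res)))
    } else {
      subs[[m]] <- res
    }
  }
  if (length(failures) > 0) {
    abort(paste0("Model selection failed for: ",
                 paste(failures, collapse = "; ")),
          class = "pathdyn_fit_error")
  }
  Xtr <- feature_matrix(train)
  structure(
    list(sub_models = subs,
         metabolites = mets,
         proteins = sub("^prot:", "", grep("^prot:", names(train), value = TRUE)),
         feature_names = feature_cols(train),
         feature_max = apply(abs(Xtr), 2, max),
         state_max = apply(abs(Xtr[, grep("^met:", colnames(Xtr)),
                               drop = FALSE]), 2, max),
         seed = space$seed),
    class = "dynamics_model"
  )
}

#' @export
print.dynamics_model <- function(x, ...) {
  cat("<dynamics_model> ", length(x$sub_models), " per-metabolite regressors\n",
      sep = "")
  print(tidy(x))
  invisible(x)
}

#' @export
#' @rdname fit_dynamics
#' @param object,x A `dynamics_model`.
#' @param newdata Feature rows: a matrix or data frame containing the
#'   training feature columns (`met:`/`prot:`).
#' @param ... Unused.
predict.dynamics_model <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$feature_names, drop = FALSE])
  out <- vapply(object$metabolites, function(m) {
    sm <- object$sub_models[[m]]
    as.numeric(sm$candidate$predict(sm$model, X))
  }, numeric(nrow(X)))
  matrix(out, nrow = nrow(X), dimnames = list(NULL, object$metabolites))
}

#' @method tidy dynamics_model
#' @export
tidy.dynamics_model <- function(x, ...) {
  tibble(metabolite = x$metabolites,
         candidate = map_chr(x$sub_models, "candidate_id"),
         cv_rmse = map_dbl(x$sub_models, "cv_rmse"))
}

#' @method glance dynamics_model
#' @export
glance.dynamics_model <- function(x, ...) {
  tibble(n_metabolites = length(x$metabolites),
         mean_cv_rmse = mean(map_dbl(x$sub_models, "cv_rmse")),
         seed = x$seed)
}

#' Shuffle-split assessment of derivative predictions
#'
#' Repeatedly splits the training rows into random train/test subsets,
#' refits each metabolite's winning candidate on the training part and
#' reports the squared Pearson correlation between predicted and estimated
#' derivatives on both parts. This quantifies derivative-level accuracy,
#' which does not by itself bound trajectory-level accuracy (integration
#' compounds derivative errors).
#'
#' @param model A fitted `dynamics_model`.
#' @param data A [build_training_set()] table.
#' @param repeats Number of shuffle splits.
#' @param seed Integer seed.
#' @param test_fraction Fraction of rows held out per split.
#' @return A tibble with columns `metabolite`, `split`, `train_r2`,
#'   `test_r2`.
#' @export
assess_derivative_fit <- function(model, data, repeats = 10, seed = 1,
                                  test_fraction = 0.25) {
  stopifnot(repeats >= 1)
  X <- feature_matrix(data)
  n <- nrow(X)
  splits <- withr::with_seed(seed, {
    lapply(seq_len(repeats), function(i) {
      sample.int(n, size = max(1, round(test_fraction * n)))
    })
  })
  rows <- list()
  for (r in seq_len(repeats)) {
    hold <- splits[[r]]
    for (m in model$metabolites) {
      sm <- model$sub_models[[m]]
      y <- data[[paste0("dmdt:", m)]]
      fit <- sm$candidate$fit(X[-hold, , drop = FALSE], y[-hold], seed + r)
      r2 <- function(idx) {
        pred <- sm$candidate$predict(fit, X[idx, , drop = FALSE])
        if (sd(pred) < 1e-15 || sd(y[idx]) < 1e-15) return(NA_real_)
        cor(pred, y[idx])^2
      }
      rows[[length(rows) + 1]] <- tibble(
        metabolite = m, split = r,
        train_r2 = r2(setdiff(seq_len(n), hold)),
        test_r2 = r2(hold)
      )
    }
  }
  bind_rows(rows)
}
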