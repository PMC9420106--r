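# Concentration class labels used by the concentration tasks.
.CONC_CLASSES <- c("zero", "10uM", "100uM", "1mM", "10mM", "100mM")

conc_class <- function(c_mol) {
  lv <- c(1e-5, 1e-4, 1e-3, 1e-2, 1e-1)
  vapply(c_mol, function(ci) {
    if (is.na(ci) || ci == 0) return("zero")
    .CONC_CLASSES[1 + which.min(abs(log10(ci) - log10(lv)))]
  }, character(1))
}

# low/normal/high band per ion: low < 1 mM, normal 1-10 mM, high > 10 mM.
profile_band <- function(c_mol) {
  dplyr::case_when(c_mol < 1e-3 ~ "low",
                   c_mol <= 1e-2 ~ "normal",
                   TRUE ~ "high")
}

solution_labels <- function(solutions) {
  tbl <- solutions_table(solutions)
  wide <- tidyr::pivot_wider(tbl, id_cols = "solution",
                             names_from = "species",
                             values_from = "conc_mol_per_L",
                             values_fill = 0)
  for (ion in c("K", "Na", "Ca"))
    if (!ion %in% names(wide)) wide[[ion]] <- 0
  nz <- (wide$K > 0) + (wide$Na > 0) + (wide$Ca > 0)
  tibble::tibble(
    solution = wide$solution,
    ion = ifelse(nz == 1,
                 c("K", "Na", "Ca")[max.col(cbind(wide$K, wide$Na, wide$Ca))],
                 NA_character_),
    conc_K = wide$K, conc_Na = wide$Na, conc_Ca = wide$Ca,
    class_K = conc_class(wide$K), class_Na = conc_class(wide$Na),
    class_Ca = conc_class(wide$Ca),
    profile = paste0("K:", profile_band(wide$K),
                     "|Na:", profile_band(wide$Na),
                     "|Ca:", profile_band(wide$Ca))
  )
}

#' Assemble training samples from a multiplexed feature table
#'
#' Builds the electronic-tongue sample matrix: for each solution,
#' `n_triplets_per_solution` random device triplets are drawn (one device
#' from each ISM region, with replacement across triplets) and their
#' feature vectors concatenated, columns suffixed by the ISM label.
#' Gaussian noise with s.d. equal to `noise_frac` times the per-feature
#' s.d. (5% by default) is added to discourage overfitting. Features are
#' kept on their raw scale here; z-scoring happens inside [train_task()]
#' using training-split statistics only.
#'
#' @param features Feature tibble from [extract_features()] for the
#'   integrated chip (forward direction), covering every ISM region.
#' @param solutions The solution panel (list of [solution_spec()]) the
#'   features were measured in; supplies task labels.
#' @param n_triplets_per_solution Device triplets drawn per solution.
#' @param noise_frac Relative s.d. of the added feature noise.
#' @param feature_cols Feature columns to use; default is every numeric
#'   feature column.
#' @param seed Optional integer seed.
#' @return An `ion_samples` object: `features` (numeric tibble), `labels`
#'   (tibble aligned by row: `solution`, `ion`, per-ion concentration
#'   classes, `profile`), `feature_cols`, `isms`.
#' @export
build_samples <- function(features, solutions, n_triplets_per_solution = 200,
                          noise_frac = 0.05, feature_cols = NULL,
                          seed = NULL) {
  if ("working" %in% names(features))
    features <- dplyr::filter(features, .data$working)
  if ("direction" %in% names(features) &&
      "forward" %in% features$direction)
    features <- dplyr::filter(features, .data$direction == "forward")
  isms <- intersect(c("K", "Na", "Ca"), unique(features$ism))
  if (!length(isms)) abort("feature table has no ISM regions.")
  id_cols <- intersect(c("chip_id", "row", "col", "ism", "solution",
                         "direction", "working"), names(features))
  feature_cols <- feature_cols %||%
    names(features)[vapply(features, is.numeric, logical(1)) &
                      !names(features) %in% id_cols]
  lab_tbl <- solution_labels(solutions)
  sols <- intersect(unique(features$solution), lab_tbl$solution)
  if (!length(sols)) abort("features and solutions share no solution labels.")
  with_seed_or_not(seed, {
    per_sol <- lapply(sols, function(lab) {
      blocks <- lapply(isms, function(m) {
        pool <- features[features$ism == m & features$solution == lab,
                         feature_cols, drop = FALSE]
        if (!nrow(pool))
          abort(sprintf("ISM region '%s' has no working device for solution '%s'.",
                        m, lab))
        idx <- sample.int(nrow(pool), n_triplets_per_solution,
                          replace = TRUE)
        out <- pool[idx, , drop = FALSE]
        names(out) <- paste0(names(out), "_", m)
        out
      })
      x <- dplyr::bind_cols(blocks)
      x$solution <- lab
      x
    })
    x <- dplyr::bind_rows(per_sol)
    labels <- dplyr::left_join(tibble::tibble(solution = x$solution),
                               lab_tbl, by = "solution")
    x$solution <- NULL
    if (noise_frac > 0)
      for (j in seq_along(x)) {
        s <- sd(x[[j]])
        if (is.finite(s) && s > 0)
          x[[j]] <- x[[j]] + rnorm(nrow(x), sd = noise_frac * s)
      }
    structure(
      list(features = tibble::as_tibble(x), labels = labels,
           feature_cols = names(x), isms = isms,
           n_triplets = n_triplets_per_solution, noise_frac = noise_frac),
      class = "ion_samples"
    )
  })
}

#' @export
print.ion_samples <- function(x, ...) {
  cat(sprintf("<ion_samples> %d samples x %d features (%d solutions, ISMs: %s)\n",
              nrow(x$features), length(x$feature_cols),
              length(unique(x$labels$solution)),
              paste(x$isms, collapse = ", ")))
  invisible(x)
}

task_response <- function(samples, task) {
  lb <- samples$labels
  y <- switch(task,
    ion_type = lb$ion,
    conc_K = lb$class_K, conc_Na = lb$class_Na, conc_Ca = lb$class_Ca,
    profile = lb$profile,
    abort(paste0("unknown task '", task, "'.")))
  keep <- !is.na(y)
  if (task %in% c("conc_K", "conc_Na", "conc_Ca"))
    y <- factor(y, levels = intersect(.CONC_CLASSES, unique(y[keep])))
  list(y = factor(y[keep]), keep = keep)
}

# z-score columns by training statistics; zero-sd columns pass through.
zscore_fit <- function(x) {
  mu <- vapply(x, mean, numeric(1))
  sig <- vapply(x, sd, numeric(1))
  sig[!is.finite(sig) | sig == 0] <- 1
  list(mu = mu, sig = sig)
}
zscore_apply <- function(x, zs) {
  as.matrix(sweep(sweep(as.matrix(x), 2, zs$mu), 2, zs$sig, "/"))
}

# stratified train/test index split
stratified_split <- function(y, split_frac) {
  train <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    if (!length(idx)) next
    n_tr <- max(1L, floor(split_frac * length(idx)))
    train <- c(train, if (length(idx) == 1L) idx
               else sample(idx, n_tr))
  }
  sort(train)
}

#' Random-Forest configuration
#'
#' Default forest hyperparameters: 100 trees, maximum depth 20, Gini
#' impurity as the split criterion.
#'
#' @param trees,depth,criterion Forest hyperparameters.
#' @return Named list.
#' @export
rf_config <- function(trees = 100, depth = 20, criterion = "gini") {
  list(trees = trees, depth = depth, criterion = criterion)
}

fit_classifier <- function(method, x_train, y_train, config, seed) {
  switch(method,
    rf = ranger::ranger(
      x = x_train, y = y_train, num.trees = config$trees,
      max.depth = config$depth, splitrule = config$criterion,
      num.threads = 1, seed = seed %||% sample.int(1e6, 1)),
    svm = { requireNamespace("e1071"); e1071::svm(x_train, y_train) },
    knn = structure(list(x = x_train, y = y_train), class = "knn_ref"),
    lda = { requireNamespace("MASS")
            MASS::lda(x_train, grouping = y_train) },
    gp = { requireNamespace("kernlab")
           kernlab::gausspr(x_train, y_train) },
    abort(paste0("unknown method '", method, "'.")))
}

predict_classifier <- function(method, model, x_test) {
  switch(method,
    rf = predict(model, data = x_test, num.threads = 1)$predictions,
    svm = predict(model, x_test),
    knn = { requireNamespace("class")
            class::knn(model$x, x_test, model$y, k = 5) },
    lda = predict(model, x_test)$class,
    gp = kernlab::predict(model, x_test))
}

#' Train and evaluate a classification task
#'
#' Repeated stratified 80/20 train/test evaluation of a classifier
#' (Random Forest by default: 100 trees, depth 20, Gini impurity) on an
#' [build_samples()] sample matrix. Features are z-scored with
#' training-split statistics per repeat. Concentration tasks use the
#' classes zero, 10uM, 100uM, 1mM, 10mM, 100mM, where "zero" marks an
#' absent target ion.
#'
#' @param samples An `ion_samples` object.
#' @param task One of `"ion_type"`, `"conc_K"`, `"conc_Na"`, `"conc_Ca"`,
#'   `"profile"`.
#' @param n_repeats Independent split/train/test repeats.
#' @param split_frac Training fraction of each class.
#' @param config Forest hyperparameters, see [rf_config()].
#' @param method Classifier backend: `"rf"` (default), `"svm"`, `"knn"`,
#'   `"lda"` or `"gp"`.
#' @param seed Optional integer seed.
#' @return An `ion_task` report: per-repeat accuracies with mean, s.d. and
#'   95% CI, and the summed test confusion matrix.
#' @export
train_task <- function(samples, task = "ion_type", n_repeats = 5,
                       split_frac = 0.8, config = rf_config(),
                       method = "rf", seed = NULL) {
  tr <- task_response(samples, task)
  x <- samples$features[tr$keep, , drop = FALSE]
  y <- tr$y
  if (nlevels(y) < 2) abort("task needs at least 2 classes.")
  with_seed_or_not(seed, {
    acc <- numeric(n_repeats)
    conf <- matrix(0L, nlevels(y), nlevels(y),
                   dimnames = list(truth = levels(y), pred = levels(y)))
    for (r in seq_len(n_repeats)) {
      tr_idx <- stratified_split(y, split_frac)
      te_idx <- setdiff(seq_along(y), tr_idx)
      if (!length(te_idx)) abort("empty test split; reduce `split_frac`.")
      if (nlevels(droplevels(y[tr_idx])) < nlevels(y))
        abort("a class is absent from the training split.")
      zs <- zscore_fit(x[tr_idx, , drop = FALSE])
      x_tr <- zscore_apply(x[tr_idx, , drop = FALSE], zs)
      x_te <- zscore_apply(x[te_idx, , drop = FALSE], zs)
      model <- fit_classifier(method, x_tr, y[tr_idx], config,
                              seed = sample.int(1e6, 1))
      pred <- predict_classifier(method, model, x_te)
      pred <- factor(as.character(pred), levels = levels(y))
      acc[r] <- mean(pred == y[te_idx])
      conf <- conf + unclass(table(y[te_idx], pred))
    }
    m <- mean(acc); s <- sd(acc)
    ci <- if (n_repeats > 1)
      m + qt(c(0.025, 0.975), n_repeats - 1) * s / sqrt(n_repeats)
    else c(NA_real_, NA_real_)
    structure(
      list(task = task, method = method, config = config,
           accuracies = acc, accuracy_mean = m, accuracy_sd = s,
           ci = ci, confusion = conf, classes = levels(y),
           n_samples = length(y), n_repeats = n_repeats,
           split_frac = split_frac),
      class = "ion_task"
    )
  })
}

#' @export
print.ion_task <- function(x, ...) {
  cat(sprintf("<ion_task> %s (%s): accuracy %.3f +/- %.3f (95%% CI %.3f-%.3f, %d repeats, %d samples, %d classes)\n",
              x$task, x$method, x$accuracy_mean, x$accuracy_sd,
              x$ci[1], x$ci[2], x$n_repeats, x$n_samples,
              length(x$classes)))
  invisible(x)
}

#' Principal-component summary of multiplexed responses
#'
#' Centered (unscaled) PCA of a sample-by-feature matrix, typically Dirac
#' points of device triplets across the pure-solution panel. Returns the
#' variance fraction per component and the scores for plotting.
#'
#' @param x Numeric data frame or matrix (>= 3 rows, >= 2 columns).
#' @param labels Optional per-row grouping labels carried into the scores.
#' @return An `ion_pca` object: `variance_fraction`, `scores` (tibble),
#'   `rotation`.
#' @export
pca_report <- function(x, labels = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 3 || ncol(x) < 2) abort("need >= 3 samples and >= 2 features.")
  const <- apply(x, 2, sd) == 0
  if (any(const))
    warning(sprintf("%d constant feature(s); PCA rank reduced.", sum(const)))
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- tibble::as_tibble(pc$x)
  if (!is.null(labels)) scores$label <- labels
  structure(list(variance_fraction = vf, scores = scores,
                 rotation = pc$rotation),
            class = "ion_pca")
}

#' @export
print.ion_pca <- function(x, ...) {
  cat(sprintf("<ion_pca> first two components explain %.1f%% of variance (PC1 %.1f%%, PC2 %.1f%%)\n",
              100 * sum(x$variance_fraction[1:2]),
              100 * x$variance_fraction[1], 100 * x$variance_fraction[2]))
  invisible(x)
}

#' SHAP feature attributions for a task
#'
#' Tree-ensemble Shapley attributions computed with the TreeSHAP
#' explainer built into xgboost (`predcontrib = TRUE`), which satisfies
#' the Shapley local-accuracy identity: per-sample attributions (plus the
#' base value) sum to the model's margin prediction. Because TreeSHAP
#' requires the per-node covers a ranger forest does not retain, the
#' explained model is an xgboost tree ensemble in random-forest mode
#' (one round of `trees` parallel trees of depth `depth`, 0.632
#' subsampling) fit to the same samples; ranking stability against the
#' ranger task model is exercised in the test suite.
#'
#' @param samples An `ion_samples` object.
#' @param task Task name, see [train_task()].
#' @param model Optional pre-trained `xgb.Booster` to explain instead;
#'   non-tree models are unsupported.
#' @param config Forest hyperparameters, see [rf_config()].
#' @param seed Optional integer seed.
#' @return An `ion_importance` object: `importance` (tibble of `feature`,
#'   `mean_abs_shap`, ranked), `shap` (per-sample attribution array),
#'   `local_accuracy_dev` (max |sum(attributions) - margin|), `model`.
#' @export
importance_report <- function(samples, task = "ion_type", model = NULL,
                              config = rf_config(), seed = NULL) {
  tr <- task_response(samples, task)
  x <- samples$features[tr$keep, , drop = FALSE]
  y <- tr$y
  zs <- zscore_fit(x)
  xm <- zscore_apply(x, zs)
  if (!is.null(model) && !inherits(model, "xgb.Booster"))
    abort("only tree-ensemble (xgb.Booster) models are supported.")
  n_class <- nlevels(y)
  if (is.null(model)) {
    params <- list(
      max_depth = config$depth, eta = 1, subsample = 0.632,
      colsample_bynode = 0.7, num_parallel_tree = config$trees,
      nthread = 1)
    if (n_class > 2) {
      params$objective <- "multi:softprob"; params$num_class <- n_class
      label <- as.integer(y) - 1L
    } else {
      params$objective <- "binary:logistic"
      label <- as.integer(y) - 1L
    }
    model <- with_seed_or_not(seed, {
      params$seed <- sample.int(1e6, 1)
      xgboost::xgb.train(params = params,
                         data = xgboost::xgb.DMatrix(xm, label = label),
                         nrounds = 1, verbose = 0)
    })
  }
  dm <- xgboost::xgb.DMatrix(xm)
  contrib <- predict(model, dm, predcontrib = TRUE)
  margin <- predict(model, dm, outputmargin = TRUE)
  if (length(dim(contrib)) == 3) {
    dev <- max(abs(apply(contrib, c(1, 2), sum) - margin))
    feat_contrib <- contrib[, , seq_len(ncol(xm)), drop = FALSE]
    mean_abs <- apply(abs(feat_contrib), 3, mean)
  } else {
    dev <- max(abs(rowSums(contrib) - margin))
    feat_contrib <- contrib[, seq_len(ncol(xm)), drop = FALSE]
    mean_abs <- colMeans(abs(feat_contrib))
  }
  imp <- tibble::tibble(feature = colnames(xm),
                        mean_abs_shap = unname(mean_abs)) |>
    dplyr::arrange(dplyr::desc(.data$mean_abs_shap)) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(
    list(task = task, importance = imp, shap = contrib,
         local_accuracy_dev = dev, model = model, x = xm,
         classes = levels(y)),
    class = "ion_importance"
  )
}

#' @export
print.ion_importance <- function(x, ...) {
  cat(sprintf("<ion_importance> %s: top features by mean |SHAP| (local-accuracy dev %.2g)\n",
              x$task, x$local_accuracy_dev))
  print(head(x$importance, 4))
  invisible(x)
}

#' ISM ablation study
#'
#' Retrains a task with each ISM region's feature columns removed and
#' reports the accuracy drop relative to the full model, quantifying how
#' much each membrane contributes to the task.
#'
#' @inheritParams train_task
#' @return Tibble with `ism_removed`, `accuracy`, `accuracy_full`, `drop`.
#' @export
ablation_study <- function(samples, task = "ion_type", n_repeats = 5,
                           config = rf_config(), seed = NULL) {
  full <- train_task(samples, task, n_repeats = n_repeats, config = config,
                     seed = child_seed(seed, 0))
  rows <- purrr::imap(samples$isms, function(m, k) {
    drop_cols <- grepl(paste0("_", m, "$"), samples$feature_cols)
    if (all(drop_cols)) abort("removing this ISM leaves no features.")
    sub <- samples
    sub$features <- samples$features[, !drop_cols, drop = FALSE]
    sub$feature_cols <- samples$feature_cols[!drop_cols]
    res <- train_task(sub, task, n_repeats = n_repeats, config = config,
                      seed = child_seed(seed, k))
    tibble::tibble(ism_removed = m, accuracy = res$accuracy_mean,
                   accuracy_full = full$accuracy_mean,
                   drop = full$accuracy_mean - res$accuracy_mean)
  })
  dplyr::bind_rows(rows)
}

#' Device-subsampling study
#'
#' Evaluates how task accuracy depends on the size of the device pool,
#' emulating smaller sensor arrays (defaults follow the 1, 1/2, 1/4, 1/8
#' ladder). Because every triplet sample reuses measured per-device
#' feature vectors, a split over samples lets a forest recognize the
#' device combinations of a small pool rather than the analyte signal;
#' this study therefore scores generalization across devices: within each
#' restricted pool the devices are split 80/20, training triplets are
#' drawn from the training devices only and test triplets from the
#' held-out devices only. Redundancy then shows up directly -- a larger
#' pool covers the device-variation manifold better and transfers better
#' to unseen devices.
#'
#' @param features Feature tibble from [extract_features()].
#' @param solutions The solution panel the features were measured in.
#' @param fractions Device-pool fractions to evaluate.
#' @param task,config As in [train_task()].
#' @param n_repeats Independent device splits per fraction.
#' @param holdout_frac Fraction of the pool held out for testing.
#' @param n_triplets_per_solution,noise_frac As in [build_samples()]
#'   (training set).
#' @param n_test_triplets Test triplets per solution from held-out
#'   devices.
#' @param seed Optional integer seed.
#' @return Tibble with `fraction`, `n_devices`, `accuracy_mean`,
#'   `accuracy_sd`.
#' @export
subsample_study <- function(features, solutions,
                            fractions = c(1, 1/2, 1/4, 1/8),
                            task = "ion_type", n_repeats = 5,
                            holdout_frac = 0.2,
                            n_triplets_per_solution = 200,
                            n_test_triplets = 50,
                            noise_frac = 0.05, config = rf_config(),
                            seed = NULL) {
  if ("working" %in% names(features))
    features <- dplyr::filter(features, .data$working)
  pool <- dplyr::distinct(features, .data$row, .data$col, .data$ism)
  rows <- purrr::imap(fractions, function(f, k) {
    sel <- with_seed_or_not(child_seed(seed, k), {
      pool |>
        dplyr::group_by(.data$ism) |>
        dplyr::group_modify(function(g, key) {
          n_keep <- round(f * nrow(g))
          if (n_keep < 2)
            abort(sprintf("fraction %.3g empties the '%s' region.",
                          f, key$ism))
          g[sample.int(nrow(g), n_keep), , drop = FALSE]
        }) |>
        dplyr::ungroup()
    })
    feats <- dplyr::semi_join(features, sel, by = c("row", "col", "ism"))
    acc <- with_seed_or_not(child_seed(seed, 100 + k), {
      vapply(seq_len(n_repeats), function(r) {
        te_dev <- sel |>
          dplyr::group_by(.data$ism) |>
          dplyr::group_modify(function(g, key) {
            n_te <- max(1L, round(holdout_frac * nrow(g)))
            g[sample.int(nrow(g), n_te), , drop = FALSE]
          }) |>
          dplyr::ungroup()
        tr_dev <- dplyr::anti_join(sel, te_dev,
                                   by = c("row", "col", "ism"))
        s_tr <- build_samples(
          dplyr::semi_join(feats, tr_dev, by = c("row", "col", "ism")),
          solutions, n_triplets_per_solution, noise_frac)
        s_te <- build_samples(
          dplyr::semi_join(feats, te_dev, by = c("row", "col", "ism")),
          solutions, n_test_triplets, noise_frac)
        y_tr <- task_response(s_tr, task)
        y_te <- task_response(s_te, task)
        zs <- zscore_fit(s_tr$features[y_tr$keep, , drop = FALSE])
        x_tr <- zscore_apply(s_tr$features[y_tr$keep, , drop = FALSE], zs)
        x_te <- zscore_apply(
          s_te$features[y_te$keep, s_tr$feature_cols, drop = FALSE], zs)
        model <- fit_classifier("rf", x_tr, y_tr$y, config,
                                seed = sample.int(1e6, 1))
        pred <- predict_classifier("rf", model, x_te)
        mean(as.character(pred) == as.character(y_te$y))
      }, numeric(1))
    })
    tibble::tibble(fraction = f, n_devices = nrow(sel),
                   accuracy_mean = mean(acc), accuracy_sd = sd(acc))
  })
  dplyr::bind_rows(rows)
}
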