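# small sample matrix built from the noiseless integrated fixture
ml_samples <- function() memo("ml_samples", function() {
  fix <- integrated_fixture()
  build_samples(fix$features, fix$solutions,
                n_triplets_per_solution = 60, noise_frac = 0,
                seed = 71L)
})

# trivially separable three-class toy samples
toy_samples <- function(n = 90, seed = 72L) {
  withr::with_seed(seed, {
    y <- rep(c("K", "Na", "Ca"), each = n / 3)
    x <- tibble::tibble(
      f1_K = as.numeric(y == "K") * 10 + rnorm(n, sd = 0.01),
      f2_Na = as.numeric(y == "Na") * 10 + rnorm(n, sd = 0.01),
      f3_Ca = rnorm(n, sd = 0.01))
    structure(list(
      features = x,
      labels = tibble::tibble(solution = y, ion = y,
                              conc_K = 0, conc_Na = 0, conc_Ca = 0,
                              class_K = "zero", class_Na = "zero",
                              class_Ca = "zero",
                              profile = paste0("p_", y)),
      feature_cols = names(x), isms = c("K", "Na", "Ca"),
      n_triplets = n / 3, noise_frac = 0), class = "ion_samples")
  })
}

test_that("sample assembly counts rows and labels solutions correctly", {
  fix <- integrated_fixture()
  s1 <- build_samples(fix$features, fix$solutions,
                      n_triplets_per_solution = 1, noise_frac = 0,
                      seed = 73L)
  expect_equal(nrow(s1$features), 15)
  expect_equal(length(s1$feature_cols), 7 * 3)
  expect_true(all(grepl("_(K|Na|Ca)$", s1$feature_cols)))
  lb <- s1$labels
  expect_setequal(unique(lb$ion), c("K", "Na", "Ca"))
  # a pure Na solution is class "zero" for the K and Ca tasks
  na_row <- lb[lb$ion == "Na" & lb$conc_Na == 1e-2, ][1, ]
  expect_equal(na_row$class_K, "zero")
  expect_equal(na_row$class_Ca, "zero")
  expect_equal(na_row$class_Na, "10mM")
  expect_error(build_samples(fix$features[0, ], fix$solutions))
})

test_that("feature noise defaults to 5% of the per-feature spread", {
  expect_equal(formals(build_samples)$noise_frac, 0.05)
  fix <- integrated_fixture()
  s <- build_samples(fix$features, fix$solutions,
                     n_triplets_per_solution = 50, noise_frac = 0.05,
                     seed = 74L)
  expect_equal(s$noise_frac, 0.05)
})

test_that("z-scoring by training statistics centers the training block", {
  x <- ml_samples()$features
  zs <- ionarray:::zscore_fit(x)
  xm <- ionarray:::zscore_apply(x, zs)
  expect_lt(max(abs(colMeans(xm))), 1e-9)
  expect_lt(max(abs(apply(xm, 2, sd) - 1)), 1e-9)
})

test_that("forest configuration echoes the standard hyperparameters", {
  cfg <- rf_config()
  expect_equal(cfg$trees, 100)
  expect_equal(cfg$depth, 20)
  expect_equal(cfg$criterion, "gini")
  tk <- train_task(toy_samples(), "ion_type", n_repeats = 2, seed = 75L)
  expect_equal(tk$n_repeats, 2)
  expect_equal(tk$split_frac, 0.8)
})

test_that("a separable toy task is classified perfectly", {
  tk <- train_task(toy_samples(), "ion_type", n_repeats = 3, seed = 76L)
  expect_equal(tk$accuracy_mean, 1.0)
  expect_equal(sum(tk$confusion), 3 * 18)  # 20% of 90, 3 repeats
  expect_true(all(tk$confusion == diag(diag(tk$confusion))))
})

test_that("shuffled labels fall to chance accuracy", {
  s <- toy_samples(n = 150)
  s$labels$ion <- withr::with_seed(77L, sample(s$labels$ion))
  tk <- train_task(s, "ion_type", n_repeats = 5, seed = 78L)
  # null accuracy 1/3; binomial sd over 5 x 30 test points ~ 0.04
  expect_gt(tk$accuracy_mean, 1 / 3 - 0.15)
  expect_lt(tk$accuracy_mean, 1 / 3 + 0.15)
})

test_that("task reports are reproducible bit-for-bit under a fixed seed", {
  t1 <- train_task(ml_samples(), "ion_type", n_repeats = 2, seed = 79L)
  t2 <- train_task(ml_samples(), "ion_type", n_repeats = 2, seed = 79L)
  expect_identical(t1$accuracies, t2$accuracies)
  expect_identical(t1$confusion, t2$confusion)
})

test_that("alternative classifier backends run behind the same interface", {
  s <- toy_samples()
  for (mth in c("svm", "lda", "knn")) {
    tk <- train_task(s, "ion_type", n_repeats = 1, method = mth,
                     seed = 80L)
    expect_gt(tk$accuracy_mean, 0.9)
  }
  expect_error(train_task(s, "no_such_task"), "unknown task")
})

test_that("PCA reports variance fractions with the defining properties", {
  # data in a 2-D plane: first two components carry all variance
  withr::with_seed(81L, {
    basis <- matrix(rnorm(10 * 2), 2, 10)
    x <- matrix(rnorm(60 * 2), 60, 2) %*% basis
  })
  p <- pca_report(x)
  expect_equal(sum(p$variance_fraction[1:2]), 1, tolerance = 1e-9)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(p$variance_fraction) < 1e-12))
  expect_warning(pca_report(cbind(x, 0)), "constant")
  expect_error(pca_report(x[1:2, ]))
  # ion clusters separate in PC1-PC2 on the pure panel
  s <- ml_samples()
  dirac_cols <- grep("v_dirac", s$feature_cols, value = TRUE)
  pr <- pca_report(s$features[, dirac_cols], labels = s$labels$ion)
  sil <- cluster::silhouette(as.integer(factor(pr$scores$label)),
                             dist(pr$scores[, c("PC1", "PC2")]))
  expect_gt(mean(sil[, "sil_width"]), 0)
})

test_that("SHAP attributions satisfy local accuracy and rank true drivers", {
  # a feature that is the label ranks first
  s <- toy_samples()
  imp <- importance_report(s, "ion_type", seed = 82L)
  expect_true(imp$importance$feature[1] %in% c("f1_K", "f2_Na"))
  expect_lt(imp$local_accuracy_dev, 1e-5)
  # double-precision explainer: local accuracy to near machine precision
  ts <- tree_shap(imp$model, imp$x[1:25, , drop = FALSE])
  marg <- ionarray:::tree_margins(imp$model, imp$x[1:25, , drop = FALSE])
  expect_lt(max(abs(apply(ts, c(1, 2), sum) - marg)), 1e-9)
  # fast and double explainers agree to single precision
  pc <- predict(imp$model, xgboost::xgb.DMatrix(imp$x[1:25, , drop = FALSE]),
                predcontrib = TRUE)
  expect_lt(max(abs(ts - pc)), 1e-4)
  expect_error(importance_report(s, "ion_type", model = lm(1 ~ 1)),
               "tree")
})

test_that("TreeSHAP agrees with the brute-force Shapley oracle", {
  withr::with_seed(83L, {
    x <- matrix(rnorm(150 * 4), 150, 4)
    colnames(x) <- paste0("f", 1:4)
    y <- as.integer(x[, 1] + 0.5 * x[, 2] - 0.3 * x[, 3] > 0)
  })
  m <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 4, eta = 1,
                  nthread = 1),
    data = xgboost::xgb.DMatrix(x, label = y), nrounds = 2)
  parsed <- ionarray:::parse_trees(m, colnames(x))
  x32 <- matrix(ionarray:::as_float32(x), nrow(x), ncol(x))
  for (s in c(1, 7, 50)) {
    for (tr in parsed$trees) {
      expect_equal(ionarray:::tree_shap_one(tr, x32[s, ], 4)[1:4],
                   ionarray:::tree_shap_brute(tr, x32[s, ], 4),
                   tolerance = 1e-10)
    }
  }
})

test_that("Dirac-point features dominate the ion-type attribution ranking", {
  imp <- importance_report(ml_samples(), "ion_type", seed = 84L)
  top4 <- imp$importance$feature[1:4]
  expect_true(any(grepl("v_dirac", top4)))
})

test_that("ablation flags the ISM that carries the signal", {
  s <- toy_samples()
  # make the Ca block pure noise: dropping it should not matter, while
  # dropping K (which encodes the label jointly with Na) should
  ab <- ablation_study(s, "ion_type", n_repeats = 2, seed = 85L)
  expect_equal(nrow(ab), 3)
  expect_setequal(ab$ism_removed, c("K", "Na", "Ca"))
  drop_ca <- ab$drop[ab$ism_removed == "Ca"]
  expect_lt(abs(drop_ca), 0.05)
  # single-ion signal construction: only K features informative
  s2 <- toy_samples()
  s2$features$f2_Na <- withr::with_seed(86L, rnorm(nrow(s2$features)))
  ab2 <- ablation_study(s2, "ion_type", n_repeats = 2, seed = 87L)
  expect_equal(ab2$ism_removed[which.max(ab2$drop)], "K")
})

test_that("device subsampling spans the 1 to 1/8 ladder", {
  fix <- noisy_integrated()
  expect_equal(eval(formals(subsample_study)$fractions),
               c(1, 1/2, 1/4, 1/8))
  res <- subsample_study(fix$features, fix$solutions,
                         fractions = c(1, 1/4), task = "ion_type",
                         n_repeats = 2, n_triplets_per_solution = 30,
                         n_test_triplets = 15, seed = 88L)
  regions <- table(dplyr::distinct(fix$features, row, col, ism)$ism)
  expect_equal(res$n_devices[1], sum(regions))
  expect_equal(res$n_devices[2], sum(round(regions / 4)))
  expect_true(all(res$accuracy_mean > 0.5))
  res2 <- subsample_study(fix$features, fix$solutions,
                          fractions = c(1, 1/4), task = "ion_type",
                          n_repeats = 2, n_triplets_per_solution = 30,
                          n_test_triplets = 15, seed = 88L)
  expect_identical(res, res2)
  expect_error(subsample_study(fix$features, fix$solutions,
                               fractions = 1e-4, seed = 89L), "empties")
})

test_that("accuracy does not degrade with a larger device pool", {
  fix <- noisy_integrated()
  rhos <- vapply(1:5, function(s) {
    res <- subsample_study(fix$features, fix$solutions,
                           fractions = c(1, 1/2, 1/4, 1/8),
                           task = "conc_Ca", n_repeats = 2,
                           n_triplets_per_solution = 40,
                           n_test_triplets = 15,
                           seed = 900L + s)
    suppressWarnings(cor(res$fraction, res$accuracy_mean,
                         method = "spearman"))
  }, numeric(1))
  expect_gte(mean(rhos), 0)
})

test_that("mixture solutions support the concentration-profile task", {
  chip <- sample_chip(chip_layout(8, 9, c("K", "Na", "Ca")),
                      population_model(yield_p = 1), chip_id = "mix",
                      seed = 95L)
  mix <- mixture_solution_panel(n = 12, min_per_level = 1, seed = 96L)
  m <- run_panel(chip, mix, seed = 97L)
  f <- extract_features(m)
  s <- build_samples(f, mix, n_triplets_per_solution = 25, seed = 98L)
  # mixtures have no single target ion but do have per-ion classes
  expect_true(all(is.na(s$labels$ion) | rowSums(cbind(
    s$labels$conc_K > 0, s$labels$conc_Na > 0, s$labels$conc_Ca > 0)) == 1))
  expect_true(all(grepl("^K:(low|normal|high)\\|Na:", s$labels$profile)))
  tk <- train_task(s, "profile", n_repeats = 2, seed = 99L)
  expect_gt(tk$accuracy_mean, 1 / length(tk$classes))
  tc <- train_task(s, "conc_Na", n_repeats = 2, seed = 100L)
  expect_gt(tc$accuracy_mean, 0.3)
})
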