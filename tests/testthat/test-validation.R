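test_that("per-fold propensity refit equals fitting on the n-1 training samples", {
  set.seed(21)
  ds <- random_dataset(n_pos = 8, n_neg = 8, xi = 4)
  recipe <- feature_recipe(c("PSNP", "PSDP"))
  state <- pseudoU:::jackknife_state(ds, recipe)
  full <- fit_recipe_matrices(ds, recipe)
  for (k in c(1, 5, 16)) {
    fold <- pseudoU:::fold_matrices(state, recipe, ds$xi, k)
    refit <- fit_recipe_matrices(subset_dataset_for_test(ds, -k), recipe)
    expect_equal(fold$PSNP$Z, refit$PSNP$Z)
    expect_equal(fold$PSDP$Z, refit$PSDP$Z)
    # leakage sentinel: the fold matrix must differ from the full-data matrix
    expect_false(isTRUE(all.equal(fold$PSNP$Z, full$PSNP$Z)))
    expect_false(isTRUE(all.equal(fold$PSDP$Z, full$PSDP$Z)))
  }
})

test_that("jackknife verdicts match an independent leave-one-out oracle", {
  # For a recipe without propensity features the per-fold encodings equal the
  # global ones, so a plain LOO over e1071 is an exact oracle.
  set.seed(22)
  cfg <- synthetic_config(xi = 4, n_pos = 15, n_neg = 15, bias_strength = 0.7,
                          biased_positions = c(3, 7), seed = 3)
  ds <- generate_synthetic(cfg)
  svm <- svm_config(cost = 2, kernel_scale = 1)
  res <- jackknife(ds, feature_recipe("DC"), svm)

  X <- t(vapply(ds$segments, function(s) unname(encode_dc(s)), numeric(16)))
  oracle_scores <- vapply(seq_len(nrow(X)), function(i) {
    fit <- e1071::svm(x = X[-i, ], y = factor(ds$labels[-i], c("neg", "pos")),
                      scale = FALSE, kernel = "radial", cost = 2, gamma = 1,
                      tolerance = 1e-3)
    pr <- predict(fit, X[i, , drop = FALSE], decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    if (startsWith(colnames(dv)[1], "pos")) dv[1] else -dv[1]
  }, numeric(1))
  expect_equal(res$scores, unname(oracle_scores), tolerance = 1e-8)
})

test_that("jackknife counts are invariant to sample order", {
  cfg <- synthetic_config(xi = 4, n_pos = 10, n_neg = 10, bias_strength = 0.6,
                          biased_positions = c(2, 8), seed = 9)
  ds <- generate_synthetic(cfg)
  recipe <- feature_recipe("PSNP")
  svm <- svm_config(cost = 1, kernel_scale = 2)
  res <- jackknife(ds, recipe, svm)
  set.seed(30)
  perm <- sample(length(ds$segments))
  dsp <- psi_dataset(ds$segments[perm], ds$labels[perm], ds$xi)
  resp <- jackknife(dsp, recipe, svm)
  # solver working-set order perturbs scores at ~1e-4; verdicts must agree
  expect_equal(resp$scores, res$scores[perm], tolerance = 1e-2)
  expect_equal(resp$predicted, res$predicted[perm])
  expect_equal(unclass(resp$metrics$counts), unclass(res$metrics$counts))
})

test_that("jackknife separates a strongly planted signal and not a null one", {
  sep <- generate_synthetic(synthetic_config(xi = 6, n_pos = 30, n_neg = 30,
                                             bias_strength = 1,
                                             biased_positions = c(4, 5, 9, 10),
                                             seed = 17))
  res <- jackknife(sep, feature_recipe("PSNP"), svm_config(cost = 4, kernel_scale = 2))
  expect_gte(res$metrics$acc, 0.9)

  null <- generate_synthetic(synthetic_config(xi = 6, n_pos = 50, n_neg = 50,
                                              bias_strength = 0, seed = 18))
  res0 <- jackknife(null, feature_recipe("PSNP"), svm_config(cost = 4, kernel_scale = 2))
  expect_gte(res0$metrics$acc, 0.35)
  expect_lte(res0$metrics$acc, 0.65)
})

test_that("jackknife refuses degenerate datasets", {
  tiny <- psi_dataset(c("AUA", "GUC", "CUC"), c("pos", "neg", "neg"), xi = 1)
  expect_error(jackknife(tiny, feature_recipe("NC")), ">= 2 samples per class")
})

test_that("independent evaluation fits once on train and scores test", {
  motif <- c("G", "C", "A")
  cfg <- synthetic_config(xi = 5, n_pos = 40, n_neg = 40, bias_strength = 1,
                          biased_positions = c(3, 4, 8), seed = 41,
                          planted_nucleotides = motif)
  train <- generate_synthetic(cfg)
  test <- generate_synthetic(synthetic_config(xi = 5, n_pos = 25, n_neg = 25,
                                              bias_strength = 1,
                                              biased_positions = c(3, 4, 8),
                                              seed = 41 + 1000,
                                              planted_nucleotides = motif),
                             name = "fresh")
  recipe <- feature_recipe(c("PSNP", "DC"))
  svm <- svm_config(cost = 4, kernel_scale = 2)
  res <- evaluate_independent(train, test, recipe, svm)
  expect_gte(res$metrics$acc, 0.9)

  # resubstitution is at least as optimistic as the jackknife here
  resub <- suppressWarnings(evaluate_independent(train, train, recipe, svm))
  jk <- jackknife(train, recipe, svm)
  expect_gte(resub$metrics$acc, jk$metrics$acc)
  expect_warning(evaluate_independent(train, train, recipe, svm), "both train and test")

  other_xi <- generate_synthetic(synthetic_config(xi = 4, seed = 1))
  expect_error(evaluate_independent(train, other_xi, recipe, svm), "xi mismatch")
})

test_that("grid search is an argmax over jackknife cells with stable ties", {
  cfg <- synthetic_config(xi = 4, n_pos = 12, n_neg = 12, bias_strength = 0.8,
                          biased_positions = c(2, 7), seed = 55)
  ds <- generate_synthetic(cfg)
  recipe <- feature_recipe("PSNP")

  one <- default_grid(kernel_scale = 2, cost = 8)
  gs1 <- grid_search(ds, recipe, one)
  expect_equal(gs1$best$cost, 8)
  expect_equal(gs1$best$kernel_scale, 2)
  jk <- jackknife(ds, recipe, svm_config(cost = 8, kernel_scale = 2))
  expect_equal(gs1$best_result$metrics$mcc, jk$metrics$mcc)

  grid <- default_grid(kernel_scale = c(0.5, 2, 8), cost = c(1, 16))
  gs <- grid_search(ds, recipe, grid, criterion = "Acc")
  expect_equal(nrow(gs$table), 6L)
  expect_true(all(gs$best_result$metrics$acc >= gs$table$Acc))

  # the default grid spans the extremes seen in published optima
  dflt <- default_grid()
  expect_true(all(c(0.25, 2) %in% dflt$kernel_scale))
  expect_true(all(c(0.03125, 8, 1024) %in% dflt$cost))
  expect_true(1024 %in% dflt$kernel_scale)
  expect_error(default_grid(cost = -1), "positive")
})
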