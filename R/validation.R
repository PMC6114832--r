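#' RBF-SVM hyperparameter configuration
#'
#' The radial kernel is parameterized by a kernel scale s, with
#' `K(x, y) = exp(-||x - y||^2 / s^2)`. Libraries parameterized by gamma use
#' `gamma = 1 / s^2`; the conversion is applied internally when fitting.
#'
#' @param cost Box constraint c (> 0).
#' @param kernel_scale Kernel scale s (> 0).
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(cost = 1, kernel_scale = 1) {
  if (!is.numeric(cost) || cost <= 0) stop("cost must be > 0", call. = FALSE)
  if (!is.numeric(kernel_scale) || kernel_scale <= 0) {
    stop("kernel_scale must be > 0", call. = FALSE)
  }
  structure(list(cost = cost, kernel_scale = kernel_scale,
                 kernel = "radial"), class = "svm_config")
}

#' @export
print.svm_config <- function(x, ...) {
  cat(sprintf("<svm_config> RBF, box constraint c = %g, kernel scale s = %g (gamma = %g)\n",
              x$cost, x$kernel_scale, 1 / x$kernel_scale^2))
  invisible(x)
}

# Fit an RBF SVM on an encoded feature matrix. No feature scaling: the
# encoders already emit bounded values, and silent rescaling would detach
# results from the reported hyperparameters.
#' @importFrom e1071 svm
#' @importFrom stats predict
fit_rbf_svm <- function(x, labels, config) {
  y <- factor(labels, levels = c("neg", "pos"))
  if (nlevels(droplevels(y)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  e1071::svm(x = x, y = y, scale = FALSE, kernel = "radial",
             cost = config$cost, gamma = 1 / config$kernel_scale^2,
             tolerance = 1e-3, cachesize = 100)
}

# Decision scores oriented so that positive score means the positive class.
# libsvm's decision value sign follows internal label order, exposed in the
# decision-value column name ("pos/neg" or "neg/pos").
svm_scores <- function(model, x) {
  pr <- stats::predict(model, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  if (startsWith(colnames(dv)[1], "pos")) as.vector(dv) else -as.vector(dv)
}

#' Candidate grid for SVM hyperparameter search
#'
#' Defaults span powers of two: kernel scale from 2^-3 to 2^10 and box
#' constraint from 2^-5 to 2^10, wide enough to contain every optimum the
#' benchmark tables report (including 0.03125 and 1024).
#'
#' @param kernel_scale,cost Positive numeric candidate vectors.
#' @return An object of class `grid_spec`.
#' @export
default_grid <- function(kernel_scale = 2^(-3:10), cost = 2^(-5:10)) {
  if (length(kernel_scale) == 0L || length(cost) == 0L ||
      any(kernel_scale <= 0) || any(cost <= 0)) {
    stop("grid values must be nonempty and positive", call. = FALSE)
  }
  structure(list(kernel_scale = kernel_scale, cost = cost),
            class = "grid_spec")
}

# Per-fold propensity refit via count downdating: subtracting the held-out
# sample's one-hot counts from its class's totals is exactly a refit on the
# n - 1 training samples.
jackknife_state <- function(dataset, recipe) {
  nuc <- seg_nuc_idx(dataset$segments)
  state <- list(nuc = nuc, pos = dataset$labels == "pos")
  if ("PSDP" %in% recipe$features) state$din <- seg_dinuc_idx(nuc)
  for (kind in intersect(c("PSNP", "PSDP"), recipe$features)) {
    idx <- if (kind == "PSNP") state$nuc else state$din
    K <- if (kind == "PSNP") 4L else 16L
    state[[paste0("cpos_", kind)]] <- position_counts(idx[state$pos, , drop = FALSE], K)
    state[[paste0("cneg_", kind)]] <- position_counts(idx[!state$pos, , drop = FALSE], K)
  }
  state
}

fold_matrices <- function(state, recipe, xi, holdout) {
  fitted <- list()
  for (kind in intersect(c("PSNP", "PSDP"), recipe$features)) {
    cpos <- state[[paste0("cpos_", kind)]]
    cneg <- state[[paste0("cneg_", kind)]]
    row <- if (kind == "PSNP") state$nuc[holdout, ] else state$din[holdout, ]
    hit <- cbind(row, seq_along(row))
    if (state$pos[holdout]) cpos[hit] <- cpos[hit] - 1L
    else cneg[hit] <- cneg[hit] - 1L
    fitted[[kind]] <- propensity_from_counts(cpos, cneg, kind, xi)
  }
  fitted
}

#' Leakage-safe jackknife (leave-one-out) evaluation
#'
#' For every sample in turn: the PSNP/PSDP propensity matrices are refit on
#' the remaining n - 1 samples only, all samples are encoded with those
#' matrices, an SVM is trained on the n - 1 training samples and scores the
#' held-out one. Refitting inside the fold prevents the held-out sample's
#' class frequencies from leaking into its own features. Verdicts are
#' aggregated into confusion counts, Chou metrics and a ROC/AUC over the
#' per-sample decision scores. Deterministic for fixed inputs.
#'
#' @param dataset A [psi_dataset] with at least 2 samples per class.
#' @param recipe A [feature_recipe].
#' @param svm An [svm_config].
#' @return An object of class `evaluation_result`: `metrics` (a
#'   [chou_metrics] set with AUC filled in), `scores`, `predicted`,
#'   `labels`, `roc`.
#' @export
jackknife <- function(dataset, recipe, svm = svm_config()) {
  n <- length(dataset$segments)
  if (n < 4L || n_pos(dataset) < 2L || n_neg(dataset) < 2L) {
    stop("jackknife requires >= 2 samples per class so every fold trains on both classes",
         call. = FALSE)
  }
  static <- static_block(dataset, recipe)
  state <- if (recipe_needs_fitting(recipe)) jackknife_state(dataset, recipe)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    fitted <- if (!is.null(state)) fold_matrices(state, recipe, dataset$xi, i)
    x <- assemble_features(dataset, recipe, fitted, static)
    model <- fit_rbf_svm(x[-i, , drop = FALSE], dataset$labels[-i], svm)
    scores[i] <- svm_scores(model, x[i, , drop = FALSE])
  }
  finish_evaluation(dataset$labels, scores, dataset, recipe, svm)
}

# Cache the training-set-independent feature blocks once; propensity blocks
# are recomputed per fold.
static_block <- function(dataset, recipe) {
  local_feats <- setdiff(recipe$features, c("PSNP", "PSDP"))
  if (length(local_feats) == 0L) return(NULL)
  sub <- feature_recipe(local_feats, psednc = recipe$psednc)
  encode_matrix(dataset$segments, dataset$xi, sub)
}

assemble_features <- function(dataset, recipe, fitted, static) {
  local_feats <- setdiff(recipe$features, c("PSNP", "PSDP"))
  blocks <- lapply(recipe$features, function(f) {
    if (f %in% c("PSNP", "PSDP")) {
      sub <- feature_recipe(f, psednc = recipe$psednc)
      encode_matrix(dataset$segments, dataset$xi, sub, fitted)
    } else {
      j <- match(f, local_feats)
      dims <- c(NC = 4L, DC = 16L, pseDNC = 16L + recipe$psednc$lambda)
      start <- if (j == 1L) 1L else sum(dims[local_feats[seq_len(j - 1L)]]) + 1L
      static[, start:(start + dims[[f]] - 1L), drop = FALSE]
    }
  })
  do.call(cbind, blocks)
}

finish_evaluation <- function(labels, scores, dataset, recipe, svm) {
  predicted <- ifelse(scores > 0, "pos", "neg")
  metrics <- chou_metrics(tally_predictions(labels, predicted))
  roc <- roc_auc(labels, scores)
  metrics$auc <- roc$auc
  structure(
    list(metrics = metrics, scores = scores, predicted = predicted,
         labels = labels, roc = roc$curve, dataset = dataset$name,
         recipe = recipe, svm = svm),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> %s, %s, c = %g, s = %g\n  ",
              x$dataset, paste(x$recipe$features, collapse = " + "),
              x$svm$cost, x$svm$kernel_scale))
  print(x$metrics)
  invisible(x)
}

#' Independent-test evaluation
#'
#' Fits the propensity matrices and the SVM once on the full training set,
#' then scores the test set. Train and test must share the half-window size;
#' disjointness is the caller's responsibility (a warning is raised when
#' identical segments are spotted in both).
#'
#' @param train,test [psi_dataset] objects with the same `xi`.
#' @inheritParams jackknife
#' @return An `evaluation_result` for the test set.
#' @export
evaluate_independent <- function(train, test, recipe, svm = svm_config()) {
  if (train$xi != test$xi) {
    stop(sprintf("xi mismatch: train %d vs test %d", train$xi, test$xi),
         call. = FALSE)
  }
  if (length(test$segments) == 0L) stop("test set is empty", call. = FALSE)
  overlap <- intersect(train$segments, test$segments)
  if (length(overlap) > 0L) {
    warning(sprintf("%d segment(s) appear in both train and test", length(overlap)))
  }
  fitted <- fit_recipe_matrices(train, recipe)
  xtr <- encode_matrix(train$segments, train$xi, recipe, fitted)
  xte <- encode_matrix(test$segments, test$xi, recipe, fitted)
  model <- fit_rbf_svm(xtr, train$labels, svm)
  scores <- svm_scores(model, xte)
  finish_evaluation(test$labels, scores, test, recipe, svm)
}

#' Grid search over SVM hyperparameters by jackknife
#'
#' Runs the full leakage-safe jackknife at every (cost, kernel scale) cell
#' and returns the best configuration by the chosen criterion. Ties are
#' broken by higher Acc, then smaller cost, then larger kernel scale.
#'
#' @inheritParams jackknife
#' @param grid A [default_grid()] specification.
#' @param criterion `"MCC"` (default) or `"Acc"`.
#' @return A list with `best` (an [svm_config]), `best_result` (its
#'   `evaluation_result`) and `table` (data.frame of cost, kernel_scale,
#'   Sen, Spe, Acc, MCC, AUC for every cell).
#' @export
grid_search <- function(dataset, recipe, grid = default_grid(),
                        criterion = c("MCC", "Acc")) {
  criterion <- match.arg(criterion)
  cells <- expand.grid(cost = grid$cost, kernel_scale = grid$kernel_scale,
                       KEEP.OUT.ATTRS = FALSE)
  results <- vector("list", nrow(cells))
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cfg <- svm_config(cost = cells$cost[i], kernel_scale = cells$kernel_scale[i])
    res <- jackknife(dataset, recipe, cfg)
    results[[i]] <- res
    rows[[i]] <- cbind(data.frame(cost = cfg$cost,
                                  kernel_scale = cfg$kernel_scale),
                       as.data.frame(res$metrics))
  }
  table <- do.call(rbind, rows)
  key <- if (criterion == "MCC") table$MCC else table$Acc
  ord <- order(-key, -table$Acc, table$cost, -table$kernel_scale)
  best_i <- ord[1]
  list(best = svm_config(cost = table$cost[best_i],
                         kernel_scale = table$kernel_scale[best_i]),
       best_result = results[[best_i]], table = table)
}
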