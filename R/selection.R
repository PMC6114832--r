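#' Sequential forward feature selection
#'
#' Greedy wrapper search over feature types. Round 1 scores every single
#' candidate feature by jackknife (with a grid search over the SVM
#' hyperparameters for each candidate); each later round scores every
#' one-feature extension of the incumbent recipe. The search stops when no
#' extension strictly improves the criterion; the incumbent is the optimal
#' subset.
#'
#' @param dataset A [psi_dataset].
#' @param candidates Character vector of feature types to search over
#'   (default all five).
#' @param grid A [default_grid()] specification searched per candidate.
#' @param criterion `"MCC"` (default; ties broken by Acc) or `"Acc"`.
#' @param psednc A [psednc_config] used by pseDNC candidates.
#' @param verbose Print per-round progress to stderr.
#' @return An object of class `sfs_trace`: per-round candidate tables, the
#'   selected recipe and criterion value per round, the final
#'   [feature_recipe], its best [svm_config] and `evaluation_result`, and
#'   `n_jackknife_runs`, the number of jackknife evaluations performed.
#' @export
sfs <- function(dataset, candidates = FEATURE_TYPES, grid = default_grid(),
                criterion = c("MCC", "Acc"), psednc = psednc_config(),
                verbose = FALSE) {
  criterion <- match.arg(criterion)
  stopifnot(length(candidates) >= 1L, all(candidates %in% FEATURE_TYPES))
  crit_of <- function(m) if (criterion == "MCC") m$MCC else m$Acc

  incumbent <- character(0)
  best_value <- -Inf
  best_cfg <- NULL
  best_result <- NULL
  rounds <- list()
  n_runs <- 0L

  repeat {
    remaining <- setdiff(candidates, incumbent)
    if (length(remaining) == 0L) break
    round_rows <- list()
    round_best <- NULL
    for (f in remaining) {
      recipe <- feature_recipe(c(incumbent, f), psednc = psednc)
      gs <- grid_search(dataset, recipe, grid, criterion)
      n_runs <- n_runs + nrow(gs$table)
      m <- gs$best_result$metrics
      row <- data.frame(
        subset = paste(recipe$features, collapse = "+"),
        Sen = m$sen, Spe = m$spe, Acc = m$acc, MCC = m$mcc, AUC = m$auc,
        kernel_scale = gs$best$kernel_scale, cost = gs$best$cost
      )
      round_rows[[f]] <- row
      cand <- list(feature = f, recipe = recipe, cfg = gs$best,
                   result = gs$best_result,
                   value = crit_of(data.frame(MCC = m$mcc, Acc = m$acc)),
                   acc = m$acc)
      if (is.null(round_best) || cand$value > round_best$value ||
          (cand$value == round_best$value && cand$acc > round_best$acc)) {
        round_best <- cand
      }
      if (verbose) {
        message(sprintf("round %d: %-22s Acc %.4f MCC %.4f (c=%g, s=%g)",
                        length(incumbent) + 1L, row$subset, m$acc, m$mcc,
                        gs$best$cost, gs$best$kernel_scale))
      }
    }
    table <- do.call(rbind, round_rows)
    rownames(table) <- NULL
    improved <- round_best$value > best_value
    rounds[[length(rounds) + 1L]] <- list(
      table = table,
      selected = if (improved) paste(round_best$recipe$features, collapse = "+") else NA_character_,
      value = round_best$value, improved = improved
    )
    if (!improved) break
    incumbent <- round_best$recipe$features
    best_value <- round_best$value
    best_cfg <- round_best$cfg
    best_result <- round_best$result
  }

  structure(
    list(rounds = rounds, final_features = incumbent,
         final_recipe = feature_recipe(incumbent, psednc = psednc),
         best_config = best_cfg, best_result = best_result,
         criterion = criterion, best_value = best_value,
         n_jackknife_runs = n_runs),
    class = "sfs_trace"
  )
}

#' @export
print.sfs_trace <- function(x, ...) {
  cat(sprintf("<sfs_trace> %d round(s), criterion %s\n", length(x$rounds),
              x$criterion))
  for (r in seq_along(x$rounds)) {
    sel <- x$rounds[[r]]$selected
    cat(sprintf("  round %d: %s (%s = %.4f)\n", r,
                if (is.na(sel)) "no improvement - stop" else sel,
                x$criterion, x$rounds[[r]]$value))
  }
  cat(sprintf("  final subset: %s\n", paste(x$final_features, collapse = "+")))
  invisible(x)
}

#' Write an SFS trace as a per-round TSV
#'
#' One row per candidate subset per round, mirroring the layout of a
#' feature-selection results table (subset, Sen, Spe, Acc, MCC, kernel
#' scale, box constraint).
#'
#' @param trace An [sfs] trace.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sfs_trace <- function(trace, path) {
  rows <- do.call(rbind, lapply(seq_along(trace$rounds), function(r) {
    cbind(round = r, trace$rounds[[r]]$table)
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
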