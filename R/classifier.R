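BUNDLE_FORMAT_VERSION <- 1L

# Stable hash of a run configuration, for provenance stamping.
config_hash <- function(object) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(object, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Train a deployable site-prediction model
#'
#' Fits the recipe's propensity matrices and the RBF SVM on the full
#' dataset and packages everything needed to score new segments: the
#' trained SVM, the fitted matrices, the feature recipe, the
#' hyperparameters, and provenance (training-set name, config hash,
#' package version). Training is deterministic given its inputs.
#'
#' @param dataset A [psi_dataset].
#' @param recipe A [feature_recipe].
#' @param svm An [svm_config].
#' @param species Optional species tag (e.g. `"H. sapiens"`) stored with
#'   the bundle.
#' @return An object of class `model_bundle`.
#' @export
train_model <- function(dataset, recipe, svm = svm_config(), species = NULL) {
  stopifnot(inherits(dataset, "psi_dataset"), inherits(recipe, "feature_recipe"),
            inherits(svm, "svm_config"))
  if (n_pos(dataset) < 1L || n_neg(dataset) < 1L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  fitted <- fit_recipe_matrices(dataset, recipe)
  x <- encode_matrix(dataset$segments, dataset$xi, recipe, fitted)
  model <- fit_rbf_svm(x, dataset$labels, svm)
  cfg <- list(dataset = dataset$name, recipe = recipe$features,
              psednc = recipe$psednc, svm = unclass(svm), xi = dataset$xi)
  structure(
    list(svm_model = model, recipe = recipe, matrices = fitted,
         svm = svm, xi = dataset$xi, species = species,
         provenance = list(
           training_set = dataset$name,
           n_pos = n_pos(dataset), n_neg = n_neg(dataset),
           config_hash = config_hash(cfg),
           package_version = as.character(utils::packageVersion("pseudoU"))
         ),
         format_version = BUNDLE_FORMAT_VERSION),
    class = "model_bundle"
  )
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle> %s%s: %s, xi = %d, c = %g, s = %g\n",
              x$provenance$training_set,
              if (is.null(x$species)) "" else sprintf(" (%s)", x$species),
              paste(x$recipe$features, collapse = " + "), x$xi,
              x$svm$cost, x$svm$kernel_scale))
  cat(sprintf("  trained on %d pos / %d neg, config %s\n",
              x$provenance$n_pos, x$provenance$n_neg,
              substr(x$provenance$config_hash, 1, 8)))
  invisible(x)
}

#' Decision scores for a set of segments
#'
#' @param bundle A [train_model()] bundle.
#' @param segments List of [rna_segment] objects (or character vector of
#'   segment strings) with the bundle's `xi`.
#' @return Numeric vector of SVM decision scores; a score above 0 is called
#'   a pseudouridine site.
#' @export
predict_scores <- function(bundle, segments) {
  stopifnot(inherits(bundle, "model_bundle"))
  if (is.list(segments)) segments <- vapply(segments, seg_string, character(1))
  if (length(segments) == 0L) return(numeric(0))
  for (s in segments) validate_segment(s, bundle$xi)
  x <- encode_matrix(segments, bundle$xi, bundle$recipe, bundle$matrices)
  svm_scores(bundle$svm_model, x)
}

#' @export
predict.model_bundle <- function(object, segments, ...) {
  predict_scores(object, segments)
}

#' Scan a query sequence for pseudouridine sites
#'
#' Extracts one mirror-padded window per uridine (as the web scanner does),
#' scores each with the bundle's SVM, and labels sites by the sign of the
#' decision score (threshold 0).
#'
#' @param bundle A [train_model()] bundle.
#' @param id Sequence identifier for the report.
#' @param sequence Query RNA (or DNA; T is mapped to U), at least
#'   `2*xi + 1` nucleotides long.
#' @param threshold Decision threshold; default 0.
#' @return A data.frame with one row per U: `id`, `position` (1-based),
#'   `score`, `label` (`"Psi"` / `"not-Psi"`), `segment`.
#' @export
scan_sequence <- function(bundle, id, sequence, threshold = 0) {
  stopifnot(inherits(bundle, "model_bundle"))
  segs <- extract_segments(sequence, bundle$xi, id = id)
  if (length(segs) == 0L) {
    return(data.frame(id = character(0), position = integer(0),
                      score = numeric(0), label = character(0),
                      segment = character(0), stringsAsFactors = FALSE))
  }
  scores <- predict_scores(bundle, segs)
  data.frame(
    id = id,
    position = vapply(segs, function(s) s$origin$position, integer(1)),
    score = scores,
    label = ifelse(scores > threshold, "Psi", "not-Psi"),
    segment = vapply(segs, seg_string, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Scan every sequence in a FASTA file
#'
#' @param bundle A [train_model()] bundle.
#' @param path FASTA path.
#' @param threshold Decision threshold; default 0.
#' @return A data.frame of site predictions for all records.
#' @export
scan_fasta <- function(bundle, path, threshold = 0) {
  recs <- read_fasta(path)
  do.call(rbind, lapply(seq_len(nrow(recs)), function(i) {
    scan_sequence(bundle, recs$id[i], recs$sequence[i], threshold)
  }))
}

#' Save / load a model bundle
#'
#' Bundles round-trip losslessly through RDS with an explicit format
#' version that is checked on load.
#'
#' @param bundle A [train_model()] bundle.
#' @param path File path.
#' @return `save_bundle` returns `path` invisibly; `load_bundle` returns
#'   the [model_bundle].
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "model_bundle"))
  saveRDS(bundle, path, version = 2)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  bundle <- tryCatch(readRDS(path), error = function(e) {
    stop(sprintf("cannot read model bundle '%s': %s", path,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!inherits(bundle, "model_bundle") ||
      is.null(bundle$format_version)) {
    stop(sprintf("'%s' is not a model bundle", path), call. = FALSE)
  }
  if (bundle$format_version != BUNDLE_FORMAT_VERSION) {
    stop(sprintf("bundle format version %s is not supported (expected %d)",
                 bundle$format_version, BUNDLE_FORMAT_VERSION), call. = FALSE)
  }
  bundle
}

#' Species presets for the shipped predictor
#'
#' The per-species defaults of the published predictor: half-window size,
#' selected feature subset and jackknife-optimal SVM hyperparameters for
#' human (21-nt windows, PSNP + DC, s = 2, c = 8), yeast (31-nt windows,
#' DC + PSNP + pseDNC, s = 0.25, c = 2) and mouse (21-nt windows,
#' PSNP + DC, s = 1, c = 2).
#'
#' @param species `"human"`, `"yeast"` or `"mouse"`.
#' @return A list with `species`, `xi`, `min_length`, `recipe` (a
#'   [feature_recipe]) and `svm` (an [svm_config]).
#' @export
species_preset <- function(species = c("human", "yeast", "mouse")) {
  species <- match.arg(species)
  p <- switch(species,
    human = list(tag = "H. sapiens", xi = 10L,
                 recipe = feature_recipe(c("PSNP", "DC")),
                 svm = svm_config(cost = 8, kernel_scale = 2)),
    yeast = list(tag = "S. cerevisiae", xi = 15L,
                 recipe = feature_recipe(c("DC", "PSNP", "pseDNC")),
                 svm = svm_config(cost = 2, kernel_scale = 0.25)),
    mouse = list(tag = "M. musculus", xi = 10L,
                 recipe = feature_recipe(c("PSNP", "DC")),
                 svm = svm_config(cost = 2, kernel_scale = 1))
  )
  list(species = p$tag, xi = p$xi, min_length = 2L * p$xi + 1L,
       recipe = p$recipe, svm = p$svm)
}
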