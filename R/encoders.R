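#' Dinucleotide physicochemical properties
#'
#' Loads the 16 x 3 table of RNA dinucleotide properties (free energy,
#' hydrophilicity, stacking energy) used by the pseudo dinucleotide
#' composition encoder. The table ships as a CSV resource and can be
#' overridden with a user file in the same layout (column `dinucleotide`
#' plus one column per property); rows are matched by dinucleotide name, so
#' file order does not matter.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return A 16 x 3 numeric matrix, rows in lexicographic dinucleotide order.
#' @export
dinucleotide_properties <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dinucleotide_properties.csv",
                        package = "pseudoU", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"dinucleotide" %in% names(tab)) {
    stop("property table must have a 'dinucleotide' column", call. = FALSE)
  }
  missing <- setdiff(RNA_DINUCS, tab$dinucleotide)
  if (length(missing) > 0L) {
    stop(sprintf("property table is missing dinucleotides: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  m <- as.matrix(tab[match(RNA_DINUCS, tab$dinucleotide), -1, drop = FALSE])
  rownames(m) <- RNA_DINUCS
  storage.mode(m) <- "double"
  m
}

#' Standardize a property table
#'
#' Z-scores each property across the 16 dinucleotides (mean 0, SD 1), so
#' that properties on very different scales (stacking energies near -15
#' versus hydrophilicities near 0.3) contribute comparably to the pseudo
#' dinucleotide correlation term.
#'
#' @param table A 16 x k property matrix as from [dinucleotide_properties()].
#' @return The standardized matrix with attribute `normalized = TRUE`.
#' @export
normalize_properties <- function(table) {
  stopifnot(is.matrix(table), nrow(table) == 16L)
  m <- scale(table)
  attr(m, "scaled:center") <- NULL
  attr(m, "scaled:scale") <- NULL
  attr(m, "normalized") <- TRUE
  m
}

#' Nucleotide composition of a segment
#'
#' @param segment An [rna_segment] or segment string.
#' @return Numeric vector of 4 frequencies in order A, C, G, U; sums to 1.
#' @export
encode_nc <- function(segment) {
  s <- seg_string(segment)
  idx <- match(strsplit(s, "", fixed = TRUE)[[1]], RNA_BASES)
  v <- tabulate(idx, nbins = 4L) / nchar(s)
  names(v) <- RNA_BASES
  v
}

#' Dinucleotide composition of a segment
#'
#' Frequencies of the L - 1 overlapping dinucleotides.
#'
#' @inheritParams encode_nc
#' @return Numeric vector of 16 frequencies in lexicographic order AA..UU;
#'   sums to 1.
#' @export
encode_dc <- function(segment) {
  s <- seg_string(segment)
  idx <- match(strsplit(s, "", fixed = TRUE)[[1]], RNA_BASES)
  d <- (idx[-length(idx)] - 1L) * 4L + idx[-1L]
  v <- tabulate(d, nbins = 16L) / (length(idx) - 1L)
  names(v) <- RNA_DINUCS
  v
}

#' Configuration for the pseudo dinucleotide composition encoder
#'
#' @param lambda Number of correlation tiers (non-negative integer). Tier j
#'   correlates dinucleotides j steps apart, so `lambda` must not exceed
#'   L - 2 for segments of length L. Default 2.
#' @param w Weight of the correlation block relative to the composition
#'   block (positive real). Default 0.5.
#' @param properties Character subset of the property columns to use;
#'   default all three.
#' @return An object of class `psednc_config`.
#' @export
psednc_config <- function(lambda = 2, w = 0.5,
                          properties = c("free_energy", "hydrophilicity",
                                         "stacking_energy")) {
  lambda <- as.integer(lambda)
  if (is.na(lambda) || lambda < 0L) stop("lambda must be >= 0", call. = FALSE)
  if (!is.numeric(w) || w <= 0) stop("w must be > 0", call. = FALSE)
  if (length(properties) == 0L) stop("need at least one property", call. = FALSE)
  structure(list(lambda = lambda, w = w, properties = properties),
            class = "psednc_config")
}

# Mean squared property difference between two dinucleotide index vectors.
psednc_theta_terms <- function(prop, i, j) {
  rowMeans((prop[i, , drop = FALSE] - prop[j, , drop = FALSE])^2)
}

#' Pseudo dinucleotide composition of a segment
#'
#' Augments the 16 dinucleotide frequencies f_u with `lambda` tier
#' correlation factors: theta_j is the average, over all dinucleotide pairs
#' j steps apart, of the mean squared difference of their standardized
#' physicochemical property values. The output is
#' `d_u = f_u / (1 + w * sum(theta))` for u <= 16 and
#' `d_{16+j} = w * theta_j / (1 + w * sum(theta))`, so entries are
#' non-negative and sum to 1, and the first 16 entries are proportional to
#' the plain dinucleotide composition.
#'
#' @inheritParams encode_nc
#' @param cfg A [psednc_config].
#' @param table A normalized property matrix from [normalize_properties()];
#'   defaults to the packaged table.
#' @return Numeric vector of length `16 + lambda`.
#' @export
encode_psednc <- function(segment, cfg = psednc_config(),
                          table = normalize_properties(dinucleotide_properties())) {
  s <- seg_string(segment)
  L <- nchar(s)
  if (cfg$lambda > L - 2L) {
    stop(sprintf("lambda = %d exceeds L - 2 = %d for this segment",
                 cfg$lambda, L - 2L), call. = FALSE)
  }
  prop <- table[, cfg$properties, drop = FALSE]
  f <- encode_dc(s)
  nd <- L - 1L
  idx <- match(strsplit(s, "", fixed = TRUE)[[1]], RNA_BASES)
  d <- (idx[-L] - 1L) * 4L + idx[-1L]
  theta <- numeric(cfg$lambda)
  if (cfg$lambda > 0L) {
    for (j in seq_len(cfg$lambda)) {
      i1 <- seq_len(nd - j)
      theta[j] <- mean(psednc_theta_terms(prop, d[i1], d[i1 + j]))
    }
  }
  denom <- 1 + cfg$w * sum(theta)
  v <- c(f / denom, cfg$w * theta / denom)
  names(v) <- c(RNA_DINUCS,
                if (cfg$lambda > 0L) paste0("theta", seq_len(cfg$lambda)))
  v
}

#' Fit a position-specific propensity matrix
#'
#' Computes per-position occurrence frequencies separately from the positive
#' and negative segments (columns sum to 1 in each), and their difference
#' Z = Z_plus - Z_minus. PSNP matrices are 4 x (2*xi + 1) over nucleotides;
#' PSDP matrices are 16 x 2*xi over overlapping dinucleotides. Frequencies
#' are plain maximum-likelihood counts with no pseudocounts.
#'
#' @param dataset A [psi_dataset] with at least one segment per class.
#' @param kind `"PSNP"` or `"PSDP"`.
#' @return An object of class `propensity_matrix` with elements `Z_plus`,
#'   `Z_minus`, `Z`, `kind`, `xi`.
#' @export
fit_propensity <- function(dataset, kind = c("PSNP", "PSDP")) {
  kind <- match.arg(kind)
  stopifnot(inherits(dataset, "psi_dataset"))
  if (n_pos(dataset) < 1L || n_neg(dataset) < 1L) {
    stop("need at least one positive and one negative segment", call. = FALSE)
  }
  idx <- seg_nuc_idx(dataset$segments)
  if (kind == "PSDP") idx <- seg_dinuc_idx(idx)
  K <- if (kind == "PSNP") 4L else 16L
  pos <- dataset$labels == "pos"
  cpos <- position_counts(idx[pos, , drop = FALSE], K)
  cneg <- position_counts(idx[!pos, , drop = FALSE], K)
  propensity_from_counts(cpos, cneg, kind, dataset$xi)
}

position_counts <- function(idx, K) {
  apply(idx, 2, tabulate, nbins = K)
}

propensity_from_counts <- function(counts_pos, counts_neg, kind, xi) {
  Zp <- sweep(counts_pos, 2, colSums(counts_pos), "/")
  Zm <- sweep(counts_neg, 2, colSums(counts_neg), "/")
  labels <- if (kind == "PSNP") RNA_BASES else RNA_DINUCS
  dimnames(Zp) <- dimnames(Zm) <- list(labels, NULL)
  structure(
    list(kind = kind, Z_plus = Zp, Z_minus = Zm, Z = Zp - Zm,
         xi = as.integer(xi)),
    class = "propensity_matrix"
  )
}

#' @export
print.propensity_matrix <- function(x, ...) {
  cat(sprintf("<propensity_matrix> %s, %d x %d (xi = %d)\n",
              x$kind, nrow(x$Z), ncol(x$Z), x$xi))
  invisible(x)
}

check_matrix_xi <- function(matrix, xi, kind) {
  if (!inherits(matrix, "propensity_matrix") || matrix$kind != kind) {
    stop(sprintf("a fitted %s propensity matrix is required", kind),
         call. = FALSE)
  }
  if (matrix$xi != xi) {
    stop(sprintf("matrix xi = %d does not match segment xi = %d",
                 matrix$xi, xi), call. = FALSE)
  }
}

#' Encode a segment by position-specific nucleotide propensity
#'
#' Component j is the fitted Z value of the segment's nucleotide at position
#' j. The center component is always 0 because both classes carry U there.
#'
#' @inheritParams encode_nc
#' @param matrix A fitted PSNP [propensity_matrix][fit_propensity] with
#'   matching `xi`.
#' @return Numeric vector of length `2*xi + 1`.
#' @export
encode_psnp <- function(segment, matrix) {
  s <- seg_string(segment)
  xi <- (nchar(s) - 1L) %/% 2L
  check_matrix_xi(matrix, xi, "PSNP")
  idx <- match(strsplit(s, "", fixed = TRUE)[[1]], RNA_BASES)
  matrix$Z[cbind(idx, seq_along(idx))]
}

#' Encode a segment by position-specific dinucleotide propensity
#'
#' Component j is the fitted Z value of the segment's j-th overlapping
#' dinucleotide.
#'
#' @inheritParams encode_psnp
#' @param matrix A fitted PSDP [propensity_matrix][fit_propensity] with
#'   matching `xi`.
#' @return Numeric vector of length `2*xi`.
#' @export
encode_psdp <- function(segment, matrix) {
  s <- seg_string(segment)
  xi <- (nchar(s) - 1L) %/% 2L
  check_matrix_xi(matrix, xi, "PSDP")
  idx <- match(strsplit(s, "", fixed = TRUE)[[1]], RNA_BASES)
  d <- (idx[-length(idx)] - 1L) * 4L + idx[-1L]
  matrix$Z[cbind(d, seq_along(d))]
}

FEATURE_TYPES <- c("NC", "DC", "pseDNC", "PSNP", "PSDP")

#' Define a feature recipe
#'
#' An ordered set of feature types to concatenate. NC, DC and pseDNC are
#' functions of the segment alone; PSNP and PSDP additionally require fitted
#' propensity matrices.
#'
#' @param features Character vector from `NC`, `DC`, `pseDNC`, `PSNP`,
#'   `PSDP`; order is the concatenation order.
#' @param psednc A [psednc_config] used when `pseDNC` is included.
#' @return An object of class `feature_recipe`.
#' @export
feature_recipe <- function(features, psednc = psednc_config()) {
  features <- as.character(features)
  if (length(features) == 0L) stop("recipe must be nonempty", call. = FALSE)
  bad <- setdiff(features, FEATURE_TYPES)
  if (length(bad) > 0L) {
    stop(sprintf("unknown feature type(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(features)) stop("feature names must be unique", call. = FALSE)
  structure(list(features = features, psednc = psednc),
            class = "feature_recipe")
}

#' @export
print.feature_recipe <- function(x, ...) {
  cat(sprintf("<feature_recipe> %s\n", paste(x$features, collapse = " + ")))
  invisible(x)
}

recipe_needs_fitting <- function(recipe) {
  any(c("PSNP", "PSDP") %in% recipe$features)
}

#' Dimension of a feature recipe
#'
#' @param recipe A [feature_recipe].
#' @param xi Half-window size.
#' @return Total feature dimension (NC = 4, DC = 16, pseDNC = 16 + lambda,
#'   PSNP = 2*xi + 1, PSDP = 2*xi).
#' @export
recipe_dim <- function(recipe, xi) {
  dims <- c(NC = 4L, DC = 16L, pseDNC = 16L + recipe$psednc$lambda,
            PSNP = 2L * xi + 1L, PSDP = 2L * xi)
  sum(dims[recipe$features])
}

#' Fit the propensity matrices a recipe needs
#'
#' @param dataset A [psi_dataset].
#' @param recipe A [feature_recipe].
#' @return Named list with entries `PSNP` and/or `PSDP` as required (empty
#'   list for purely segment-local recipes).
#' @export
fit_recipe_matrices <- function(dataset, recipe) {
  fitted <- list()
  for (kind in intersect(c("PSNP", "PSDP"), recipe$features)) {
    fitted[[kind]] <- fit_propensity(dataset, kind)
  }
  fitted
}

#' Encode one segment under a feature recipe
#'
#' @inheritParams encode_nc
#' @param recipe A [feature_recipe].
#' @param fitted Named list of fitted propensity matrices (from
#'   [fit_recipe_matrices()]) when the recipe includes PSNP/PSDP.
#' @param table Normalized property matrix for pseDNC.
#' @return Numeric feature vector; components concatenated in recipe order.
#' @export
encode <- function(segment, recipe, fitted = list(),
                   table = normalize_properties(dinucleotide_properties())) {
  parts <- lapply(recipe$features, function(f) {
    switch(f,
      NC = encode_nc(segment),
      DC = encode_dc(segment),
      pseDNC = encode_psednc(segment, recipe$psednc, table),
      PSNP = {
        if (is.null(fitted$PSNP)) stop("recipe includes PSNP but no fitted PSNP matrix was supplied", call. = FALSE)
        encode_psnp(segment, fitted$PSNP)
      },
      PSDP = {
        if (is.null(fitted$PSDP)) stop("recipe includes PSDP but no fitted PSDP matrix was supplied", call. = FALSE)
        encode_psdp(segment, fitted$PSDP)
      }
    )
  })
  unlist(parts, use.names = FALSE)
}

# Vectorized dataset encoding: one row per segment. The fast path is exact
# (same arithmetic as encode() per segment) and is what the jackknife and
# trainer use.
encode_matrix <- function(sequences, xi, recipe, fitted = list(),
                          table = normalize_properties(dinucleotide_properties())) {
  n <- length(sequences)
  nuc <- seg_nuc_idx(sequences)
  L <- ncol(nuc)
  din <- seg_dinuc_idx(nuc)
  blocks <- lapply(recipe$features, function(f) {
    switch(f,
      NC = t(apply(nuc, 1, function(r) tabulate(r, 4L))) / L,
      DC = t(apply(din, 1, function(r) tabulate(r, 16L))) / (L - 1L),
      pseDNC = t(vapply(seq_len(n), function(i) {
        encode_psednc(sequences[i], recipe$psednc, table)
      }, numeric(16L + recipe$psednc$lambda))),
      PSNP = {
        check_matrix_xi(fitted$PSNP, xi, "PSNP")
        matrix(fitted$PSNP$Z[cbind(as.vector(nuc),
                                   rep(seq_len(L), each = n))], nrow = n)
      },
      PSDP = {
        check_matrix_xi(fitted$PSDP, xi, "PSDP")
        matrix(fitted$PSDP$Z[cbind(as.vector(din),
                                   rep(seq_len(L - 1L), each = n))], nrow = n)
      }
    )
  })
  do.call(cbind, blocks)
}

#' Encode a whole dataset as a feature matrix
#'
#' @param dataset A [psi_dataset].
#' @param recipe A [feature_recipe].
#' @param fitted Fitted matrices; by default fit on `dataset` itself (do not
#'   use the default inside a cross-validation fold).
#' @return Numeric matrix, one row per segment, columns named per component.
#' @export
encode_dataset <- function(dataset, recipe,
                           fitted = fit_recipe_matrices(dataset, recipe)) {
  m <- encode_matrix(dataset$segments, dataset$xi, recipe, fitted)
  colnames(m) <- feature_names(recipe, dataset$xi)
  m
}

feature_names <- function(recipe, xi) {
  unlist(lapply(recipe$features, function(f) {
    switch(f,
      NC = paste0("NC_", RNA_BASES),
      DC = paste0("DC_", RNA_DINUCS),
      pseDNC = paste0("pseDNC_", c(RNA_DINUCS, if (recipe$psednc$lambda > 0L)
        paste0("theta", seq_len(recipe$psednc$lambda)))),
      PSNP = paste0("PSNP_", seq_len(2L * xi + 1L)),
      PSDP = paste0("PSDP_", seq_len(2L * xi))
    )
  }), use.names = FALSE)
}
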