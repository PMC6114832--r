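#' Configuration for the synthetic benchmark generator
#'
#' The generator emulates the structure of the curated pseudouridine
#' benchmarks: balanced sets of fixed-length segments with an invariant
#' central U, where the positive class carries a position-specific nucleotide
#' skew of configurable strength and the negative class is uniform.
#'
#' @param xi Half-window size (default 10, giving 21-nt segments).
#' @param n_pos,n_neg Positive / negative sample counts (default 100 each).
#' @param bias_strength Value in \[0, 1\]: at each biased position the
#'   positive class draws a planted nucleotide with probability
#'   `bias_strength + (1 - bias_strength)/4` (so 0 is the null model and 1
#'   makes the position constant).
#' @param biased_positions 1-based positions carrying the planted signal;
#'   must exclude the center. Default: offsets -2, -1, +1, +2 around the
#'   central U, a motif-like flank signal.
#' @param seed Integer seed; generation is bit-reproducible for a fixed seed.
#' @param planted_nucleotides Optional character vector (one of A/C/G/U per
#'   biased position) fixing the planted motif, e.g. to draw train and test
#'   sets from the same class-conditional distribution under different
#'   seeds. By default the motif is drawn once from the seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(xi = 10, n_pos = 100, n_neg = 100,
                             bias_strength = 0.6,
                             biased_positions = xi + 1 + c(-2, -1, 1, 2),
                             seed = 1, planted_nucleotides = NULL) {
  xi <- as.integer(xi)
  center <- xi + 1L
  biased_positions <- as.integer(biased_positions)
  if (!is.numeric(bias_strength) || bias_strength < 0 || bias_strength > 1) {
    stop("bias_strength must be in [0, 1]", call. = FALSE)
  }
  if (any(biased_positions < 1L | biased_positions > 2L * xi + 1L) ||
      center %in% biased_positions) {
    stop("biased_positions must lie in 1..2*xi+1 and exclude the center",
         call. = FALSE)
  }
  if (n_pos < 1L || n_neg < 1L) stop("need at least one sample per class", call. = FALSE)
  if (!is.null(planted_nucleotides)) {
    if (length(planted_nucleotides) != length(biased_positions) ||
        !all(planted_nucleotides %in% RNA_BASES)) {
      stop("planted_nucleotides must give one of A/C/G/U per biased position",
           call. = FALSE)
    }
  }
  structure(
    list(xi = xi, n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
         bias_strength = bias_strength, biased_positions = biased_positions,
         seed = as.integer(seed), planted_nucleotides = planted_nucleotides),
    class = "synthetic_config"
  )
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic labeled benchmark
#'
#' Positives draw nucleotides at the biased positions from a distribution
#' skewed toward a per-position planted nucleotide (chosen once from the
#' seed); negatives, and all unbiased positions, draw uniformly. The center
#' is always U in both classes.
#'
#' @param config A [synthetic_config].
#' @param name Dataset name.
#' @return A [psi_dataset] with positives first.
#' @export
generate_synthetic <- function(config, name = "synthetic") {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    L <- 2L * config$xi + 1L
    center <- config$xi + 1L
    planted <- if (is.null(config$planted_nucleotides)) {
      sample(4L, length(config$biased_positions), replace = TRUE)
    } else {
      match(config$planted_nucleotides, RNA_BASES)
    }
    b <- config$bias_strength
    p_bias <- rep((1 - b) / 4, 4)

    draw_class <- function(n, biased) {
      m <- matrix(sample(4L, n * L, replace = TRUE), nrow = n, ncol = L)
      if (biased && length(config$biased_positions) > 0L) {
        for (k in seq_along(config$biased_positions)) {
          p <- p_bias
          p[planted[k]] <- p[planted[k]] + b
          m[, config$biased_positions[k]] <-
            sample(4L, n, replace = TRUE, prob = p)
        }
      }
      m[, center] <- 4L  # U
      apply(m, 1, function(r) paste(RNA_BASES[r], collapse = ""))
    }

    segs <- c(draw_class(config$n_pos, TRUE), draw_class(config$n_neg, FALSE))
    labels <- c(rep("pos", config$n_pos), rep("neg", config$n_neg))
    ds <- psi_dataset(segs, labels, config$xi, name = name)
    attr(ds, "planted") <- list(positions = config$biased_positions,
                                nucleotides = RNA_BASES[planted])
    ds
  })
}
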