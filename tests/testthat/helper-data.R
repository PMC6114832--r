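# Tiny fixtures built in code.

# xi = 1 toy with hand-enumerable propensity frequencies.
toy_dataset <- function() {
  psi_dataset(c("AUA", "AUA", "GUC", "AUA"),
              c("pos", "pos", "neg", "neg"), xi = 1, name = "toy")
}

random_segment <- function(xi) {
  L <- 2L * xi + 1L
  chars <- sample(c("A", "C", "G", "U"), L, replace = TRUE)
  chars[xi + 1L] <- "U"
  paste(chars, collapse = "")
}

random_dataset <- function(n_pos = 10, n_neg = 10, xi = 5, name = "rand") {
  segs <- replicate(n_pos + n_neg, random_segment(xi))
  psi_dataset(segs, rep(c("pos", "neg"), c(n_pos, n_neg)), xi, name = name)
}

write_temp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

subset_dataset_for_test <- function(ds, keep) {
  psi_dataset(ds$segments[keep], ds$labels[keep], ds$xi, name = ds$name)
}

# Path where the curated benchmark FASTA files would live if they could be
# redistributed with the package.
benchmark_path <- function(name) {
  system.file("extdata", "benchmarks", paste0(name, ".fasta"),
              package = "pseudoU")
}
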