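test_that("nucleotide and dinucleotide composition count k-mers correctly", {
  expect_equal(unname(encode_nc("AUAUA")), c(0.6, 0, 0, 0.4))
  expect_equal(unname(encode_nc("UUUUU")), c(0, 0, 0, 1))
  dc <- encode_dc("AUAUA")
  expect_equal(unname(dc[c("AU", "UA")]), c(0.5, 0.5))
  expect_equal(sum(dc), 1)
  expect_equal(unname(encode_dc("UUUUU")["UU"]), 1)

  # DC equals direct enumeration of the L-1 overlapping pairs
  set.seed(3)
  for (rep in 1:20) {
    s <- random_segment(xi = 6)
    chars <- strsplit(s, "")[[1]]
    pairs <- paste0(chars[-length(chars)], chars[-1])
    oracle <- table(factor(pairs, levels = names(encode_dc(s)))) / length(pairs)
    expect_equal(unname(encode_dc(s)), as.numeric(oracle))
    expect_equal(sum(encode_nc(s)), 1)
  }
})

test_that("property table standardization gives zero-mean unit-SD columns", {
  raw <- dinucleotide_properties()
  expect_equal(dim(raw), c(16L, 3L))
  expect_equal(unname(raw["GG", ]), c(-3.260, 0.170, -11.100))
  norm <- normalize_properties(raw)
  expect_true(all(abs(colMeans(norm)) < 1e-9))
  expect_true(all(abs(apply(norm, 2, sd) - 1) < 1e-9))
  # standardized value recomputed by hand from the raw column
  fe <- raw[, "free_energy"]
  expect_equal(unname(norm["GG", "free_energy"]),
               (raw["GG", "free_energy"] - mean(fe)) / sd(fe))
  # a table missing a dinucleotide is rejected
  p <- withr::local_tempfile(fileext = ".csv")
  tab <- data.frame(dinucleotide = rownames(raw), raw, check.names = FALSE)
  utils::write.csv(tab[rownames(tab) != "GG", ], p, row.names = FALSE)
  expect_error(dinucleotide_properties(p), "missing dinucleotides: GG")
})

test_that("pseDNC reduces to DC at lambda = 0 and for homopolymers", {
  tab <- normalize_properties(dinucleotide_properties())
  set.seed(5)
  for (rep in 1:20) {
    s <- random_segment(xi = 5)
    v <- encode_psednc(s, psednc_config(lambda = 0), tab)
    expect_equal(unname(v), unname(encode_dc(s)))
  }
  # identical dinucleotides everywhere: every correlation term vanishes
  v <- encode_psednc("UUUUU", psednc_config(lambda = 3), tab)
  expect_equal(unname(v), c(unname(encode_dc("UUUUU")), 0, 0, 0))
})

test_that("pseDNC matches a brute-force evaluation of the tier formula", {
  tab <- normalize_properties(dinucleotide_properties())
  cfg <- psednc_config(lambda = 1, w = 0.7, properties = "hydrophilicity")
  s <- "GAUCU"  # 5-nt toy, dinucleotides GA AU UC CU
  d <- c("GA", "AU", "UC", "CU")
  theta1 <- mean(sapply(1:3, function(i) {
    (tab[d[i], "hydrophilicity"] - tab[d[i + 1], "hydrophilicity"])^2
  }))
  f <- encode_dc(s)
  expected <- c(f / (1 + 0.7 * theta1), 0.7 * theta1 / (1 + 0.7 * theta1))
  got <- encode_psednc(s, cfg, tab)
  expect_equal(unname(got), unname(expected))
  expect_equal(sum(got), 1)
  expect_true(all(got >= 0))
  # lambda beyond L - 2 is rejected
  expect_error(encode_psednc(s, psednc_config(lambda = 4), tab), "lambda")
})

test_that("propensity fitting reproduces hand-enumerated toy frequencies", {
  ds <- toy_dataset()  # pos {AUA, AUA}, neg {GUC, AUA}
  psdp <- fit_propensity(ds, "PSDP")
  expect_equal(dim(psdp$Z), c(16L, 2L))
  expect_equal(unname(psdp$Z["AU", 1]), 0.5)
  expect_equal(unname(psdp$Z["GU", 1]), -0.5)
  expect_equal(unname(psdp$Z["UA", 2]), 0.5)
  expect_equal(unname(psdp$Z["UC", 2]), -0.5)
  expect_equal(sum(abs(psdp$Z)), 2)  # all other entries zero

  psnp <- fit_propensity(ds, "PSNP")
  expect_equal(unname(encode_psnp("AUA", psnp)), c(0.5, 0, 0.5))
  expect_equal(unname(encode_psdp("AUA", psdp)), c(0.5, 0.5))

  # identical classes give the zero matrix and zero encodings
  same2 <- psi_dataset(c("AUA", "GUC", "AUA", "GUC"),
                       rep(c("pos", "neg"), each = 2), xi = 1)
  z <- fit_propensity(same2, "PSNP")
  expect_true(all(z$Z == 0))
  expect_equal(unname(encode_psnp("GUC", z)), c(0, 0, 0))

  expect_error(fit_propensity(psi_dataset("AUA", "pos", 1), "PSNP"),
               "positive and one negative")
})

test_that("propensity matrices are column-stochastic differences", {
  set.seed(8)
  for (rep in 1:10) {
    ds <- random_dataset(n_pos = sample(3:12, 1), n_neg = sample(3:12, 1),
                         xi = sample(2:6, 1))
    for (kind in c("PSNP", "PSDP")) {
      m <- fit_propensity(ds, kind)
      expect_true(all(abs(colSums(m$Z_plus) - 1) < 1e-9))
      expect_true(all(abs(colSums(m$Z_minus) - 1) < 1e-9))
      expect_true(all(abs(colSums(m$Z)) < 1e-9))
      expect_true(all(m$Z >= -1 & m$Z <= 1))
    }
    psnp <- fit_propensity(ds, "PSNP")
    expect_true(all(psnp$Z[, ds$xi + 1] == 0))  # center invariantly U
  }
})

test_that("recipe encoding concatenates components at the documented dimensions", {
  set.seed(13)
  ds <- random_dataset(n_pos = 6, n_neg = 6, xi = 10)
  r <- feature_recipe(c("PSNP", "DC"))
  expect_equal(recipe_dim(r, 10), 37L)
  fitted <- fit_recipe_matrices(ds, r)
  v <- encode(ds$segments[1], r, fitted)
  expect_length(v, 37L)
  expect_equal(v[1:21], unname(encode_psnp(ds$segments[1], fitted$PSNP)))
  expect_equal(v[22:37], unname(encode_dc(ds$segments[1])))

  r2 <- feature_recipe(c("DC", "PSNP", "pseDNC"), psednc = psednc_config(lambda = 2))
  expect_equal(recipe_dim(r2, 15), 65L)

  expect_equal(encode(ds$segments[2], feature_recipe("NC")),
               unname(encode_nc(ds$segments[2])))
  expect_error(encode(ds$segments[1], r), "no fitted PSNP")

  # dataset-level encoding agrees with per-segment encoding row by row
  X <- encode_dataset(ds, r, fitted)
  expect_equal(colnames(X)[1], "PSNP_1")
  for (i in c(1, 5, 12)) {
    expect_equal(unname(X[i, ]), encode(ds$segments[i], r, fitted))
  }
  r3 <- feature_recipe(c("NC", "pseDNC"))
  X3 <- encode_dataset(ds, r3)
  for (i in c(2, 9)) {
    expect_equal(unname(X3[i, ]), encode(ds$segments[i], r3))
  }
})

test_that("xi mismatch between matrix and segment is rejected", {
  ds <- random_dataset(xi = 4)
  m <- fit_propensity(ds, "PSNP")
  expect_error(encode_psnp(random_segment(5), m), "xi")
  expect_error(encode_psdp(random_segment(5), fit_propensity(ds, "PSDP")), "xi")
})

test_that("planted positional bias dominates the fitted propensity columns", {
  hits <- 0L
  for (seed in 1:5) {
    cfg <- synthetic_config(xi = 6, n_pos = 150, n_neg = 150,
                            bias_strength = 0.8, biased_positions = 4,
                            seed = seed)
    ds <- generate_synthetic(cfg)
    Z <- fit_propensity(ds, "PSNP")$Z
    norms <- sqrt(colSums(Z^2))
    norms[7] <- -Inf  # center column is identically zero
    if (which.max(norms) == 4L) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
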