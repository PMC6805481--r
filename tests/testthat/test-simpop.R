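# Synthetic multi-population generator: founder divergence, gene dropping,
# QTL/phenotype assignment, determinism.

test_that("zero divergence makes populations exchangeable", {
  cfg <- sim_config(n_populations = 2, founders_per_pop = 60,
                    generations = 0, n_seq_markers = 2000,
                    n_chip_markers = 100, n_qtl = 10, divergence = 0,
                    seed = 1)
  f <- with_seed(1, simulate_founders(cfg))
  M <- f$panel$dosage
  pop <- f$pedigree$population
  d <- colMeans(M[pop == "POP1", ]) / 2 - colMeans(M[pop == "POP2", ]) / 2
  # no systematic frequency difference; binomial noise only
  expect_lt(abs(mean(d)), 0.01)
  expect_lt(abs(hudson_fst(M[pop == "POP1", ], M[pop == "POP2", ])), 0.01)
})

test_that("the divergence knob is calibrated as an Fst", {
  fst <- vapply(1:10, function(seed) {
    cfg <- sim_config(n_populations = 2, founders_per_pop = 60,
                      generations = 0, n_seq_markers = 5000,
                      n_chip_markers = 100, n_qtl = 10, divergence = 0.1,
                      seed = seed)
    f <- with_seed(seed, simulate_founders(cfg))
    M <- f$panel$dosage
    pop <- f$pedigree$population
    hudson_fst(M[pop == "POP1", ], M[pop == "POP2", ])
  }, 0)
  expect_lt(abs(mean(fst) - 0.1), 0.03)
})

test_that("the chip panel is a strict subset of the sequence panel", {
  b <- simulate_population(small_sim_config(5))
  chip <- colnames(b$chip_panel$dosage)
  seqm <- colnames(b$seq_panel$dosage)
  expect_true(all(chip %in% seqm))
  expect_lt(length(chip), length(seqm))
  # evenly spaced subsets span every chromosome
  expect_setequal(unique(b$chip_panel$map$chrom), unique(b$seq_panel$map$chrom))
})

test_that("pedigree counts follow the mating design", {
  cfg <- sim_config(n_populations = 2, founders_per_pop = 40,
                    generations = 3, dams_per_sire = 4, progeny_per_dam = 2,
                    n_seq_markers = 200, n_chip_markers = 20, n_qtl = 5,
                    seed = 2)
  b <- simulate_population(cfg)
  n_sires <- max(1, round(40 / (4 * 2)))
  per_gen <- 2 * n_sires * 4 * 2
  expect_equal(nrow(b$pedigree), 2 * 40 + 3 * per_gen)
  expect_error(simulate_pedigree_and_dropdown(
    sim_config(founders_per_pop = 4, generations = 5, seed = 1),
    with_seed(1, simulate_founders(sim_config(founders_per_pop = 4,
                                              n_seq_markers = 50,
                                              n_chip_markers = 5,
                                              n_qtl = 2, seed = 1)))),
    "parents")
})

test_that("gene dropping respects Mendelian inheritance", {
  b <- simulate_population(small_sim_config(7))
  M <- b$seq_panel$dosage
  expect_true(all(M %in% 0:2))
  off <- b$pedigree[b$pedigree$generation == 1, ][1, ]
  # offspring dosage never exceeds what the parents can transmit
  s <- M[off$sire, ]; d <- M[off$dam, ]; o <- M[off$id, ]
  expect_true(all(o >= pmax(0, s / 2 + d / 2 - 1) - 1e-9))
  expect_gt(cor(o, (s + d) / 2), 0.3)
})

test_that("full sibs average one half genomic relatedness", {
  rel <- vapply(1:5, function(seed) {
    cfg <- sim_config(n_populations = 1, founders_per_pop = 20,
                      generations = 1, dams_per_sire = 1,
                      progeny_per_dam = 2, n_chromosomes = 5,
                      n_seq_markers = 4000, n_chip_markers = 100,
                      n_qtl = 10, divergence = 0, seed = seed)
    b <- simulate_population(cfg)
    sibs <- b$pedigree[b$pedigree$generation == 1, ]
    fam <- split(sibs$id, paste(sibs$sire, sibs$dam))
    fam <- fam[lengths(fam) == 2]
    mean(vapply(fam, function(ids) {
      M <- b$seq_panel$dosage
      p <- colMeans(M) / 2
      ok <- p > 0.05 & p < 0.95
      z1 <- M[ids[1], ok] - 2 * p[ok]
      z2 <- M[ids[2], ok] - 2 * p[ok]
      sum(z1 * z2) / (2 * sum(p[ok] * (1 - p[ok])))
    }, 0))
  }, 0)
  expect_lt(abs(mean(rel) - 0.5), 0.05)
})

test_that("true breeding values are exact QTL sums at the target variance", {
  b <- simulate_population(small_sim_config(9))
  eff <- b$qtl_effects
  for (tr in unique(eff$trait)) {
    e <- eff[eff$trait == tr, ]
    g <- as.numeric(b$seq_panel$dosage[rownames(b$tbv), e$marker] %*% e$effect)
    expect_equal(unname(b$tbv[, tr]), g - mean(g), tolerance = 1e-10)
  }
  specs <- b$config$trait_specs
  for (ts in specs)
    expect_equal(var(b$tbv[, ts$name]), ts$h2, tolerance = 1e-10)
})

test_that("phenotypes carry the requested structure and heritability", {
  cfg <- sim_config(n_populations = 2, founders_per_pop = 80,
                    generations = 3, dams_per_sire = 4, progeny_per_dam = 3,
                    n_seq_markers = 800, n_chip_markers = 80, n_qtl = 40,
                    seed = 31)
  b <- simulate_population(cfg)
  rec <- b$records
  # repeated trait: exactly `parities` records per phenotyped sow
  nba <- rec[rec$trait == "NBA", ]
  expect_true(all(table(nba$id) == 3))
  expect_true(all(b$pedigree$sex[match(unique(nba$id), b$pedigree$id)] == "F"))
  # single-record trait: full sibs share a litter code
  age <- rec[rec$trait == "AGE", ]
  expect_true(all(table(age$id) == 1))
  sib <- b$pedigree[b$pedigree$generation == 2, ]
  l <- age$litter[match(sib$id[1:2], age$id)]
  # regression of phenotype on TBV has slope near one
  sl <- vapply(unique(rec$trait), function(tr) {
    r <- rec[rec$trait == tr, ]
    unname(coef(lm(r$value ~ b$tbv[r$id, tr]))[2])
  }, 0)
  expect_true(all(abs(sl - 1) < 0.35))
  expect_lt(abs(mean(sl) - 1), 0.15)
})

test_that("requesting h2 at the interval edge errors", {
  expect_error(trait_spec("x", "repeated", h2 = 0), "h2")
  expect_error(trait_spec("x", "repeated", h2 = 1), "h2")
  expect_error(trait_spec("x", "repeated", h2 = 0.5,
                          rep_or_litter_var_ratio = 0.6),
               "< 1")
})

test_that("the same seed reproduces the bundle byte for byte", {
  b1 <- simulate_population(small_sim_config(17))
  b2 <- simulate_population(small_sim_config(17))
  expect_identical(b1$seq_panel$dosage, b2$seq_panel$dosage)
  expect_identical(b1$pedigree, b2$pedigree)
  expect_identical(b1$records, b2$records)
  expect_identical(b1$qtl_effects, b2$qtl_effects)
  b3 <- simulate_population(small_sim_config(18))
  expect_false(identical(b1$seq_panel$dosage, b3$seq_panel$dosage))
})

test_that("single-population panels show no PCA cluster structure", {
  cfg <- sim_config(n_populations = 1, founders_per_pop = 60,
                    generations = 0, n_seq_markers = 1000,
                    n_chip_markers = 100, n_qtl = 10, divergence = 0,
                    seed = 23)
  b <- simulate_population(cfg)
  pc <- pca_structure(b$seq_panel, n_components = 5)
  # leading eigenvalue share stays in the random-matrix noise band
  expect_lt(pc$var_explained[1], 3 / 60)
})
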