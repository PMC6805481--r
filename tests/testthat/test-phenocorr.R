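# Weight adjustment to 100 kg, herd-year-season coding, pedigree BLUP and
# corrected phenotypes with the reliability filter.

test_that("age adjustment reproduces the correction-factor formula", {
  expect_equal(adjust_age(160, 100, "M"), 160)
  expect_equal(adjust_age(160, 110, "M"), 160 + (100 - 110) * (160 - 50.775) / 110)
  expect_equal(adjust_age(160, 110, "M"), 150.0705, tolerance = 1e-4)
  expect_equal(adjust_age(160, 110, "F"), 149.6714, tolerance = 1e-4)
  expect_error(adjust_age(160, 0, "M"), "positive")
  expect_warning(adjust_age(160, 80, "M"), "85-130")
})

test_that("backfat adjustment reproduces the correction-factor formula", {
  expect_equal(adjust_bft(12, 100, "M"), 12)
  expect_equal(adjust_bft(12, 110, "M"), 12 + (100 - 110) * 12 / (110 + 7.277))
  expect_equal(adjust_bft(12, 110, "M"), 10.9767, tolerance = 1e-4)
  expect_equal(adjust_bft(12, 90, "F"), 13.2066, tolerance = 1e-4)
  # vectorised over sexes
  expect_equal(adjust_bft(c(12, 12), c(110, 90), c("M", "F")),
               c(10.9767, 13.2066), tolerance = 1e-4)
})

test_that("seasons follow the four windows with December rolled forward", {
  expect_equal(hys_code("H", 2013, 1), "H_2013_S1")
  expect_equal(hys_code("H", 2013, 2), "H_2013_S1")
  expect_equal(hys_code("H", 2013, 12), "H_2014_S1")
  expect_equal(hys_code("H", 2013, 3), "H_2013_S2")
  expect_equal(hys_code("H", 2013, 6), "H_2013_S3")
  expect_equal(hys_code("H", 2013, 9), "H_2013_S4")
  expect_equal(hys_code("H", 2013, 11), "H_2013_S4")
  expect_equal(hys_code("H", 2013, 5, sex = "F"), "H_2013_S2_F")
  # identical herd/year/season map to one level
  expect_equal(hys_code("H", 2013, 1), hys_code("H", 2013, 2))
})

test_that("records without a parseable date are dropped with a message", {
  rec <- data.frame(id = c("a", "b"), value = 1:2, herd = "H",
                    date = c("2013-05-01", NA), sex = c("F", "F"))
  expect_message(out <- build_fixed_effects(rec, "repeated"), "dropped")
  expect_equal(out$id, "a")
  expect_equal(out$hys, "H_2013_S2")
})

test_that("pedigree BLUP recovers breeding values and the parent mean", {
  b <- simulate_population(small_sim_config(41))
  rec <- b$records[b$records$trait == "AGE", ]
  fit <- fit_pedigree_blup(rec, b$pedigree, "single_record")
  expect_gt(cor(fit$ebv[rownames(b$tbv)], b$tbv[, "AGE"]), 0.3)
  expect_true(all(fit$reliability >= 0 & fit$reliability <= 1))
  # an unphenotyped terminal offspring sits at its parent average
  ped2 <- rbind(b$pedigree,
                data.frame(id = "TERM", sire = b$pedigree$id[1],
                           dam = b$pedigree$id[2], sex = "F",
                           birth_date = "2015-01-01", population = "POP1",
                           herd = "POP1", generation = 4L))
  fit2 <- fit_pedigree_blup(rec, ped2, "single_record", vc = fit$vc$sigma2)
  expect_equal(unname(fit2$ebv["TERM"]),
               unname(0.5 * (fit2$ebv[b$pedigree$id[1]] +
                               fit2$ebv[b$pedigree$id[2]])),
               tolerance = 1e-8)
})

test_that("EBVs scale with the data while reliabilities stay put", {
  b <- simulate_population(small_sim_config(43))
  rec <- b$records[b$records$trait == "NBA", ]
  fit1 <- fit_pedigree_blup(rec, b$pedigree, "repeated")
  rec2 <- rec
  rec2$value <- rec$value * 3
  vc2 <- fit1$vc$sigma2 * c(9, 9, 9)
  names(vc2) <- names(fit1$vc$sigma2)
  fit2 <- fit_pedigree_blup(rec2, b$pedigree, "repeated", vc = vc2)
  expect_equal(fit2$ebv, fit1$ebv * 3, tolerance = 1e-6)
  expect_equal(fit2$reliability, fit1$reliability, tolerance = 1e-6)
})

test_that("corrected phenotypes add the right residual summary", {
  fake <- structure(list(
    ebv = c(a = 1.2, b = 0.4, d = -0.1),
    reliability = c(a = 0.8, b = 0.29, d = 0.5),
    residuals = data.frame(id = c("a", "a", "b", "d"),
                           parity = c(1, 2, 1, 1),
                           residual = c(0.5, -0.5, 0.2, 0.3)),
    trait_kind = "repeated"), class = "ebv_result")
  yc <- derive_yc(fake)
  # residuals averaging zero leave y_c = EBV; reliability 0.29 is filtered
  expect_setequal(yc$id, c("a", "d"))
  expect_equal(yc$y_c[yc$id == "a"], 1.2)
  expect_equal(yc$y_c[yc$id == "d"], -0.1 + 0.3)
  expect_false("b" %in% yc$id)
})

test_that("correction pays off when fixed-effect noise is substantial", {
  # with herd-year-season effects comparable to the phenotypic SD, removing
  # them through the model beats the raw phenotype as a proxy for the TBV
  gain <- vapply(1:10, function(seed) {
    b <- simulate_population(sim_config(
      n_populations = 1, founders_per_pop = 100, generations = 2,
      dams_per_sire = 4, progeny_per_dam = 3, n_chromosomes = 2,
      n_seq_markers = 400, n_chip_markers = 60, n_qtl = 30,
      divergence = 0, hys_sd = 1, seed = 500 + seed))
    rec <- b$records[b$records$trait == "AGE", ]
    fit <- fit_pedigree_blup(rec, b$pedigree, "single_record")
    yc <- derive_yc(fit, min_reliability = 0)
    tbv <- b$tbv[yc$id, "AGE"]
    raw <- rec$value[match(yc$id, rec$id)]
    cor(yc$y_c, tbv) - cor(raw, tbv)
  }, 0)
  expect_gt(mean(gain), 0)
})
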