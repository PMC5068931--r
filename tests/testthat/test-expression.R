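test_that("a perfect 10-fold series with doubling chemistry fits exactly", {
  cps <- 20 - log10(c(1, 0.1, 0.01)) / log10(2)
  cv <- fit_calibration(c(1, 0.1, 0.01), cps)
  expect_equal(cv$slope, -1 / log10(2), tolerance = 1e-10)
  expect_equal(round(cv$slope, 4), -3.3219)
  expect_equal(cv$efficiency, 2, tolerance = 1e-10)
  expect_true(cv$valid)
  expect_equal(tidy(cv)$n_points, 3)
})

test_that("degenerate calibration inputs are rejected or flagged", {
  expect_error(fit_calibration(c(1, 0.1), c(20, 23)), "3 distinct")
  flat <- suppressWarnings(fit_calibration(c(1, 0.1, 0.01), c(20, 20, 20)))
  expect_false(flat$valid)
  expect_true(is.na(flat$efficiency))
})

test_that("noisy dilution series recover the generating efficiency", {
  des <- demo_qpcr_design(noise_sd = 0.1)
  effs <- purrr::map_dbl(1:50, function(s) {
    cp <- simulate_qpcr(des, seed = 1000 + s)
    fit_calibrations(cp)[["ft1"]]$efficiency
  })
  expect_lt(abs(mean(effs) - 1.90), 0.05)
})

test_that("relative_ratio has its closed forms and symmetry", {
  expect_equal(relative_ratio(2, 25, 2, 25), 1)
  expect_equal(relative_ratio(2, 20, 2, 18), 4)
  expect_equal(relative_ratio(1.95, 22, 1.90, 24.5),
               exp(22 * log(1.95) - 24.5 * log(1.90)), tolerance = 1e-12)
  withr::local_seed(3)
  for (k in 1:20) {
    e <- runif(1, 1.5, 2.1); cp <- runif(1, 10, 35)
    expect_equal(relative_ratio(e, cp, e, cp), 1)
    # doubling-chemistry limit
    cp2 <- runif(1, 10, 35)
    expect_equal(relative_ratio(2, cp, 2, cp2), 2^(cp - cp2))
  }
  expect_error(relative_ratio(1, 20, 2, 20))
})

test_that("calibrator correction cancels multiplicative run effects", {
  expect_equal(calibrator_normalize(3, 2, 2), 3)
  expect_equal(calibrator_normalize(3, 2, 1), 1.5)
  withr::local_seed(9)
  for (k in 1:20) {
    v <- runif(3, 0.1, 10); s <- runif(1, 0.1, 10)
    expect_equal(calibrator_normalize(v[1], v[2] * s, v[3] * s),
                 calibrator_normalize(v[1], v[2], v[3]))
  }
  expect_error(calibrator_normalize(-1, 1, 1))
})

test_that("aggregate_sample inverts simple constructed tables", {
  base <- tidyr::expand_grid(
    sample_id = "s1", run_id = "run1", rt_replicate = 1:2,
    tech_replicate = 1:2)
  cp <- dplyr::bind_rows(
    dplyr::mutate(base, gene_id = "target", cp = 24, role = "target"),
    dplyr::mutate(base, gene_id = "actin", cp = 24, role = "reference")) |>
    dplyr::mutate(dilution = NA_real_)
  curves <- tibble::tibble(gene_id = c("target", "actin"), efficiency = 2)
  out <- aggregate_sample(cp, curves, "actin")
  expect_equal(out$ratio, 1)
  expect_equal(out$sd, 0)
  expect_equal(out$n_rt_replicates, 2)

  cp2 <- dplyr::mutate(cp, cp = ifelse(gene_id == "target", cp - 1, cp))
  expect_equal(aggregate_sample(cp2, curves, "actin")$ratio, 2)

  # permuting replicate order changes nothing
  cp3 <- cp2[sample(nrow(cp2)), ]
  expect_equal(aggregate_sample(cp3, curves, "actin"),
               aggregate_sample(cp2, curves, "actin"))

  noref <- dplyr::filter(cp2, gene_id == "target")
  expect_error(aggregate_sample(noref, curves, "actin"), "reference gene")
})

test_that("a noiseless simulated experiment inverts to the design ratios", {
  des <- demo_qpcr_design(noise_sd = 0, run_offsets = c(run1 = 0, run2 = 1.3))
  cp <- simulate_qpcr(des, seed = 17)
  curves <- fit_calibrations(cp)
  out <- aggregate_sample(cp, curves, "actin") |>
    dplyr::arrange(sample_id, gene_id)
  truth <- dplyr::arrange(des$ratios, sample_id, gene_id)
  expect_equal(out$sample_id, truth$sample_id)
  expect_equal(out$ratio, truth$ratio, tolerance = 1e-9)
  expect_equal(out$sd, rep(0, 4), tolerance = 1e-9)
})

test_that("cdna_rescale bridges by the geometric mean factor", {
  r <- tibble::tibble(sample_id = "s", gene_id = "g", ratio = c(1, 2),
                      sd = 0, n_rt_replicates = 2, normalization = "cdna")
  one <- tibble::tibble(cdna_value = 1, actin_value = 2)
  out <- cdna_rescale(r, one)
  expect_equal(out$ratio, c(2, 4))
  expect_equal(unique(out$normalization), "cdna_rescaled")
  expect_equal(cdna_rescale(c(1, 2), tibble::tibble(cdna_value = 1,
                                                    actin_value = 1)),
               c(1, 2))
  two <- tibble::tibble(cdna_value = c(1, 1), actin_value = c(2, 8))
  expect_equal(cdna_rescale(1, two), 4)
  expect_error(cdna_rescale(r, one[0, ]), "bridge")
})

test_that("fpkm implements its definition and scaling laws", {
  expect_equal(fpkm(1000, 1000, 1e6), 1000)
  expect_equal(fpkm(0, 1000, 1e6), 0)
  expect_equal(fpkm(250, 2000, 5e6), 25)
  withr::local_seed(12)
  f <- sample(1:1e4, 5); L <- sample(200:3000, 5); M <- 2e6
  expect_equal(fpkm(2 * f, L, M), 2 * fpkm(f, L, M))
  expect_equal(fpkm(f, 2 * L, M), fpkm(f, L, M) / 2)
  expect_equal(fpkm(f, L, 2 * M), fpkm(f, L, M) / 2)
  expect_error(fpkm(10, 0, 1e6), "positive")
  expect_error(fpkm(10, 100, 0), "positive")
})
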