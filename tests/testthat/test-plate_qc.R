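test_that("plate normalization divides by the stimulated-vehicle mean", {
  cpd <- tibble::tibble(compound_id = "C01", cell_count = 2000,
                        intensity_ccl2 = 150, intensity_icam1 = 150)
  wells <- make_plate(stim_ccl2 = c(190, 210), veh_ccl2 = c(40, 40),
                      compounds = cpd)
  nm <- normalize_plate(wells)
  expect_equal(nm$activity_ccl2[nm$compound_id == "C01"], 150 / 200)
  expect_equal(nm$activity_ccl2[nm$role == "vehicle_only"], c(0.2, 0.2))
  # the reference wells themselves average exactly 1
  expect_equal(mean(nm$activity_ccl2[nm$role == "vehicle_stim"]), 1,
               tolerance = 1e-15)
})

test_that("normalization is invariant to a global plate factor", {
  cpd <- tibble::tibble(compound_id = sprintf("C%02d", 1:5),
                        cell_count = 2000,
                        intensity_ccl2 = c(150, 80, 210, 400, 20),
                        intensity_icam1 = c(90, 260, 150, 310, 55))
  wells <- make_plate(compounds = cpd)
  nm1 <- normalize_plate(wells)
  for (k in c(0.3, 7.7)) {
    scaled <- wells
    scaled$intensity_ccl2 <- scaled$intensity_ccl2 * k
    scaled$intensity_icam1 <- scaled$intensity_icam1 * k
    nm2 <- normalize_plate(scaled)
    expect_equal(nm2$activity_ccl2, nm1$activity_ccl2, tolerance = 1e-12)
    expect_equal(nm2$activity_icam1, nm1$activity_icam1, tolerance = 1e-12)
  }
})

test_that("normalization errors on missing or degenerate controls, and zeroes dead wells", {
  wells <- make_plate()
  expect_error(normalize_plate(wells[wells$role != "vehicle_stim", ]),
               class = "screenfunnel_normalization_error")
  flat <- make_plate(stim_ccl2 = c(0, 0), stim_icam1 = c(0, 0))
  expect_error(normalize_plate(flat),
               class = "screenfunnel_degenerate_control_error")

  cpd <- tibble::tibble(compound_id = "C01", cell_count = 0L,
                        intensity_ccl2 = NA_real_, intensity_icam1 = NA_real_)
  nm <- normalize_plate(make_plate(compounds = cpd))
  dead <- nm[nm$compound_id == "C01", ]
  expect_true(is.na(dead$activity_ccl2))
  expect_equal(dead$cell_ratio, 0)
})

test_that("zprime matches the closed form and its symmetries", {
  # noiseless controls give the maximal window of 1
  expect_equal(zprime(c(200, 200, 200), c(40, 40, 40)), 1)
  # constructed two-point groups with exact moments: mu 200 sd 10 vs mu 40 sd 6
  pos <- 200 + c(-5, 5) * sqrt(2)
  neg <- 40 + c(-3, 3) * sqrt(2)
  expect_equal(zprime(pos, neg), 1 - 3 * 16 / 160, tolerance = 1e-12)

  # symmetry, shift- and scale-invariance on randomized inputs
  set.seed(101)
  for (i in 1:10) {
    p <- rnorm(8, 10, 1); n <- rnorm(6, 2, 0.5)
    z <- zprime(p, n)
    expect_equal(zprime(n, p), z, tolerance = 1e-12)
    expect_equal(zprime(p + 3.2, n + 3.2), z, tolerance = 1e-10)
    expect_equal(zprime(p * 5.5, n * 5.5), z, tolerance = 1e-10)
    expect_lte(z, 1)
  }

  expect_error(zprime(c(1, 2), c(2)),
               class = "screenfunnel_insufficient_replicates")
  expect_error(zprime(c(1, 3), c(3, 1)),
               class = "screenfunnel_undefined_window")
})

test_that("channel concordance is the product-moment correlation with p-value", {
  x <- c(0.2, 0.7, 1.1, 1.4, 2.0)
  expect_equal(channel_concordance(x, 2 * x)$r, 1, tolerance = 1e-12)
  expect_equal(channel_concordance(x, -x + 5)$r, -1, tolerance = 1e-12)
  # hand product-moment computation for (1,2,3) vs (1,2,4): r = 3/sqrt(28/3)
  cc <- channel_concordance(c(1, 2, 3), c(1, 2, 4))
  expect_equal(cc$r, 3 / sqrt(28 / 3), tolerance = 1e-12)
  expect_true(cc$p_value > 0 && cc$p_value < 1)
  expect_error(channel_concordance(c(1, 1, 1), c(1, 2, 3)),
               class = "screenfunnel_degenerate_input")
})

test_that("concordance between channels rises toward 1 as well noise vanishes", {
  r_at <- function(cv) {
    cfg <- sim_config(n_compounds = 60, fraction_modulators = 0.3,
                      fraction_cytotoxic = 0, seed = 21)
    sim <- simulate_screen(cfg, noise_model(well_cv = cv, plate_sigma = 0.1),
                           "primary")
    nm <- normalize_screen(sim$dataset)
    cpd <- nm[nm$role == "compound", ]
    channel_concordance(cpd$activity_ccl2, cpd$activity_icam1)$r
  }
  rs <- vapply(c(0.2, 0.05, 0.01), r_at, numeric(1))
  expect_true(all(diff(rs) > 0))
  expect_gt(rs[3], 0.99)
})

test_that("the TGFbeta control verdict follows observed inhibition", {
  plate <- make_normalized("X", 1)[0, ]
  tg <- tibble::tibble(plate_id = "P1", row = "A", col = 11:12,
                       role = c("tgfb_low", "tgfb_high"), compound_id = "",
                       concentration_um = 0, cell_count = 2000,
                       activity_ccl2 = c(0.75, 0.5),
                       activity_icam1 = c(0.75, 0.5), cell_ratio = 1)
  v <- control_check(dplyr::bind_rows(plate, tg))
  expect_equal(v$inhibition[v$role == "tgfb_high"], 0.5)
  expect_equal(unique(v$verdict), "pass")

  tg$activity_ccl2 <- c(1, 1)
  expect_equal(unique(control_check(dplyr::bind_rows(plate, tg))$verdict),
               "fail")

  expect_warning(v0 <- control_check(plate), "skipped")
  expect_equal(v0$verdict, "not_evaluated")
})

test_that("plate_qc reports per-plate and pooled screen windows", {
  sim <- simulate_screen(sim_config(n_compounds = 80, seed = 33),
                         noise_model(), "primary")
  nm <- normalize_screen(sim$dataset)
  qc <- plate_qc(nm)
  expect_equal(nrow(qc$plates), length(unique(nm$plate_id)))
  expect_true(all(qc$plates$zprime_ccl2 <= 1))
  expect_true(all(qc$plates$separation_ccl2 > 1))
  expect_true(is.finite(qc$screen$zprime_ccl2))
  # the simulated assay window is positive and below the noiseless maximum
  expect_gt(qc$screen$zprime_ccl2, 0)
  expect_lt(qc$screen$zprime_ccl2, 1)
})
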