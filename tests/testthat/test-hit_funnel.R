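test_that("primary filter applies the effect/variability/cytotoxicity rules in order", {
  s <- make_summaries(
    make_normalized("C01", c(0.74, 0.76)),            # -25%, CV ~1.9%
    make_normalized("C02", c(1.10, 1.10)),            # +10%: sub-threshold
    make_normalized("C03", c(0.40, 0.44), cell_ratio = 0.35),  # cytotoxic
    make_normalized("C04", c(1.30, 1.34)))            # +32% induction
  out <- primary_filter(s)
  v <- setNames(out$verdict, out$compound_id)
  expect_equal(v[["C01"]], "hit_down")
  expect_equal(v[["C02"]], "not_hit")
  expect_equal(v[["C03"]], "excluded_cytotoxic")  # pre-empts the -58% effect
  expect_equal(v[["C04"]], "hit_up")
  expect_equal(out$percent_change_ccl2[out$compound_id == "C01"], -25)
})

test_that("single-replicate compounds are refused by name", {
  s <- make_summaries(make_normalized("C09", 0.7))
  expect_error(primary_filter(s), "C09",
               class = "screenfunnel_insufficient_replicates")
})

test_that("secondary filter confirms only primary hits and rejects variable triplicates", {
  s <- make_summaries(
    make_normalized("C01", c(0.70, 0.75, 0.72)),   # -27.7%, CV ~3.5%
    make_normalized("C02", c(0.60, 1.00, 1.10)),   # CV ~29%: too variable
    make_normalized("C03", c(0.72, 0.74, 0.73)))   # would pass, not a primary hit
  out <- secondary_filter(s, primary_hits = c("C01", "C02"))
  v <- setNames(out$verdict, out$compound_id)
  expect_equal(v[["C01"]], "hit_down")
  expect_equal(v[["C02"]], "excluded_variable")
  expect_equal(v[["C03"]], "not_evaluated")
  expect_error(secondary_filter(make_summaries(make_normalized("C04", c(1, 1)))),
               class = "screenfunnel_insufficient_replicates")
})

test_that("thresholds are sharp: inclusive on effect, strict on cell loss", {
  s <- make_summaries(
    make_normalized("E01", c(0.80, 0.80)),
    make_normalized("E02", c(1.20, 1.20)),
    make_normalized("E03", c(0.801, 0.801)),
    make_normalized("E04", c(1.199, 1.199)),
    make_normalized("E05", c(0.5, 0.5), cell_ratio = 0.5))
  v <- setNames(primary_filter(s)$verdict, s$compound_id)
  expect_equal(v[["E01"]], "hit_down")
  expect_equal(v[["E02"]], "hit_up")
  expect_equal(v[["E03"]], "not_hit")
  expect_equal(v[["E04"]], "not_hit")
  expect_equal(v[["E05"]], "excluded_cytotoxic")
})

test_that("direction comes from the larger-magnitude qualifying channel", {
  s <- make_summaries(
    make_normalized("D01", c(0.75, 0.75), c(1.40, 1.40)),
    make_normalized("D02", c(0.60, 0.60), c(1.25, 1.25)))
  out <- primary_filter(s)
  expect_equal(out$verdict[out$compound_id == "D01"], "hit_up")    # +40 beats -25
  expect_equal(out$verdict[out$compound_id == "D02"], "hit_down")  # -40 beats +25
})

test_that("dose selection maximises effect among tolerated doses with tie-breaks", {
  ter <- make_summaries(
    make_normalized("C01", c(0.90, 0.90), concentration_um = 0.1),
    make_normalized("C01", c(0.70, 0.70), concentration_um = 1),
    make_normalized("C01", c(0.55, 0.55), cell_ratio = 0.3,
                    concentration_um = 10))
  d <- dose_select(ter)
  expect_equal(d$chosen_dose, 1)
  expect_equal(d$verdict, "hit_down")

  # all doses inert: not_hit at the max-|effect| dose
  inert <- make_summaries(
    make_normalized("C02", c(0.95, 0.95), concentration_um = 0.1),
    make_normalized("C02", c(0.90, 0.90), concentration_um = 1))
  d2 <- dose_select(inert)
  expect_equal(d2$verdict, "not_hit")
  expect_equal(d2$chosen_dose, 1)

  # tied effect: the higher cell ratio wins
  tie <- make_summaries(
    make_normalized("C03", c(0.70, 0.70), cell_ratio = 0.9,
                    concentration_um = 1),
    make_normalized("C03", c(0.70, 0.70), cell_ratio = 0.7,
                    concentration_um = 10))
  expect_equal(dose_select(tie)$chosen_dose, 1)

  # no tolerated dose at all
  tox <- make_summaries(
    make_normalized("C04", c(0.5, 0.5), cell_ratio = 0.4,
                    concentration_um = 1),
    make_normalized("C04", c(0.4, 0.4), cell_ratio = 0.2,
                    concentration_um = 10))
  expect_equal(dose_select(tox)$verdict, "excluded_cytotoxic")
})

test_that("stimulus-independent effects are flagged above the basal threshold", {
  s <- make_summaries(
    make_normalized("C01", c(1.02, 1.02)),
    make_normalized("C02", c(1.45, 1.45)),
    make_normalized("C03", c(0.70, 0.70)))
  flags <- independence_check(s)
  f <- setNames(flags$flag, flags$compound_id)
  expect_equal(f[["C01"]], "none")
  expect_equal(f[["C02"]], "basal_up")
  expect_equal(f[["C03"]], "basal_down")

  # simulator with all basal effects at 1 and zero noise: zero flags
  cfg <- sim_config(n_compounds = 40, fraction_modulators = 0.2,
                    basal_sd = 0, seed = 14)
  sim <- simulate_screen(cfg, noise_model(well_cv = 0, plate_sigma = 0),
                         "independence")
  res <- run_tier(sim$dataset)$result
  expect_true(all(res$flag == "none"))
})

test_that("ranking diversifies by therapeutic class deterministically", {
  s <- make_summaries(
    make_normalized("A1", c(0.50, 0.50)), make_normalized("A2", c(0.55, 0.55)),
    make_normalized("A3", c(0.60, 0.60)), make_normalized("B1", c(0.70, 0.70)),
    make_normalized("B2", c(0.72, 0.72)), make_normalized("C1", c(0.74, 0.74)))
  conf <- primary_filter(s)
  ann <- tibble::tibble(
    compound_id = c("A1", "A2", "A3", "B1", "B2", "C1"),
    therapeutic_class = c("cardiotonic", "cardiotonic", "cardiotonic",
                          "anti-bacterial", "anti-bacterial", "anti-asthmatic"))
  top <- rank_and_diversify(conf, ann, k = 4, max_per_class = 2)
  # top-2 cardiotonics (A1 -50%, A2 -45%) then the next best of other classes
  expect_equal(top$compound_id, c("A1", "A2", "B1", "B2"))
  expect_equal(attr(top, "shortfall"), 0L)

  # k beyond availability reports the shortfall
  all6 <- rank_and_diversify(conf, ann, k = 10, max_per_class = 3)
  expect_equal(attr(all6, "shortfall"), 10L - nrow(all6))

  # identical effects tie-break lexicographically on compound id
  tied <- primary_filter(make_summaries(
    make_normalized("Z9", c(0.7, 0.7)), make_normalized("A0", c(0.7, 0.7))))
  expect_equal(rank_and_diversify(tied, NULL, k = 2)$compound_id[1], "A0")
  expect_error(rank_and_diversify(conf, ann, k = 0), "positive")
})

test_that("verdicts are invariant to well-row permutation", {
  cfg <- sim_config(n_compounds = 60, fraction_modulators = 0.2,
                    fraction_cytotoxic = 0.1, seed = 8)
  sim <- simulate_screen(cfg, noise_model(), "primary")
  r1 <- run_tier(sim$dataset)$result
  shuffled <- sim$dataset
  set.seed(99)
  shuffled$wells <- shuffled$wells[sample(nrow(shuffled$wells)), ]
  r2 <- run_tier(shuffled)$result
  expect_equal(r1, r2)
})

test_that("the funnel is monotone: secondary hits are primary hits", {
  cfg <- sim_config(n_compounds = 78, fraction_modulators = 0.25,
                    fraction_cytotoxic = 0.05, seed = 17)
  prim <- run_tier(simulate_screen(cfg, noise_model(), "primary")$dataset)
  p_hits <- hit_ids(prim$result)
  sec <- run_tier(simulate_screen(cfg, noise_model(), "secondary")$dataset,
                  primary_hits = p_hits)
  s_hits <- hit_ids(sec$result)
  expect_true(all(s_hits %in% p_hits))
  short <- rank_and_diversify(sec$result, NULL, k = 5)
  expect_true(all(short$compound_id %in% s_hits))
})
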