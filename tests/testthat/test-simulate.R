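zero_noise_config <- function(seed = 1, ...) {
  cohort_config(
    seed = seed,
    sigma_u = 0,
    glyc_noise = c(G6P = 0, F6P = 0, F16BP = 0, DHAP = 0, PG23 = 0,
                   PEP = 0, PYR = 0),
    coupling = utils::modifyList(default_coupling(),
                                 list(tau_t1 = 0, tau_t2 = 0)),
    noise = list(cv_sample_analyte = 0, cv_channel = 0, enzyme_cv = 0,
                 absorbance_sd = 0, ocr_animal_cv = 0, ocr_stage_cv = 0),
    tissue_cv = 0, is_cv = 0,
    body_weight = c(nose_mean = 39.8, nose_sd = 0, se_mean = 39.8,
                    se_sd = 0),
    ...)
}

no_effect_table <- function() {
  dplyr::mutate(default_effect_table(), effect = 0)
}

equal_conc <- function() {
  d <- default_concentrations()
  dplyr::mutate(d, mean_se = .data$mean_nose, sem_nose = 0, sem_se = 0)
}

test_that("the default effect table carries the configured group effects", {
  eff <- default_effect_table()
  pick <- function(domain, target)
    eff$effect[eff$domain == domain & eff$target == target]
  expect_equal(pick("glycolysis", "G6P"), 0.22)
  expect_equal(pick("glycolysis", "F6P"), 0.21)
  expect_equal(pick("glycolysis", "DHAP"), 0.17)
  expect_equal(pick("glycolysis", "PEP"), 0.20)
  expect_equal(pick("tca_turn1", "SUC"), 0.35)
  expect_equal(pick("tca_turn1", "MAL"), 0)
  expect_equal(pick("tca_turn2", "OG2"), 0.47)
  expect_equal(pick("tca_turn2", "SUC"), 0.55)
  expect_equal(pick("enzyme", "PDH"), 0.33)
  expect_equal(pick("enzyme", "OGDH"), 0.55)
  expect_true(all(eff$effect[eff$domain == "ocr"] == 0))
})

test_that("generation is deterministic for a fixed seed", {
  a <- generate_cohort(cohort_config(seed = 123))
  b <- generate_cohort(cohort_config(seed = 123))
  expect_identical(a$peaks, b$peaks)
  expect_identical(a$traces, b$traces)
  expect_identical(a$ocr_coupling, b$ocr_coupling)
  expect_identical(a$truth$enrichment, b$truth$enrichment)
  c <- generate_cohort(cohort_config(seed = 124))
  expect_false(identical(a$peaks, c$peaks))
})

test_that("zero noise and zero effects make the groups identical", {
  cfg <- zero_noise_config(effect_table = no_effect_table(),
                           concentrations = equal_conc())
  co <- generate_cohort(cfg)
  enr <- dplyr::left_join(co$truth$enrichment,
                          dplyr::select(co$samples, "sample", "group"),
                          by = "sample")
  by_group <- dplyr::summarise(
    dplyr::group_by(enr, .data$metabolite, .data$turn, .data$group),
    m = mean(.data$enrichment), s = sd(.data$enrichment), .groups = "drop")
  expect_true(all(by_group$s == 0))
  wide <- tidyr::pivot_wider(by_group[, -5], names_from = "group",
                             values_from = "m")
  expect_equal(wide$NoSE, wide$SE)
  act <- dplyr::summarise(dplyr::group_by(co$truth$activity, .data$enzyme,
                                          .data$group),
                          m = mean(.data$activity), s = sd(.data$activity),
                          .groups = "drop")
  expect_true(all(act$s == 0))
  act_w <- tidyr::pivot_wider(act[, c("enzyme", "group", "m")],
                              names_from = "group", values_from = "m")
  expect_equal(act_w$NoSE, act_w$SE)
})

test_that("zero measurement noise makes pipeline enrichment equal the latent truth", {
  cfg <- zero_noise_config(seed = 5)
  # keep biological spread but no measurement noise
  cfg$sigma_u <- 0.25
  cfg$coupling$tau_t1 <- 0.25
  co <- generate_cohort(cfg)
  enr <- percent_enrichment(co$peaks)
  chk <- dplyr::inner_join(enr, co$truth$enrichment,
                           by = c("sample", "metabolite", "turn"),
                           suffix = c("", ".true"))
  expect_equal(chk$enrichment, chk$enrichment.true, tolerance = 1e-12)
  expect_true(all(co$peaks$area >= 0))
})

test_that("configured SE effects are recovered by the pipeline on average", {
  des <- design_transitions()
  reds <- vapply(1:30, function(s) {
    co <- generate_cohort(cohort_config(seed = 1000 + s), design = des)
    enr <- dplyr::left_join(percent_enrichment(co$peaks, des),
                            dplyr::select(co$samples, "sample", "group"),
                            by = "sample")
    g6p <- enr[enr$metabolite == "G6P", ]
    100 * (1 - mean(g6p$enrichment[g6p$group == "SE"]) /
             mean(g6p$enrichment[g6p$group == "NoSE"]))
  }, numeric(1))
  expect_lt(abs(mean(reds) - 22), 5)
})

test_that("invalid configurations are rejected", {
  eff <- default_effect_table()
  eff$effect[eff$target == "G6P" & eff$domain == "glycolysis"] <- 1.2
  expect_error(cohort_config(effect_table = eff), "fractions")
  expect_error(cohort_config(n_nose = 2), "at least 3")
  cp <- default_coupling()
  cp$pyr_loading[["OG2"]] <- 0.99  # with mito loading 0.58 exceeds unit var
  expect_error(cohort_config(coupling = cp), "loadings")
})

test_that("generated OCR profiles have no group effect and valid stages", {
  co <- generate_cohort(cohort_config(seed = 9))
  expect_true(all(co$ocr_coupling$state3adp > co$ocr_coupling$state4o))
  cp <- coupling_params(co$ocr_coupling)
  expect_true(all(cp$coupling_efficiency > 0 & cp$coupling_efficiency < 1))
  ef <- electron_flow_params(co$ocr_electron)
  expect_true(all(ef$complexI > 0 & ef$complexII > 0))
})
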