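line_trace <- function(slope_au_min, n = 31, dt = 10, start = 1, sd = 0) {
  t <- seq(0, by = dt, length.out = n)
  tibble::tibble(time_s = t,
                 absorbance = start + slope_au_min * t / 60 + rnorm(n, 0, sd))
}

test_that("specific activity converts slopes via Beer-Lambert and protein", {
  # flat trace: zero activity, full window
  flat <- specific_activity(line_trace(0), epsilon = 6.22, path_length = 1,
                            protein = 0.01, volume_ml = 1)
  expect_equal(flat$activity, 0)
  expect_equal(flat$window_end, 31L)

  # exact line: 0.0622 AU/min, eps 6.22, 1 cm, 1 mL, 0.01 mg -> 1000
  act <- specific_activity(line_trace(-0.0622), epsilon = 6.22,
                           path_length = 1, protein = 0.01, volume_ml = 1)
  expect_equal(act$activity, 1000, tolerance = 1e-9)
  expect_equal(act$slope, -0.0622, tolerance = 1e-9)
  expect_equal(act$r_squared, 1)
})

test_that("noisy traces recover the configured slope within 5 percent", {
  set.seed(7)
  for (i in 1:20) {
    tr <- line_trace(0.05, sd = 8e-4, start = 0.05)
    act <- specific_activity(tr, epsilon = 6.22, path_length = 0.55,
                             protein = 0.02, volume_ml = 0.2)
    truth <- 0.05 / (6.22 * 0.55) * 0.2 * 1000 / 0.02
    expect_lt(abs(act$activity / truth - 1), 0.05)
  }
})

test_that("the linear window stops before substrate depletion", {
  # linear for 150 s, then plateau
  t <- seq(0, 300, 10)
  y <- ifelse(t <= 150, 1.2 - 0.002 * t, 1.2 - 0.002 * 150)
  act <- specific_activity(tibble::tibble(time_s = t, absorbance = y),
                           epsilon = 6.22, path_length = 1, protein = 0.01,
                           volume_ml = 1)
  expect_lt(act$window_end, length(t))
  expect_lt(abs(act$slope - (-0.12)), 0.02)
})

test_that("traces with no linear window are flagged rather than extrapolated", {
  set.seed(8)
  t <- seq(0, 300, 10)
  y <- 0.5 + rnorm(length(t), 0, 0.05)  # pure noise, no trend
  act <- specific_activity(tibble::tibble(time_s = t, absorbance = y),
                           epsilon = 6.22, path_length = 1, protein = 0.01,
                           volume_ml = 1)
  expect_true(is.na(act$activity))
  expect_equal(act$flag, "no_linear_window")
  expect_error(specific_activity(line_trace(0.01, n = 3), 6.22), "points")
  expect_error(specific_activity(line_trace(0.01), epsilon = -1), "positive")
})

test_that("coupling parameters implement the stage arithmetic", {
  p <- tibble::tibble(sample = "m1", state2 = 45, state3adp = 100,
                      state4o = 40, state3u = 120, nonmito = 10, protein = 1)
  out <- coupling_params(p)
  expect_equal(out$atp_linked, 60)           # (100-10) - (40-10)
  expect_equal(out$rcr, 3)                   # 90 / 30
  expect_equal(out$coupling_efficiency, 60 / 90)
  expect_equal(out$state3u, 110)

  # all stages equal to nonmito: every parameter 0, RCR undefined
  z <- tibble::tibble(state2 = 10, state3adp = 10, state4o = 10,
                      state3u = 10, nonmito = 10, protein = 2)
  zo <- coupling_params(z)
  expect_equal(zo$atp_linked, 0)
  expect_true(is.na(zo$rcr))
  expect_equal(zo$flag, "rcr_undefined")
})

test_that("electron flow parameters implement the stage arithmetic", {
  p <- tibble::tibble(state3u = 120, post_rotenone = 30, post_succinate = 90,
                      post_malonate = 20, nonmito = 0, protein = 1)
  out <- electron_flow_params(p)
  expect_equal(out$complexI, 90)
  expect_equal(out$complexII, 70)

  zero <- tibble::tibble(state3u = 0, post_rotenone = 0, post_succinate = 0,
                         post_malonate = 0, nonmito = 0, protein = 1)
  zo <- electron_flow_params(zero)
  expect_equal(zo$complexI, 0)
  expect_equal(zo$complexII, 0)

  neg <- tibble::tibble(state3u = 20, post_rotenone = 30, post_succinate = 90,
                        post_malonate = 20, nonmito = 0, protein = 1)
  expect_equal(electron_flow_params(neg)$flag, "negative_respiration")
})

test_that("mito parameters are invariant to a common stage offset and scale with protein", {
  p <- tibble::tibble(state2 = 45, state3adp = 280, state4o = 60,
                      state3u = 320, nonmito = 12, protein = 0.004)
  shifted <- dplyr::mutate(p, dplyr::across(
    c("state2", "state3adp", "state4o", "state3u", "nonmito"), ~ .x + 25))
  expect_equal(coupling_params(p)$atp_linked,
               coupling_params(shifted)$atp_linked)
  expect_equal(coupling_params(p)$rcr, coupling_params(shifted)$rcr)
  doubled <- dplyr::mutate(p, protein = protein * 2)
  expect_equal(coupling_params(doubled)$atp_linked,
               coupling_params(p)$atp_linked / 2)
})
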