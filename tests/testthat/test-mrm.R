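test_that("nominal bases round the instrument masses to integers", {
  b <- nominal_bases()
  expect_equal(b[b$analyte == "CIT", c("base_q1", "base_q3")],
               tibble::tibble(base_q1 = 191L, base_q3 = 111L))
  expect_equal(b[b$analyte == "SUC", c("base_q1", "base_q3")],
               tibble::tibble(base_q1 = 117L, base_q3 = 73L))
  # integer inputs pass through unchanged
  tab <- tibble::tibble(Analyte = "X", Q1 = 120, Q3 = 75, RT = 1,
                        DP = -10, CE = -10, CXP = -5)
  expect_equal(nominal_bases(tab),
               tibble::tibble(analyte = "X", base_q1 = 120L, base_q3 = 75L))
})

test_that("labeled transitions follow the fragment rules per analyte", {
  # phosphate fragment: Q3 independent of labeling
  g6p <- labeled_transitions("G6P", new_pool("G6P", "111111"))
  expect_equal(g6p[, c("q1", "q3")], tibble::tibble(q1 = 265, q3 = 97))
  # pyruvate loses its labeled carboxyl
  pyr <- labeled_transitions("PYR", new_pool("PYR", "111"))
  expect_equal(pyr[, c("q1", "q3")], tibble::tibble(q1 = 90, q3 = 45))
  # citrate first turn: one or both acetyl labels survive the carboxyl loss
  cit <- labeled_transitions("CIT", new_pool("CIT", "110000"))
  expect_equal(cit$q1, c(193, 193))
  expect_equal(sort(cit$q3), c(112, 113))
  # an unlabeled pool reproduces the instrument-decimal transition
  unl <- labeled_transitions("CIT", new_pool("CIT", "000000"))
  expect_equal(unl$q1, 190.96)
  expect_equal(unl$q3, 110.9)
  # instrument parameters are copied from the unlabeled analyte
  expect_true(all(cit$rt == 22.6 & cit$dp == -50))
})

test_that("second-turn transitions cover both 2OG precursor channels", {
  pools <- propagate(tracer = "111111")
  og2 <- labeled_transitions("OG2", pools[pools$metabolite == "OG2" &
                                            pools$turn == 2, ])
  expect_equal(og2[, c("q1", "q3")],
               tibble::tibble(q1 = c(148, 148, 149), q3 = c(103, 104, 104)))
  suc <- labeled_transitions("SUC", pools[pools$metabolite == "SUC" &
                                            pools$turn == 2, ])
  expect_equal(suc$q1, c(120, 120))
  expect_equal(sort(suc$q3), c(75, 76))
})

test_that("q1 offsets equal the pool mass shift and phosphate q3 is label-invariant", {
  design <- design_transitions()
  bases <- nominal_bases()
  lab <- dplyr::inner_join(design[design$precursor_shift > 0, ], bases,
                           by = "analyte")
  expect_true(all(lab$q1 - lab$base_q1 == lab$precursor_shift))
  phos <- lab[lab$analyte %in% c("G6P", "F6P", "F16BP", "DHAP", "PG23"), ]
  expect_true(all(phos$q3 == 97))
  expect_true(all(lab$q3[lab$analyte == "PEP"] == 79))
  expect_true(all(lab$q3 < lab$q1))
})

test_that("carboxyl-loss q3 shifts match direct enumeration over pool masks", {
  pools <- propagate(tracer = "111111")
  rules <- fragment_rules()
  for (met in c("CIT", "OG2", "SUC", "FUM", "MAL")) {
    lost_sets <- rules$lost[[which(rules$analyte == met)]]
    for (turn in 1:2) {
      pool <- pools[pools$metabolite == met & pools$turn == turn, ]
      expected <- unique(unlist(lapply(pool$mask, function(m) {
        bits <- strsplit(m, "")[[1]] == "1"
        vapply(lost_sets, function(ls) sum(bits) - sum(bits[ls]), numeric(1))
      })))
      got <- labeled_transitions(met, pool)
      expect_setequal(got$product_shift, expected)
    }
  }
})

test_that("transition tables round-trip through CSV exactly", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  design <- design_transitions()
  write_transition_table(design, tmp)
  header <- readLines(tmp, n = 1)
  expect_equal(header, "Analyte,PrecursorShift,ProductShift,Q1,Q3,RT,DP,CE,CXP")
  back <- read_transition_table(tmp)
  expect_equal(back$q1, design$q1)
  expect_equal(back$q3, design$q3)
  expect_equal(back$analyte, design$analyte)
  expect_equal(back$rt, design$rt)

  # empty list -> header-only file
  write_transition_table(design[0, ], tmp)
  expect_equal(length(readLines(tmp)), 1L)
})

test_that("the full uniform-tracer design contains the expected channel counts", {
  design <- design_transitions()
  lab <- design[design$precursor_shift > 0, ]
  # one labeled channel per glycolytic analyte
  glyc <- lab[lab$analyte %in% c("G6P", "F6P", "F16BP", "DHAP", "PG23",
                                 "PEP", "PYR"), ]
  expect_equal(nrow(glyc), 7L)
  # two product ions per TCA analyte per turn, except the extra 2OG M+4
  tca <- lab[!lab$analyte %in% glyc$analyte, ]
  expect_equal(nrow(tca), 6L * 2L * 2L + 1L)
  # every analyte keeps its unlabeled channel
  expect_equal(sum(design$precursor_shift == 0), 13L)
})
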