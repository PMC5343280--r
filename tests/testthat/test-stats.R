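test_that("two-way ANOVA matches the closed-form decomposition on balanced data", {
  set.seed(11)
  d <- expand.grid(g = c("NoSE", "SE"), m = c("G6P", "F6P", "PEP"),
                   rep = 1:5, KEEP.OUT.ATTRS = FALSE)
  d$y <- rnorm(nrow(d), mean = ifelse(d$g == "SE", -1, 0) +
                 as.numeric(factor(d$m)))
  av <- two_way_anova(d, "y", "g", "m")
  oracle <- balanced_twoway_ss(d$y, d$g, d$m)
  expect_equal(av$terms$sumsq, c(oracle$a, oracle$b, oracle$ab),
               tolerance = 1e-10)
  expect_equal(av$rss, oracle$resid, tolerance = 1e-10)
  expect_equal(av$df_residual, nrow(d) - 6L)
})

test_that("type III sums of squares on unbalanced data match car::Anova", {
  skip_if_not_installed("car")
  set.seed(21)
  d <- data.frame(g = rep(c("NoSE", "SE"), c(11, 10)))
  d <- do.call(rbind, lapply(c("G6P", "SUC", "MAL"), function(m)
    transform(d, m = m)))
  d <- d[-c(3, 25, 40), ]  # make it unbalanced
  d$y <- rnorm(nrow(d)) + (d$g == "SE") * (d$m == "SUC") * 1.5
  av <- two_way_anova(d, "y", "g", "m")

  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- lm(y ~ g * m, data = d)
  ca <- car::Anova(fit, type = 3)
  expect_equal(av$terms$sumsq, ca[c("g", "m", "g:m"), "Sum Sq"],
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(av$terms$p.value, ca[c("g", "m", "g:m"), "Pr(>F)"],
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("degenerate and invalid ANOVA inputs are handled explicitly", {
  d <- expand.grid(g = c("a", "b"), m = c("x", "y"), rep = 1:3)
  d$y <- 5
  av <- two_way_anova(d, "y", "g", "m")
  expect_equal(av$terms$sumsq, rep(0, 3))
  expect_equal(av$terms$statistic, rep(0, 3))

  d2 <- d[!(d$g == "a" & d$m == "x"), ]
  d2$y <- rnorm(nrow(d2))
  expect_error(two_way_anova(d2, "y", "g", "m"), "empty cell")
  d$y[1] <- NA
  expect_error(two_way_anova(d, "y", "g", "m"), "non-finite")
})

test_that("a pure group shift rarely produces large interaction statistics", {
  set.seed(31)
  hits <- 0L
  crit <- stats::qf(0.95, 2, 54)
  for (i in 1:200) {
    d <- expand.grid(g = c("a", "b"), m = c("x", "y", "z"), rep = 1:10)
    d$y <- rnorm(nrow(d)) + (d$g == "b") * 2
    av <- two_way_anova(d, "y", "g", "m")
    f_int <- av$terms$statistic[3]
    if (f_int < crit) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.9)
})

test_that("Fisher LSD uses the pooled residual MS and matches hand arithmetic", {
  # known MS: lsd_contrast with MS 4, means 10 vs 6, n 4/4 -> t = 2.828
  ct <- lsd_contrast(10, 6, 4, 4, ms = 4, df = 6)
  expect_equal(ct$statistic, 2 * sqrt(2), tolerance = 1e-12)

  # equal group means -> t = 0, p = 1
  d <- expand.grid(g = c("a", "b"), m = c("x", "y"), rep = 1:4)
  # cell means equal across groups; replicate-level jitter keeps MS_resid > 0
  d$y <- rep(c(1, 1, 3, 3), 4) + rep(c(0.1, -0.1), each = 4, length.out = 16)
  av <- two_way_anova(d, "y", "g", "m")
  lsd <- fisher_lsd(av)
  expect_equal(lsd$estimate, c(0, 0))
  expect_equal(lsd$p.value, c(1, 1))

  # with the pooled variance as MS, the LSD contrast is the pooled t test
  set.seed(41)
  x <- rnorm(8, 10); y <- rnorm(9, 8)
  pooled <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  ct2 <- lsd_contrast(mean(x), mean(y), length(x), length(y),
                      ms = pooled, df = length(x) + length(y) - 2)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(ct2$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(ct2$p.value, tt$p.value, tolerance = 1e-12)
})

test_that("fisher_lsd reports per-metabolite group means and df from the model", {
  set.seed(51)
  d <- expand.grid(g = c("NoSE", "SE"), m = c("G6P", "SUC"), rep = 1:6)
  d$y <- rnorm(nrow(d)) + (d$g == "SE" & d$m == "SUC") * 3
  av <- two_way_anova(d, "y", "g", "m")
  lsd <- fisher_lsd(av)
  expect_equal(lsd$df, rep(av$df_residual, 2))
  expect_equal(lsd$mean_NoSE[lsd$m == "G6P"],
               mean(d$y[d$g == "NoSE" & d$m == "G6P"]))
  expect_true(lsd$significant[lsd$m == "SUC"])
})

test_that("Pearson correlation matches the direct formula and handles edge cases", {
  x <- c(1, 2, 4, 7, 9)
  y <- c(2, 1, 5, 8, 8)
  ct <- pearson_cor(x, y)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ct$estimate, r_direct, tolerance = 1e-12)
  t_direct <- r_direct * sqrt((5 - 2) / (1 - r_direct^2))
  expect_equal(ct$p.value, 2 * pt(abs(t_direct), 3, lower.tail = FALSE),
               tolerance = 1e-12)

  expect_equal(pearson_cor(x, x)$estimate, 1)
  expect_equal(pearson_cor(x, -x)$estimate, -1)
  # affine invariance with positive slope, sign flip with negative
  expect_equal(pearson_cor(2 * x + 3, y)$estimate, ct$estimate)
  expect_equal(pearson_cor(-2 * x + 3, y)$estimate, -ct$estimate)
  expect_equal(pearson_cor(rep(1, 5), y)$flag, "constant_input")
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
})

test_that("unpaired t test pools variances and flags degenerate input", {
  expect_equal(unpaired_t(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(unpaired_t(c(1, 2, 3), c(1, 2, 3))$p.value, 1)

  x <- c(5, 7, 9, 11); y <- c(4, 6, 8)
  tt <- unpaired_t(x, y)
  pooled <- ((3) * var(x) + (2) * var(y)) / 5
  t_hand <- (mean(x) - mean(y)) / sqrt(pooled * (1 / 4 + 1 / 3))
  expect_equal(tt$statistic, t_hand, tolerance = 1e-12)
  expect_equal(tt$df, 5L)

  expect_equal(unpaired_t(c(1, 1), c(1, 1))$p.value, 1)
  expect_equal(unpaired_t(c(1, 1), c(2, 2))$flag, "degenerate")
})
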