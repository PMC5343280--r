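# Statistical battery: two-way type III ANOVA with uncorrected Fisher's LSD
# posttests, Pearson correlation, pooled-variance t tests.

#' Two-way ANOVA with interaction (type III sums of squares)
#'
#' Fits the full-factorial linear model `value ~ A * B` with sum-to-zero
#' contrasts and computes partial (type III) sums of squares by model
#' comparison: the SS of each effect is the increase in residual SS when its
#' columns are dropped from the full model matrix. Type III SS are used so
#' that unbalanced cells are handled the way mainstream commercial packages
#' do; type II is available via `ss_type = 2`.
#'
#' @param data Data frame with the response and two factor columns.
#' @param value,factor_a,factor_b Column names (strings) of the response and
#'   the two factors.
#' @param ss_type 3 (default) or 2.
#' @return An object of class `glucotrace_anova`; see [tidy()] and
#'   [glance()] methods. Contains per-effect SS, df, F and p, plus residual
#'   MS/df and cell means.
#' @examples
#' df <- expand.grid(g = c("a", "b"), m = c("x", "y"), rep = 1:4)
#' df$y <- rnorm(nrow(df))
#' tidy(two_way_anova(df, "y", "g", "m"))
#' @export
two_way_anova <- function(data, value, factor_a, factor_b, ss_type = 3) {
  y <- data[[value]]
  A <- factor(data[[factor_a]])
  B <- factor(data[[factor_b]])
  if (!all(is.finite(y))) abort("response contains non-finite values")
  if (nlevels(A) < 2 || nlevels(B) < 2)
    abort("both factors need at least 2 levels")
  counts <- table(A, B)
  if (any(counts == 0)) {
    empty <- which(counts == 0, arr.ind = TRUE)
    abort(paste0("empty cell(s): ",
                 paste(sprintf("%s:%s", rownames(counts)[empty[, 1]],
                               colnames(counts)[empty[, 2]]),
                       collapse = ", ")))
  }
  if (!ss_type %in% c(2, 3)) abort("ss_type must be 2 or 3")

  mm <- stats::model.matrix(~ A * B,
                            contrasts.arg = list(A = "contr.sum",
                                                 B = "contr.sum"))
  asg <- attr(mm, "assign")  # 0 intercept, 1 A, 2 B, 3 A:B
  rss <- function(cols) {
    fit <- lm.fit(mm[, cols, drop = FALSE], y)
    sum(fit$residuals^2)
  }
  rss_full <- rss(seq_len(ncol(mm)))
  ss_total <- sum((y - mean(y))^2)
  # constant response: every decomposition is exactly zero
  if (ss_total == 0) rss_full <- 0
  df_resid <- length(y) - qr(mm)$rank
  ms_resid <- if (df_resid > 0) rss_full / df_resid else NA_real_

  effect_ss <- function(term) {
    if (ss_type == 3) {
      keep <- which(asg != term)
    } else {
      # type II: respect marginality - drop the term from the model that
      # contains all other terms not containing it
      base_terms <- switch(as.character(term),
                           "1" = c(0, 2), "2" = c(0, 1), "3" = c(0, 1, 2))
      keep <- which(asg %in% base_terms)
      return(rss(keep) - rss(c(keep, which(asg == term))))
    }
    rss(keep) - rss_full
  }
  terms <- c(factor_a, factor_b, paste0(factor_a, ":", factor_b))
  df_eff <- c(nlevels(A) - 1L, nlevels(B) - 1L,
              (nlevels(A) - 1L) * (nlevels(B) - 1L))
  ss <- vapply(1:3, effect_ss, numeric(1))
  ss <- pmax(ss, 0)
  if (ss_total == 0) ss <- rep(0, 3)
  f <- (ss / df_eff) / ms_resid
  if (!is.na(ms_resid) && ms_resid == 0) f <- ifelse(ss == 0, 0, Inf)
  p <- if (is.na(ms_resid)) rep(NA_real_, 3) else pf(f, df_eff, df_resid,
                                                     lower.tail = FALSE)
  structure(list(
    terms = tibble::tibble(term = terms, sumsq = ss, df = df_eff,
                           statistic = f, p.value = p),
    rss = rss_full, df_residual = df_resid, ms_residual = ms_resid,
    n = length(y), ss_type = ss_type,
    data = tibble::tibble(value = y, a = A, b = B),
    factor_names = c(factor_a, factor_b),
    flag = if (df_resid == 0) "zero_residual_df" else NA_character_),
    class = "glucotrace_anova")
}

#' @export
print.glucotrace_anova <- function(x, ...) {
  cat(sprintf("Two-way ANOVA (type %s SS), n = %d\n", x$ss_type, x$n))
  print(x$terms)
  cat(sprintf("Residuals: SS = %.4g on %d df (MS = %.4g)\n",
              x$rss, x$df_residual, x$ms_residual))
  invisible(x)
}

#' @rdname two_way_anova
#' @param x A `glucotrace_anova` object.
#' @param ... Unused.
#' @export
tidy.glucotrace_anova <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$terms, meansq = .data$sumsq / .data$df,
                  .after = "df"),
    tibble::tibble(term = "Residuals", sumsq = x$rss, df = x$df_residual,
                   meansq = x$ms_residual, statistic = NA_real_,
                   p.value = NA_real_))
}

#' @rdname two_way_anova
#' @export
glance.glucotrace_anova <- function(x, ...) {
  tibble::tibble(n = x$n, df.residual = x$df_residual,
                 ms.residual = x$ms_residual, ss.type = x$ss_type,
                 flag = x$flag)
}

#' Single LSD contrast from a residual mean square
#'
#' The elementary Fisher-LSD arithmetic:
#' t = (mean1 - mean2) / sqrt(ms * (1/n1 + 1/n2)) on `df` degrees of freedom,
#' uncorrected two-sided p. With `ms` equal to the two groups' pooled
#' variance and `df = n1 + n2 - 2` this is exactly the pooled-variance t
#' test.
#'
#' @param mean1,mean2 Group means.
#' @param n1,n2 Group sizes.
#' @param ms Residual (pooled) mean square.
#' @param df Residual degrees of freedom.
#' @return One-row tibble: estimate, statistic, df, p.value.
#' @export
lsd_contrast <- function(mean1, mean2, n1, n2, ms, df) {
  se <- sqrt(ms * (1 / n1 + 1 / n2))
  t <- (mean1 - mean2) / se
  tibble::tibble(estimate = mean1 - mean2, statistic = t, df = df,
                 p.value = 2 * pt(abs(t), df, lower.tail = FALSE))
}

#' Uncorrected Fisher's LSD posttests after a two-way ANOVA
#'
#' For each level of the second (within) factor, compares the two levels of
#' the first (between) factor using the pooled residual mean square of the
#' full two-way model:
#' t = (mean1 - mean2) / sqrt(MS_resid * (1/n1 + 1/n2)) on the residual df,
#' with uncorrected two-sided p values.
#'
#' @param anova A `glucotrace_anova` fitted on the same data.
#' @param alpha Significance threshold used for the `significant` column.
#' @return Tibble: one row per within-factor level with group means, the mean
#'   difference, t, df, p and a significance flag.
#' @export
fisher_lsd <- function(anova, alpha = 0.05) {
  stopifnot(inherits(anova, "glucotrace_anova"))
  d <- anova$data
  if (nlevels(d$a) != 2L)
    abort("fisher_lsd expects a two-level between factor (first factor)")
  lv <- levels(d$a)
  ms <- anova$ms_residual
  df <- anova$df_residual
  out <- lapply(levels(d$b), function(bl) {
    di <- d[d$b == bl, ]
    n1 <- sum(di$a == lv[1]); n2 <- sum(di$a == lv[2])
    m1 <- mean(di$value[di$a == lv[1]])
    m2 <- mean(di$value[di$a == lv[2]])
    se <- sqrt(ms * (1 / n1 + 1 / n2))
    t <- (m1 - m2) / se
    tibble::tibble(level = bl, mean_1 = m1, mean_2 = m2, n_1 = n1, n_2 = n2,
                   estimate = m1 - m2, statistic = t, df = df,
                   p.value = 2 * pt(abs(t), df, lower.tail = FALSE))
  })
  out <- dplyr::bind_rows(out)
  names(out)[names(out) == "level"] <- anova$factor_names[2]
  names(out)[names(out) == "mean_1"] <- paste0("mean_", lv[1])
  names(out)[names(out) == "mean_2"] <- paste0("mean_", lv[2])
  dplyr::mutate(out, significant = .data$p.value < alpha)
}

#' Pearson correlation with two-sided p value
#'
#' Sample Pearson r with p from t = r * sqrt((n - 2) / (1 - r^2)) on n - 2
#' degrees of freedom (two-sided), as in [stats::cor.test()]. Constant input
#' vectors yield `NA` with a `constant_input` flag rather than an error.
#'
#' @param x,y Numeric vectors of equal length (pairs with missing values are
#'   dropped).
#' @return One-row tibble: estimate (r), n, statistic (t), df, p.value, flag.
#' @examples
#' pearson_cor(1:5, c(2, 4, 5, 4, 7))
#' @export
pearson_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("pearson_cor needs at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble::tibble(estimate = NA_real_, n = n, statistic = NA_real_,
                          df = n - 2L, p.value = NA_real_,
                          flag = "constant_input"))
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(estimate = unname(ct$estimate), n = n,
                 statistic = unname(ct$statistic),
                 df = as.integer(ct$parameter), p.value = ct$p.value,
                 flag = NA_character_)
}

#' Unpaired two-sided Student's t test (pooled variance)
#'
#' Classical equal-variance two-sample t test. Degenerate inputs with zero
#' pooled variance return t = 0, p = 1 when the means are equal, otherwise
#' `NA` with a `degenerate` flag.
#'
#' @param x,y Numeric vectors (the two groups).
#' @return One-row tibble: estimate (mean difference), mean_x, mean_y,
#'   statistic, df, p.value, flag.
#' @examples
#' unpaired_t(c(1, 2, 3), c(2, 3, 5))
#' @export
unpaired_t <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) abort("each group needs n >= 2")
  pooled <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  df <- length(x) + length(y) - 2L
  if (pooled == 0) {
    if (mean(x) == mean(y)) {
      return(tibble::tibble(estimate = 0, mean_x = mean(x), mean_y = mean(y),
                            statistic = 0, df = df, p.value = 1,
                            flag = NA_character_))
    }
    return(tibble::tibble(estimate = mean(x) - mean(y), mean_x = mean(x),
                          mean_y = mean(y), statistic = NA_real_, df = df,
                          p.value = NA_real_, flag = "degenerate"))
  }
  tt <- t.test(x, y, var.equal = TRUE, alternative = "two.sided")
  tibble::tibble(estimate = unname(tt$estimate[1] - tt$estimate[2]),
                 mean_x = unname(tt$estimate[1]),
                 mean_y = unname(tt$estimate[2]),
                 statistic = unname(tt$statistic),
                 df = as.integer(tt$parameter), p.value = tt$p.value,
                 flag = NA_character_)
}
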