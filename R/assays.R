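# Enzyme specific activities from continuous absorbance traces and
# mitochondrial respiration parameters from staged OCR profiles.

#' Enzyme specific activity from a continuous absorbance trace
#'
#' Fits the longest initial linear segment of the trace (minimum
#' `min_points` points, coefficient of determination >= `r2_min`) and converts
#' the absolute slope to a specific activity via Beer-Lambert:
#' activity = |slope| (AU/min) / (epsilon * path_length) * volume * 1000 /
#' protein, in nmol min^-1 mg protein^-1. If no window reaches the linearity
#' threshold the result is `NA` with a `no_linear_window` flag - the rate is
#' never extrapolated from a nonlinear trace. A perfectly flat trace is a
#' valid zero-activity fit.
#'
#' @param trace Data frame with columns `time_s` (strictly increasing seconds)
#'   and `absorbance` (AU); at least 5 points.
#' @param epsilon Molar extinction coefficient, mM^-1 cm^-1 (6.22 for
#'   NAD(P)H at 340 nm, 13.6 for TNB at 412 nm; MTT-formazan requires a
#'   per-assay calibration value).
#' @param path_length Optical path length in cm. Microplate assays have no
#'   1-cm path: pass the per-well value computed from the fill volume.
#' @param protein Protein in the reaction, mg.
#' @param volume_ml Reaction volume, mL.
#' @param r2_min,min_points Linearity window rule (defaults 0.98 and 5).
#' @return One-row tibble: activity (nmol/min/mg), slope (AU/min),
#'   window_start, window_end (indices), r_squared, flag.
#' @examples
#' tr <- tibble::tibble(time_s = seq(0, 300, 10),
#'                      absorbance = 1 - 0.001 * seq(0, 300, 10))
#' specific_activity(tr, epsilon = 6.22, path_length = 1,
#'                   protein = 0.01, volume_ml = 1)
#' @export
specific_activity <- function(trace, epsilon, path_length = 1, protein = 1,
                              volume_ml = 1, r2_min = 0.98, min_points = 5) {
  if (epsilon <= 0 || path_length <= 0 || protein <= 0 || volume_ml <= 0)
    abort("epsilon, path_length, protein and volume_ml must be positive")
  t <- trace$time_s
  y <- trace$absorbance
  n <- length(t)
  if (n < min_points) abort(sprintf("trace needs at least %d points", min_points))
  if (any(diff(t) <= 0)) abort("times must be strictly increasing")

  # prefix linear fits via cumulative sums
  ct <- cumsum(t); ct2 <- cumsum(t^2)
  cy <- cumsum(y); cy2 <- cumsum(y^2); cty <- cumsum(t * y)
  m <- seq_len(n)
  sxx <- ct2 - ct^2 / m
  syy <- cy2 - cy^2 / m
  sxy <- cty - ct * cy / m
  slope <- sxy / sxx
  r2 <- ifelse(syy > 0, sxy^2 / (sxx * syy), 1)  # flat prefix: perfect fit

  ok <- which(m >= min_points & r2 >= r2_min)
  if (length(ok) == 0L) {
    return(tibble::tibble(activity = NA_real_, slope = NA_real_,
                          window_start = NA_integer_, window_end = NA_integer_,
                          r_squared = max(r2[m >= min_points]),
                          flag = "no_linear_window"))
  }
  end <- max(ok)
  slope_min <- slope[end] * 60  # AU/s -> AU/min
  act <- abs(slope_min) / (epsilon * path_length) * volume_ml * 1000 / protein
  tibble::tibble(activity = act, slope = slope_min, window_start = 1L,
                 window_end = as.integer(end), r_squared = r2[end],
                 flag = NA_character_)
}

#' Mitochondrial coupling-assay parameters from staged OCR readings
#'
#' Subtracts nonmitochondrial respiration from every stage, normalizes to
#' protein, and derives: ATP-linked respiration = state 3 ADP - state 4o,
#' respiratory control ratio = state 3 ADP / state 4o, and coupling
#' efficiency = ATP-linked / state 3 ADP. A state 4o that is not positive
#' after subtraction leaves the RCR undefined (flagged).
#'
#' @param profile Data frame, one row per mitochondrial preparation, columns
#'   `state2`, `state3adp`, `state4o`, `state3u`, `nonmito` (pmol O2/min) and
#'   `protein` (mg). Extra columns (e.g. `sample`, `group`) are carried
#'   through.
#' @return Tibble with the carried-through id columns plus protein-normalized
#'   state2, state3adp, state4o, state3u, atp_linked, rcr,
#'   coupling_efficiency and flag.
#' @examples
#' coupling_params(tibble::tibble(state2 = 45, state3adp = 100, state4o = 40,
#'                                state3u = 120, nonmito = 10, protein = 1))
#' @export
coupling_params <- function(profile) {
  need <- c("state2", "state3adp", "state4o", "state3u", "nonmito", "protein")
  miss <- setdiff(need, names(profile))
  if (length(miss) > 0L)
    abort(paste("coupling profile missing:", paste(miss, collapse = ", ")))
  if (any(unlist(profile[need]) < 0, na.rm = TRUE))
    abort("OCR readings and protein must be >= 0")
  id_cols <- setdiff(names(profile), need)
  norm <- function(x) (x - profile$nonmito) / profile$protein
  out <- tibble::as_tibble(profile[id_cols])
  out$state2 <- norm(profile$state2)
  out$state3adp <- norm(profile$state3adp)
  out$state4o <- norm(profile$state4o)
  out$state3u <- norm(profile$state3u)
  out$atp_linked <- out$state3adp - out$state4o
  out$rcr <- ifelse(out$state4o > 0, out$state3adp / out$state4o, NA_real_)
  out$coupling_efficiency <- ifelse(out$state3adp != 0,
                                    out$atp_linked / out$state3adp, NA_real_)
  out$flag <- ifelse(out$state4o <= 0, "rcr_undefined", NA_character_)
  out
}

#' Electron-flow assay parameters from staged OCR readings
#'
#' Complex I-driven respiration = state 3u - OCR after rotenone; complex
#' II-driven respiration = OCR after succinate - OCR after malonate; all
#' stages nonmitochondrial-subtracted and protein-normalized. Negative
#' derived respiration is reported with a `negative_respiration` warning flag
#' (possible uncoupled preparation), not silently clipped.
#'
#' @param profile Data frame, one row per preparation, columns `state3u`,
#'   `post_rotenone`, `post_succinate`, `post_malonate`, `nonmito`, `protein`.
#' @return Tibble with id columns plus normalized state3u, complexI,
#'   complexII and flag.
#' @examples
#' electron_flow_params(tibble::tibble(
#'   state3u = 120, post_rotenone = 30, post_succinate = 90,
#'   post_malonate = 20, nonmito = 0, protein = 1))
#' @export
electron_flow_params <- function(profile) {
  need <- c("state3u", "post_rotenone", "post_succinate", "post_malonate",
            "nonmito", "protein")
  miss <- setdiff(need, names(profile))
  if (length(miss) > 0L)
    abort(paste("electron-flow profile missing:", paste(miss, collapse = ", ")))
  if (any(unlist(profile[need]) < 0, na.rm = TRUE))
    abort("OCR readings and protein must be >= 0")
  id_cols <- setdiff(names(profile), need)
  norm <- function(x) (x - profile$nonmito) / profile$protein
  out <- tibble::as_tibble(profile[id_cols])
  out$state3u <- norm(profile$state3u)
  out$complexI <- out$state3u - norm(profile$post_rotenone)
  out$complexII <- norm(profile$post_succinate) - norm(profile$post_malonate)
  out$flag <- ifelse(out$complexI < 0 | out$complexII < 0,
                     "negative_respiration", NA_character_)
  out
}
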