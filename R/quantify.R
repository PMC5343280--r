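# Percent 13C enrichment and total concentrations from integrated peak areas.

#' Validate peak records against a transition design
#'
#' Every (analyte, precursor_shift, product_shift) combination in the records
#' must exist in the design, and areas must be nonnegative.
#'
#' @param peaks Tibble: sample, analyte, precursor_shift, product_shift, area.
#' @param design Transition design (as from [design_transitions()]).
#' @return `peaks`, invisibly.
#' @export
validate_peaks <- function(peaks, design = design_transitions()) {
  need <- c("sample", "analyte", "precursor_shift", "product_shift", "area")
  miss <- setdiff(need, names(peaks))
  if (length(miss) > 0L)
    abort(paste("peak table missing columns:", paste(miss, collapse = ", ")))
  if (any(peaks$area < 0, na.rm = TRUE)) abort("peak areas must be >= 0")
  bad <- dplyr::anti_join(
    dplyr::distinct(peaks, .data$analyte, .data$precursor_shift,
                    .data$product_shift),
    design, by = c("analyte", "precursor_shift", "product_shift"))
  if (nrow(bad) > 0L) {
    abort(paste0("peak records not in the transition design: ",
                 paste(sprintf("%s M+%d>+%d", bad$analyte,
                               bad$precursor_shift, bad$product_shift),
                       collapse = "; ")))
  }
  invisible(peaks)
}

#' Percent 13C enrichment per sample, metabolite and TCA turn
#'
#' For each sample and metabolite, the enrichment of turn t is
#' 100 * (sum of areas of that turn's labeled transitions, summed over both
#' product ions where two are monitored) / (unlabeled area + sum of areas of
#' all monitored labeled transitions of the metabolite). Samples missing the
#' unlabeled (shift 0) channel are flagged `missing_unlabeled` and get `NA`
#' (never an imputed zero); an all-zero denominator is flagged
#' `zero_denominator`.
#'
#' @param peaks Peak record tibble (see [validate_peaks()]).
#' @param design Transition design defining the monitored channels and their
#'   turn assignment.
#' @param na_correction Optional function applied to the joined per-channel
#'   area table before summation (hook for a natural-abundance correction);
#'   default `NULL` = no correction.
#' @return Tibble: sample, metabolite, turn, enrichment (percent),
#'   n_channels (labeled channels observed for that turn), flag.
#' @examples
#' peaks <- tibble::tibble(
#'   sample = "s1", analyte = "G6P",
#'   precursor_shift = c(0L, 6L), product_shift = 0L,
#'   area = c(800, 200))
#' percent_enrichment(peaks)
#' @export
percent_enrichment <- function(peaks, design = design_transitions(),
                               na_correction = NULL) {
  validate_peaks(peaks, design)
  x <- dplyr::inner_join(
    peaks,
    dplyr::select(design, "analyte", "turn", "precursor_shift",
                  "product_shift"),
    by = c("analyte", "precursor_shift", "product_shift"))
  if (!is.null(na_correction)) x <- na_correction(x)

  totals <- dplyr::summarise(
    dplyr::group_by(x, .data$sample, .data$analyte),
    denom = sum(.data$area),
    has_unlabeled = any(.data$turn == 0L),
    .groups = "drop")
  turns <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(x, .data$turn > 0L),
                    .data$sample, .data$analyte, .data$turn),
    labeled = sum(.data$area),
    n_channels = dplyr::n(),
    .groups = "drop")
  out <- dplyr::left_join(turns, totals, by = c("sample", "analyte"))
  out <- dplyr::mutate(
    out,
    flag = dplyr::case_when(
      !.data$has_unlabeled ~ "missing_unlabeled",
      .data$denom <= 0 ~ "zero_denominator",
      TRUE ~ NA_character_),
    enrichment = ifelse(is.na(.data$flag), 100 * .data$labeled / .data$denom,
                        NA_real_))
  dplyr::arrange(
    dplyr::select(out, "sample", metabolite = "analyte", "turn",
                  "enrichment", "n_channels", "flag"),
    .data$sample, .data$metabolite, .data$turn)
}

#' Total metabolite concentration per sample (nmol per g tissue)
#'
#' Sums all isotopologue channel areas of a metabolite, normalizes to the
#' internal-standard (AZT) area, and converts via the spiked
#' internal-standard amount, a per-analyte response factor (area per nmol
#' relative to the internal standard) and the wet tissue mass:
#' concentration = (total area / IS area) * IS nmol / response factor /
#' tissue mass.
#'
#' @param peaks Peak record tibble.
#' @param samples Sample metadata tibble with columns `sample`, `tissue_mass`
#'   (g) and `is_area` (internal-standard area).
#' @param response_factors Named numeric vector of per-analyte response
#'   factors; analytes not named get 1.0.
#' @param is_amount Internal-standard amount in nmol (default 4: 4 uL of a
#'   1 mM spike).
#' @return Tibble: sample, metabolite, concentration (nmol/g).
#' @export
total_concentration <- function(peaks, samples, response_factors = NULL,
                                is_amount = 4) {
  if (is_amount <= 0) abort("is_amount must be positive")
  if (any(samples$tissue_mass <= 0)) abort("tissue_mass must be positive")
  if (any(samples$is_area <= 0)) abort("is_area must be positive")
  sums <- dplyr::summarise(
    dplyr::group_by(peaks, .data$sample, .data$analyte),
    total_area = sum(.data$area), .groups = "drop")
  rf <- function(a) {
    if (is.null(response_factors)) return(rep(1, length(a)))
    out <- unname(response_factors[a])
    out[is.na(out)] <- 1
    out
  }
  out <- dplyr::inner_join(
    sums, dplyr::select(samples, "sample", "tissue_mass", "is_area"),
    by = "sample")
  out <- dplyr::mutate(
    out,
    response_factor = rf(.data$analyte))
  if (any(out$response_factor <= 0)) abort("response factors must be positive")
  out <- dplyr::mutate(
    out,
    concentration = (.data$total_area / .data$is_area) * is_amount /
      .data$response_factor / .data$tissue_mass)
  dplyr::arrange(
    dplyr::select(out, "sample", metabolite = "analyte", "concentration"),
    .data$sample, .data$metabolite)
}
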