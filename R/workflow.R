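# End-to-end pipeline: cohort -> enrichment, concentrations, statistics,
# assay parameters, reproducible results bundle.

domain_of <- function(metabolite, turn) {
  dplyr::case_when(
    metabolite %in% glyc_measured ~ "glycolysis",
    turn == 1L ~ "tca_turn1",
    TRUE ~ "tca_turn2")
}

#' Run the full tracing analysis on a cohort
#'
#' Quantifies percent enrichment and total concentrations from the peak
#' table, runs the statistical battery (two-way group-by-metabolite type III
#' ANOVA with uncorrected Fisher's LSD posttests per enrichment domain;
#' Pearson correlations of G6P with downstream glycolytic intermediates, of
#' pyruvate with first-turn TCA intermediates, and of 2OG with succinate,
#' per group; pooled-variance t tests for enzyme activities and mitochondrial
#' parameters), and computes enzyme specific activities and respirometry
#' parameters from the raw traces and staged OCR profiles.
#'
#' The pipeline itself is deterministic; reruns on the same cohort produce
#' identical results.
#'
#' @param cohort A `glucotrace_cohort` (from [generate_cohort()]) or a list
#'   with the same components read from files.
#' @param design Transition design used for quantification.
#' @param alpha Significance level for posttest flags (default 0.05).
#' @param ss_type ANOVA sums-of-squares type (3, the default, or 2).
#' @param na_correction Optional natural-abundance correction hook passed to
#'   [percent_enrichment()].
#' @param out_dir Optional directory: when given, every result table is
#'   written as CSV plus a JSON run log (config hash, package version).
#' @return A `glucotrace_results` list of tibbles: `enrichment`,
#'   `concentration`, `anova`, `lsd`, `correlations`, `activities`,
#'   `enzyme_tests`, `mito_coupling`, `mito_electron`, `mito_tests`.
#' @examples
#' \donttest{
#' res <- run_pipeline(generate_cohort(cohort_config(seed = 7)))
#' res$lsd
#' }
#' @export
run_pipeline <- function(cohort, design = design_transitions(), alpha = 0.05,
                         ss_type = 3, na_correction = NULL, out_dir = NULL) {
  samples <- cohort$samples
  enrichment <- percent_enrichment(cohort$peaks, design,
                                   na_correction = na_correction)
  enrichment <- dplyr::mutate(
    dplyr::left_join(enrichment,
                     dplyr::select(samples, "sample", "group"),
                     by = "sample"),
    domain = domain_of(.data$metabolite, .data$turn))
  concentration <- dplyr::left_join(
    total_concentration(cohort$peaks, samples,
                        is_amount = cohort$config$is_amount %||% 4),
    dplyr::select(samples, "sample", "group"), by = "sample")

  # two-way ANOVA + LSD per enrichment domain
  anovas <- list(); lsds <- list()
  for (dom in unique(enrichment$domain)) {
    d <- dplyr::filter(enrichment, .data$domain == dom,
                       !is.na(.data$enrichment))
    av <- two_way_anova(d, "enrichment", "group", "metabolite",
                        ss_type = ss_type)
    anovas[[dom]] <- dplyr::mutate(tidy(av), domain = dom, .before = 1)
    lsds[[dom]] <- dplyr::mutate(fisher_lsd(av, alpha = alpha),
                                 domain = dom, .before = 1)
  }
  conc_av <- two_way_anova(concentration, "concentration", "group",
                           "metabolite", ss_type = ss_type)
  anovas[["concentration"]] <- dplyr::mutate(tidy(conc_av),
                                             domain = "concentration",
                                             .before = 1)
  lsds[["concentration"]] <- dplyr::mutate(fisher_lsd(conc_av, alpha = alpha),
                                           domain = "concentration",
                                           .before = 1)

  # correlations within groups
  enr_wide <- tidyr::pivot_wider(
    dplyr::select(enrichment, "sample", "group", "metabolite", "turn",
                  "enrichment"),
    names_from = c("metabolite", "turn"), values_from = "enrichment")
  cor_spec <- dplyr::bind_rows(
    tibble::tibble(set = "glycolysis_vs_G6P", x = "G6P_1",
                   y = paste0(setdiff(glyc_measured, "G6P"), "_1")),
    tibble::tibble(set = "tca1_vs_PYR", x = "PYR_1",
                   y = paste0(tca_measured, "_1")),
    tibble::tibble(set = "OG2_vs_SUC_turn1", x = "OG2_1", y = "SUC_1"))
  correlations <- dplyr::bind_rows(lapply(unique(samples$group), function(g) {
    w <- enr_wide[enr_wide$group == g, ]
    dplyr::bind_rows(lapply(seq_len(nrow(cor_spec)), function(i) {
      dplyr::mutate(pearson_cor(w[[cor_spec$x[i]]], w[[cor_spec$y[i]]]),
                    group = g, set = cor_spec$set[i],
                    x = cor_spec$x[i], y = cor_spec$y[i], .before = 1)
    }))
  }))

  # enzyme activities from traces + t tests
  activities <- NULL; enzyme_tests <- NULL
  if (!is.null(cohort$traces)) {
    activities <- dplyr::bind_rows(lapply(
      seq_len(nrow(cohort$trace_meta)), function(i) {
        m <- cohort$trace_meta[i, ]
        tr <- cohort$traces[cohort$traces$sample == m$sample &
                              cohort$traces$enzyme == m$enzyme, ]
        dplyr::mutate(
          specific_activity(tr, epsilon = m$epsilon,
                            path_length = m$path_length, protein = m$protein,
                            volume_ml = m$volume_ml),
          sample = m$sample, group = m$group, enzyme = m$enzyme, .before = 1)
      }))
    enzyme_tests <- dplyr::bind_rows(lapply(
      unique(activities$enzyme), function(e) {
        a <- activities[activities$enzyme == e, ]
        dplyr::mutate(unpaired_t(a$activity[a$group == "NoSE"],
                                 a$activity[a$group == "SE"]),
                      enzyme = e, .before = 1)
      }))
    enzyme_tests$significant <- enzyme_tests$p.value < alpha
  }

  # mitochondrial parameters + t tests
  mito_coupling <- mito_electron <- mito_tests <- NULL
  if (!is.null(cohort$ocr_coupling)) {
    mito_coupling <- coupling_params(cohort$ocr_coupling)
    mito_electron <- electron_flow_params(cohort$ocr_electron)
    params <- dplyr::bind_rows(
      tidyr::pivot_longer(
        dplyr::select(mito_coupling, "sample", "group", "state2", "state3adp",
                      "state4o", "state3u", "atp_linked", "rcr",
                      "coupling_efficiency"),
        -c("sample", "group"), names_to = "parameter"),
      tidyr::pivot_longer(
        dplyr::select(mito_electron, "sample", "group", "complexI",
                      "complexII"),
        -c("sample", "group"), names_to = "parameter"))
    mito_tests <- dplyr::bind_rows(lapply(
      unique(params$parameter), function(p) {
        a <- params[params$parameter == p, ]
        dplyr::mutate(unpaired_t(a$value[a$group == "NoSE"],
                                 a$value[a$group == "SE"]),
                      parameter = p, .before = 1)
      }))
    mito_tests$significant <- mito_tests$p.value < alpha
  }

  res <- structure(list(
    enrichment = enrichment, concentration = concentration,
    anova = dplyr::bind_rows(anovas), lsd = dplyr::bind_rows(lsds),
    correlations = correlations, activities = activities,
    enzyme_tests = enzyme_tests, mito_coupling = mito_coupling,
    mito_electron = mito_electron, mito_tests = mito_tests,
    alpha = alpha), class = "glucotrace_results")

  if (!is.null(out_dir)) write_results(res, cohort, out_dir)
  res
}

#' @export
print.glucotrace_results <- function(x, ...) {
  cat("<glucotrace_results>\n")
  sig <- x$lsd[!is.na(x$lsd$p.value) & x$lsd$significant &
                 x$lsd$domain != "concentration", ]
  cat(sprintf("  enrichment: %d rows; significant LSD contrasts: %s\n",
              nrow(x$enrichment),
              if (nrow(sig) == 0) "none"
              else paste(sprintf("%s[%s]", sig$metabolite, sig$domain),
                         collapse = ", ")))
  invisible(x)
}

#' Write a results bundle to disk
#'
#' Writes each result tibble as CSV plus a `run_log.json` recording the
#' package version, timestamp, significance level and a hash of the cohort
#' configuration so a run can be traced to its inputs.
#'
#' @param results A `glucotrace_results` object.
#' @param cohort The cohort the results were computed from.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(results, cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("enrichment", "concentration", "anova", "lsd", "correlations",
              "activities", "enzyme_tests", "mito_coupling", "mito_electron",
              "mito_tests")
  for (tb in tables) {
    if (!is.null(results[[tb]]))
      readr::write_csv(results[[tb]], file.path(out_dir, paste0(tb, ".csv")))
  }
  log <- list(package = "glucotrace",
              version = as.character(utils::packageVersion("glucotrace")),
              timestamp = format(Sys.time(), tz = "UTC"),
              alpha = results$alpha,
              seed = cohort$config$seed,
              config_hash = rlang::hash(cohort$config))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Write a cohort's raw tables to CSV plus a ground-truth JSON log
#'
#' @param cohort A `glucotrace_cohort`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (tb in c("samples", "peaks", "trace_meta", "traces", "ocr_coupling",
               "ocr_electron")) {
    readr::write_csv(cohort[[tb]], file.path(out_dir, paste0(tb, ".csv")))
  }
  jsonlite::write_json(cohort$truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
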