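# Seeded synthetic-cohort generator: peak tables, sample metadata, enzyme
# kinetic traces and staged OCR profiles with the two-group (SE vs No SE)
# structure of a pilocarpine status-epilepticus tracing study.

glyc_measured <- c("G6P", "F6P", "F16BP", "DHAP", "PG23", "PEP", "PYR")
tca_measured <- c("CIT", "ACO", "OG2", "SUC", "FUM", "MAL")

#' Default group effect table
#'
#' Fractional reductions applied to the SE group, by domain:
#' glycolytic percent enrichment, first- and second-turn TCA percent
#' enrichment, enzyme specific activities, and OCR stages (all zero - the
#' respirometry comparisons are null).
#'
#' @return Tibble: domain, target, effect (fraction in \[0, 1)).
#' @examples
#' default_effect_table()
#' @export
default_effect_table <- function() {
  dplyr::bind_rows(
    tibble::tibble(domain = "glycolysis",
                   target = glyc_measured,
                   effect = c(0.22, 0.21, 0, 0.17, 0, 0.20, 0)),
    tibble::tibble(domain = "tca_turn1",
                   target = tca_measured,
                   effect = c(0.17, 0.17, 0, 0.35, 0.23, 0)),
    tibble::tibble(domain = "tca_turn2",
                   target = tca_measured,
                   effect = c(0, 0, 0.47, 0.55, 0.25, 0.29)),
    tibble::tibble(domain = "enzyme",
                   target = c("HK", "PGI", "PFK", "PK", "LDH", "G6PDH", "CS",
                              "PDH", "OGDH", "PCX", "GDH", "GPT", "GOT"),
                   effect = c(0, 0, 0, 0, 0, 0, 0, 0.33, 0.55, 0, 0, 0, 0)),
    tibble::tibble(domain = "ocr",
                   target = c("state2", "state3adp", "state4o", "state3u",
                              "post_rotenone", "post_succinate",
                              "post_malonate"),
                   effect = 0))
}

#' Default baseline percent enrichments (No SE group means)
#'
#' Absolute enrichment baselines for a 15-min uniformly labeled glucose bolus
#' in brain: glycolytic intermediates 12-25 percent, first TCA turn about
#' 5-6 percent, second turn about 1-1.5 percent. These set the scale only;
#' group comparisons and correlation structure are driven by the effect table
#' and coupling parameters.
#'
#' @return Tibble: domain, metabolite, baseline (percent).
#' @export
default_baseline_enrichment <- function() {
  dplyr::bind_rows(
    tibble::tibble(domain = "glycolysis", metabolite = glyc_measured,
                   baseline = c(25, 22, 20, 18, 15, 15, 12)),
    tibble::tibble(domain = "tca_turn1", metabolite = tca_measured,
                   baseline = c(6, 6, 5, 5, 5, 5)),
    tibble::tibble(domain = "tca_turn2", metabolite = tca_measured,
                   baseline = c(1.5, 1.2, 1.2, 1.0, 1.0, 1.0)))
}

#' Default total-concentration targets (nmol per g tissue)
#'
#' Group means and SEMs for the thirteen measured intermediates.
#'
#' @return Tibble: metabolite, mean_nose, sem_nose, mean_se, sem_se.
#' @export
default_concentrations <- function() {
  tibble::tribble(
    ~metabolite, ~mean_nose, ~sem_nose, ~mean_se, ~sem_se,
    "G6P",   20.1, 1.7,  24.2, 3.4,
    "F6P",   33.0, 2.2,  36.2, 5.9,
    "F16BP", 16.5, 1.0,  17.8, 1.4,
    "DHAP",  0.70, 0.08, 0.67, 0.08,
    "PG23",  11.2, 1.0,  10.9, 1.2,
    "PEP",   8.93, 1.42, 7.50, 1.33,
    "PYR",   38.2, 2.7,  34.2, 6.0,
    "CIT",   109,  5,    110,  17,
    "ACO",   1.84, 0.12, 2.24, 0.28,
    "OG2",   90.8, 6.5,  83.9, 17.4,
    "SUC",   10.1, 0.8,  8.1,  1.6,
    "FUM",   12.5, 0.9,  13.2, 2.7,
    "MAL",   45.9, 3.9,  46.1, 6.8)
}

#' Default enrichment-coupling (correlation) structure
#'
#' Latent-factor loadings that induce the cohort's correlation structure. In
#' control (No SE) animals each TCA metabolite's log-enrichment loads on the
#' standardized pyruvate log-enrichment with loading `pyr_loading`; 2OG and
#' succinate share an additional mitochondrial factor (`mito_loading`) so
#' their mutual correlation exceeds what the pyruvate factor alone would
#' give. SE animals lose the pyruvate coupling: their TCA enrichment loads
#' weakly on pyruvate (`se_pyr_loading`) and mainly on an independent
#' per-animal mitochondrial-capacity factor (`se_capacity_loading`).
#'
#' @return Named list of coupling parameters.
#' @export
default_coupling <- function() {
  list(
    tau_t1 = 0.25,   # total sdlog of first-turn enrichment across animals
    tau_t2 = 0.30,   # total sdlog of second-turn enrichment
    pyr_loading = c(CIT = 0.86, ACO = 0.80, OG2 = 0.78,
                    SUC = 0.86, FUM = 0.70, MAL = 0.91),
    mito_loading = c(CIT = 0, ACO = 0, OG2 = 0.58,
                     SUC = 0.495, FUM = 0, MAL = 0),
    se_pyr_loading = 0.35,
    se_capacity_loading = 0.45)
}

#' Default enzyme assay configuration
#'
#' Baseline specific activities (nmol/min/mg), assay read-out direction,
#' extinction coefficients and per-well protein loads. Protein loads are
#' chosen to give mid-scale absorbance changes (about 0.05 AU/min) for every
#' enzyme; extinction coefficients are 6.22 mM^-1 cm^-1 for NAD(P)H at
#' 340 nm, 13.6 for TNB at 412 nm, and a calibration value of 17 for the
#' MTT-formazan PDH assay.
#'
#' @return Tibble: enzyme, baseline, epsilon, direction, protein_mg,
#'   start_abs.
#' @export
default_enzyme_assays <- function() {
  tibble::tribble(
    ~enzyme, ~baseline, ~epsilon, ~direction, ~protein_mg, ~start_abs,
    "HK",     150, 6.22, "increase", 0.020, 0.05,
    "PGI",    800, 6.22, "increase", 0.004, 0.05,
    "PFK",     80, 6.22, "decrease", 0.036, 1.20,
    "PK",     900, 6.22, "decrease", 0.003, 1.20,
    "LDH",   1200, 6.22, "decrease", 0.0025, 1.20,
    "G6PDH",   40, 6.22, "increase", 0.070, 0.05,
    "CS",     600, 13.6, "increase", 0.002, 0.05,
    "PDH",     25, 17.0, "increase", 0.043, 0.05,
    "OGDH",    15, 6.22, "increase", 0.200, 0.05,
    "PCX",     10, 13.6, "increase", 0.130, 0.05,
    "GDH",    300, 6.22, "decrease", 0.010, 1.20,
    "GPT",     40, 6.22, "decrease", 0.070, 1.20,
    "GOT",    400, 6.22, "decrease", 0.007, 1.20)
}

#' Default OCR stage levels (pmol O2/min per well)
#'
#' @return Named list with `coupling` and `electron` stage levels and the
#'   per-well mitochondrial `protein` (mg).
#' @export
default_ocr_levels <- function() {
  list(coupling = c(state2 = 45, state3adp = 280, state4o = 60,
                    state3u = 320, nonmito = 12),
       electron = c(state3u = 330, post_rotenone = 25, post_succinate = 300,
                    post_malonate = 40, nonmito = 12),
       protein = 0.004)
}

#' Cohort generator configuration
#'
#' Bundles and validates every generator parameter. Defaults reproduce the
#' study conditions: 11 No SE and 10 SE tracing animals, 8 + 8 animals in the
#' enzyme cohort, 7 + 7 mitochondrial preparations, the default effect table,
#' baselines, concentration targets and coupling structure.
#'
#' @param n_nose,n_se Tracing-cohort group sizes.
#' @param n_enzyme,n_ocr Per-group sizes of the enzyme and respirometry
#'   cohorts.
#' @param seed Integer seed; a fixed seed makes [generate_cohort()] output
#'   identical.
#' @param baseline_enrichment,effect_table,concentrations See the
#'   corresponding `default_*()` functions.
#' @param coupling Correlation-structure parameters ([default_coupling()]).
#' @param enzymes Enzyme assay table ([default_enzyme_assays()]).
#' @param ocr_levels OCR stage levels ([default_ocr_levels()]).
#' @param sigma_u Between-animal sdlog of the shared glucose-uptake factor
#'   that multiplies all glycolytic enrichments.
#' @param glyc_noise Named per-metabolite extra sdlog on glycolytic
#'   enrichment (sets the correlation of each metabolite with G6P).
#' @param noise List: `cv_sample_analyte` (shared per sample-and-analyte
#'   ionization factor, cancels in isotope ratios), `cv_channel` (independent
#'   per-transition integration noise), `enzyme_cv` (between-animal activity
#'   CV), `absorbance_sd` (AU), `ocr_animal_cv`, `ocr_stage_cv`.
#' @param tissue_mass,tissue_cv Mean hippocampal wet mass (g) and its CV.
#' @param is_area,is_cv Internal-standard area scale and CV.
#' @param body_weight Named vector: nose_mean, nose_sd, se_mean, se_sd (g).
#' @param is_amount Internal-standard amount (nmol).
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_nose = 11, n_se = 10, n_enzyme = 8, n_ocr = 7,
                          seed = 1,
                          baseline_enrichment = default_baseline_enrichment(),
                          effect_table = default_effect_table(),
                          concentrations = default_concentrations(),
                          coupling = default_coupling(),
                          enzymes = default_enzyme_assays(),
                          ocr_levels = default_ocr_levels(),
                          sigma_u = 0.25,
                          glyc_noise = c(G6P = 0.044, F6P = 0.118,
                                         F16BP = 0.044, DHAP = 0.057,
                                         PG23 = 0.207, PEP = 0.057,
                                         PYR = 0.069),
                          noise = list(cv_sample_analyte = 0.10,
                                       cv_channel = 0.02,
                                       enzyme_cv = 0.20,
                                       absorbance_sd = 8e-4,
                                       ocr_animal_cv = 0.15,
                                       ocr_stage_cv = 0.05),
                          tissue_mass = 0.025, tissue_cv = 0.10,
                          is_area = 1e5, is_cv = 0.10,
                          body_weight = c(nose_mean = 39.8, nose_sd = 2.65,
                                          se_mean = 39.9, se_sd = 4.1),
                          is_amount = 4) {
  cfg <- list(n_nose = n_nose, n_se = n_se, n_enzyme = n_enzyme, n_ocr = n_ocr,
              seed = as.integer(seed),
              baseline_enrichment = baseline_enrichment,
              effect_table = effect_table, concentrations = concentrations,
              coupling = coupling, enzymes = enzymes, ocr_levels = ocr_levels,
              sigma_u = sigma_u, glyc_noise = glyc_noise, noise = noise,
              tissue_mass = tissue_mass, tissue_cv = tissue_cv,
              is_area = is_area, is_cv = is_cv, body_weight = body_weight,
              is_amount = is_amount)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_nose < 3 || cfg$n_se < 3) abort("need at least 3 animals per group")
  eff <- cfg$effect_table$effect
  if (any(eff < 0 | eff >= 1)) abort("effects must be fractions in [0, 1)")
  if (any(cfg$baseline_enrichment$baseline <= 0))
    abort("baseline enrichments must be positive")
  enr <- dplyr::left_join(
    cfg$baseline_enrichment,
    cfg$effect_table[cfg$effect_table$domain != "enzyme", ],
    by = c("domain", "metabolite" = "target"))
  if (any(enr$baseline * (1 - enr$effect) <= 0, na.rm = TRUE))
    abort("baseline + effect produce non-positive SE enrichment")
  tot <- dplyr::summarise(dplyr::group_by(enr, .data$metabolite),
                          total = sum(.data$baseline))
  if (any(tot$total >= 100))
    abort("summed baseline enrichments reach 100 percent")
  cp <- cfg$coupling
  if (any(cp$pyr_loading^2 + cp$mito_loading^2 > 1 + 1e-12))
    abort("coupling loadings exceed unit variance")
  if (cp$se_pyr_loading^2 + cp$se_capacity_loading^2 > 1)
    abort("SE coupling loadings exceed unit variance")
  invisible(cfg)
}

# lognormal multiplier with mean exactly 1: exp(s*z - s^2/2)
ln_factor <- function(n, sdlog) {
  if (sdlog == 0) return(rep(1, n))
  exp(rnorm(n, 0, sdlog) - sdlog^2 / 2)
}

cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

# lognormal draws with given arithmetic mean and sd
rlnorm_ms <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  sdlog <- cv_to_sdlog(sd / mean)
  rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)
}

effect_lookup <- function(effect_table, domain) {
  e <- effect_table[effect_table$domain == domain, ]
  setNames(e$effect, e$target)
}

#' Generate a synthetic two-group tracing cohort
#'
#' Draws a complete synthetic study from a [cohort_config()]: per-animal
#' latent glucose-uptake factors that multiply all glycolytic enrichments
#' (inducing the glycolytic correlation structure), first- and second-turn
#' TCA enrichments coupled to pyruvate (plus the shared 2OG/succinate
#' mitochondrial factor) in controls but driven by an independent capacity
#' factor in SE animals, group means reduced by the effect table, peak areas
#' back-computed from enrichments and concentrations with lognormal noise,
#' enzyme kinetic traces with the configured activity losses, and
#' null-difference OCR profiles. In SE animals the combined 2+3PG enrichment
#' is decoupled from the uptake factor.
#'
#' The returned ground truth contains every latent value needed to recompute
#' the expected results. With a fixed seed the output is identical across
#' calls.
#'
#' @param config A `cohort_config`.
#' @param design Transition design used to lay out peak channels; defaults to
#'   the full two-turn \[U-13C\]glucose design (pass a precomputed design to
#'   avoid rebuilding it in replicate loops).
#' @return A `glucotrace_cohort` list: `samples`, `peaks`, `trace_meta`,
#'   `traces`, `ocr_coupling`, `ocr_electron`, `truth`, `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 42))
#' head(cohort$peaks)
#' @export
generate_cohort <- function(config = cohort_config(),
                            design = design_transitions()) {
  validate_cohort_config(config)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  n1 <- config$n_nose; n2 <- config$n_se; n <- n1 + n2
  samples <- tibble::tibble(
    sample = c(sprintf("NoSE%02d", seq_len(n1)), sprintf("SE%02d", seq_len(n2))),
    group = rep(c("NoSE", "SE"), c(n1, n2)))
  se <- samples$group == "SE"
  bw <- config$body_weight
  samples$body_weight <- rnorm(n, ifelse(se, bw[["se_mean"]], bw[["nose_mean"]]),
                               ifelse(se, bw[["se_sd"]], bw[["nose_sd"]]))
  samples$tissue_mass <- rlnorm_ms(n, config$tissue_mass,
                                   config$tissue_mass * config$tissue_cv)
  samples$is_area <- rlnorm_ms(n, config$is_area,
                               config$is_area * config$is_cv)

  # ---- latent enrichment structure -----------------------------------------
  sigma_u <- config$sigma_u
  zU <- rnorm(n)
  u <- exp(sigma_u * zU - sigma_u^2 / 2)
  zU_alt <- rnorm(n)  # decoupled uptake draw for SE 2+3PG
  u_alt <- exp(sigma_u * zU_alt - sigma_u^2 / 2)
  zM <- rnorm(n)      # shared 2OG/SUC mitochondrial factor
  zC <- rnorm(n)      # SE mitochondrial-capacity factor

  base <- config$baseline_enrichment
  eff_gly <- effect_lookup(config$effect_table, "glycolysis")
  eff_t1 <- effect_lookup(config$effect_table, "tca_turn1")
  eff_t2 <- effect_lookup(config$effect_table, "tca_turn2")

  gly_base <- base[base$domain == "glycolysis", ]
  gly <- lapply(seq_len(nrow(gly_base)), function(i) {
    met <- gly_base$metabolite[i]
    s <- config$glyc_noise[[met]] %||% 0
    fac <- if (met == "PG23") ifelse(se, u_alt, u) else u
    z <- rnorm(n)
    e <- gly_base$baseline[i] * fac * exp(s * z - s^2 / 2) *
      ifelse(se, 1 - (eff_gly[[met]] %||% 0), 1)
    tibble::tibble(sample = samples$sample, metabolite = met, turn = 1L,
                   enrichment = e, z = z)
  })
  names(gly) <- gly_base$metabolite

  # standardized pyruvate log-enrichment (the TCA entry signal)
  s_pyr <- config$glyc_noise[["PYR"]] %||% 0
  tau_pyr <- sqrt(sigma_u^2 + s_pyr^2)
  zP <- if (tau_pyr > 0) (sigma_u * zU + s_pyr * gly[["PYR"]]$z) / tau_pyr
        else rep(0, n)

  cp <- config$coupling
  tca_pool <- function(domain, tau, eff) {
    b <- base[base$domain == domain, ]
    lapply(seq_len(nrow(b)), function(i) {
      met <- b$metabolite[i]
      rho <- cp$pyr_loading[[met]]; q <- cp$mito_loading[[met]]
      resid_no <- sqrt(max(0, 1 - rho^2 - q^2))
      resid_se <- sqrt(max(0, 1 - cp$se_pyr_loading^2 -
                             cp$se_capacity_loading^2))
      z <- rnorm(n)
      dev <- ifelse(se,
                    cp$se_pyr_loading * zP + cp$se_capacity_loading * zC +
                      resid_se * z,
                    rho * zP + q * zM + resid_no * z)
      e <- b$baseline[i] * exp(tau * dev - tau^2 / 2) *
        ifelse(se, 1 - (eff[[met]] %||% 0), 1)
      tibble::tibble(sample = samples$sample, metabolite = met,
                     turn = if (domain == "tca_turn1") 1L else 2L,
                     enrichment = e)
    })
  }
  t1 <- tca_pool("tca_turn1", cp$tau_t1, eff_t1)
  t2 <- tca_pool("tca_turn2", cp$tau_t2, eff_t2)

  enrichment_true <- dplyr::bind_rows(
    dplyr::select(dplyr::bind_rows(gly), -"z"),
    dplyr::bind_rows(t1), dplyr::bind_rows(t2))

  # ---- concentrations -------------------------------------------------------
  conc <- config$concentrations
  conc_true <- dplyr::bind_rows(lapply(seq_len(nrow(conc)), function(i) {
    # SEMs converted to between-animal SDs with the study's per-metabolite n
    tibble::tibble(
      sample = samples$sample, metabolite = conc$metabolite[i],
      concentration = c(
        rlnorm_ms(n1, conc$mean_nose[i], conc$sem_nose[i] * sqrt(8)),
        rlnorm_ms(n2, conc$mean_se[i], conc$sem_se[i] * sqrt(8))))
  }))

  # ---- peak areas back-computed from enrichment and concentration ----------
  channels <- dplyr::select(design, "analyte", "turn", "precursor_shift",
                            "product_shift")
  k_per_turn <- dplyr::summarise(
    dplyr::group_by(channels, .data$analyte, .data$turn),
    k = dplyr::n(), .groups = "drop")

  grid <- dplyr::inner_join(conc_true,
                            dplyr::select(samples, "sample", "tissue_mass",
                                          "is_area"),
                            by = "sample")
  grid$total_area <- grid$concentration * grid$tissue_mass /
    config$is_amount * grid$is_area
  enr_wide <- tidyr::pivot_wider(enrichment_true, names_from = "turn",
                                 values_from = "enrichment",
                                 names_prefix = "e")
  if (!"e2" %in% names(enr_wide)) enr_wide$e2 <- NA_real_
  grid <- dplyr::left_join(grid, enr_wide,
                           by = c("sample", "metabolite"))
  grid$e1[is.na(grid$e1)] <- 0
  grid$e2[is.na(grid$e2)] <- 0

  peaks <- dplyr::inner_join(
    channels, dplyr::rename(grid, analyte = "metabolite"),
    by = "analyte", relationship = "many-to-many")
  peaks <- dplyr::left_join(peaks, k_per_turn, by = c("analyte", "turn"))
  peaks$frac <- ifelse(peaks$turn == 0L, 1 - (peaks$e1 + peaks$e2) / 100,
                ifelse(peaks$turn == 1L, peaks$e1 / 100 / peaks$k,
                       peaks$e2 / 100 / peaks$k))
  peaks$area <- peaks$total_area * peaks$frac

  sa_key <- paste(peaks$sample, peaks$analyte)
  sa_fac <- ln_factor(length(unique(sa_key)),
                      cv_to_sdlog(config$noise$cv_sample_analyte))
  names(sa_fac) <- unique(sa_key)
  peaks$area <- peaks$area * sa_fac[sa_key] *
    ln_factor(nrow(peaks), cv_to_sdlog(config$noise$cv_channel))
  peaks <- dplyr::arrange(
    dplyr::select(peaks, "sample", "analyte", "precursor_shift",
                  "product_shift", "area"),
    .data$sample, .data$analyte, .data$precursor_shift, .data$product_shift)

  # ---- enzyme cohort --------------------------------------------------------
  ne <- config$n_enzyme
  enz_samples <- tibble::tibble(
    sample = c(sprintf("ENZ_NoSE%02d", seq_len(ne)),
               sprintf("ENZ_SE%02d", seq_len(ne))),
    group = rep(c("NoSE", "SE"), each = ne))
  eff_enz <- effect_lookup(config$effect_table, "enzyme")
  sd_enz <- cv_to_sdlog(config$noise$enzyme_cv)
  enz <- config$enzymes
  times <- seq(0, 300, by = 10)
  trace_meta <- list(); traces <- list(); act_true <- list()
  for (i in seq_len(nrow(enz))) {
    e <- enz[i, ]
    act <- e$baseline * ln_factor(2 * ne, sd_enz) *
      ifelse(enz_samples$group == "SE", 1 - (eff_enz[[e$enzyme]] %||% 0), 1)
    slope <- act * e$protein_mg / 1000 / 0.2 * e$epsilon * 0.55  # AU/min
    sign <- if (e$direction == "decrease") -1 else 1
    act_true[[i]] <- tibble::tibble(sample = enz_samples$sample,
                                    group = enz_samples$group,
                                    enzyme = e$enzyme, activity = act)
    trace_meta[[i]] <- tibble::tibble(
      sample = enz_samples$sample, group = enz_samples$group,
      enzyme = e$enzyme, epsilon = e$epsilon, path_length = 0.55,
      protein = e$protein_mg, volume_ml = 0.2, direction = e$direction)
    traces[[i]] <- tibble::tibble(
      sample = rep(enz_samples$sample, each = length(times)),
      enzyme = e$enzyme,
      time_s = rep(times, 2 * ne),
      absorbance = e$start_abs +
        sign * rep(slope, each = length(times)) * rep(times, 2 * ne) / 60 +
        rnorm(2 * ne * length(times), 0, config$noise$absorbance_sd))
  }
  trace_meta <- dplyr::bind_rows(trace_meta)
  traces <- dplyr::bind_rows(traces)

  # ---- OCR cohorts (null group differences) --------------------------------
  no <- config$n_ocr
  ocr_samples <- tibble::tibble(
    sample = c(sprintf("MITO_NoSE%02d", seq_len(no)),
               sprintf("MITO_SE%02d", seq_len(no))),
    group = rep(c("NoSE", "SE"), each = no))
  eff_ocr <- effect_lookup(config$effect_table, "ocr")
  lv <- config$ocr_levels
  sd_a <- cv_to_sdlog(config$noise$ocr_animal_cv)
  sd_s <- cv_to_sdlog(config$noise$ocr_stage_cv)
  stage_draw <- function(stage, level, fac) {
    eff <- if (stage %in% names(eff_ocr)) eff_ocr[[stage]] else 0
    level * fac * ln_factor(2 * no, sd_s) *
      ifelse(ocr_samples$group == "SE", 1 - eff, 1)
  }
  fac_c <- ln_factor(2 * no, sd_a)
  ocr_coupling <- ocr_samples
  for (st in c("state2", "state3adp", "state4o", "state3u"))
    ocr_coupling[[st]] <- stage_draw(st, lv$coupling[[st]], fac_c)
  ocr_coupling$nonmito <- lv$coupling[["nonmito"]] *
    ln_factor(2 * no, sd_s)
  ocr_coupling$protein <- lv$protein
  fac_e <- ln_factor(2 * no, sd_a)
  ocr_electron <- ocr_samples
  for (st in c("state3u", "post_rotenone", "post_succinate", "post_malonate"))
    ocr_electron[[st]] <- stage_draw(st, lv$electron[[st]], fac_e)
  ocr_electron$nonmito <- lv$electron[["nonmito"]] *
    ln_factor(2 * no, sd_s)
  ocr_electron$protein <- lv$protein

  structure(list(
    samples = samples, peaks = peaks,
    trace_meta = trace_meta, traces = traces,
    ocr_coupling = ocr_coupling, ocr_electron = ocr_electron,
    truth = list(enrichment = enrichment_true, concentration = conc_true,
                 activity = dplyr::bind_rows(act_true),
                 uptake_factor = tibble::tibble(sample = samples$sample,
                                                u = u)),
    config = config), class = "glucotrace_cohort")
}

#' @export
print.glucotrace_cohort <- function(x, ...) {
  cat(sprintf(
    "<glucotrace_cohort> %d + %d tracing animals, %d + %d enzyme, %d + %d OCR (seed %d)\n",
    x$config$n_nose, x$config$n_se, x$config$n_enzyme, x$config$n_enzyme,
    x$config$n_ocr, x$config$n_ocr, x$config$seed))
  cat(sprintf("  peaks: %d rows; traces: %d rows\n",
              nrow(x$peaks), nrow(x$traces)))
  invisible(x)
}
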