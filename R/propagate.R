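# Tracer propagation: glycolysis once, TCA cycle for one or two turns.

glycolytic_ids <- c("G6P", "F6P", "F16BP", "DHAP", "GA3P", "PG23", "PEP", "PYR")
tca_ids <- c("CIT", "ACO", "OG2", "SUC", "FUM", "MAL", "OAA")

pick_pool <- function(pools, metabolite) {
  pools[pools$metabolite == metabolite, , drop = FALSE]
}

relabel_pool <- function(pool, metabolite) {
  pool$metabolite <- metabolite
  pool
}

#' Propagate a positional glucose tracer through glycolysis and the TCA cycle
#'
#' Carries a positional tracer mask on glucose through the packaged atom maps.
#' Triose phosphate isomerase is modeled as complete equilibration: the
#' triose pools (and everything downstream of glyceraldehyde 3-phosphate) are
#' the equal mixture of the aldolase-derived halves, so each half of glucose
#' contributes one pyruvate. Turn-1 TCA pools arise from condensing the
#' tracer-derived acetyl-CoA with unlabeled oxaloacetate; turn-2 pools from
#' condensing the turn-1-derived oxaloacetate (after the fumarate symmetry
#' scrambling) with tracer-derived acetyl-CoA again. Dilution by unlabeled
#' acetyl-CoA is deliberately not modeled here: it is handled downstream as
#' enrichment fractions, so these pools describe labeled molecules only.
#'
#' @param net A `carbon_network` (default: the packaged network).
#' @param tracer Glucose label mask, e.g. `"111111"` for \[U-13C\]glucose or
#'   `"110000"` for \[1,2-13C\]glucose.
#' @param n_turns Number of TCA turns to follow (1 or 2).
#' @return A pool tibble with columns `metabolite`, `turn`, `mask`, `weight`.
#'   Glycolytic pools (and acetyl-CoA) are turn-independent and reported with
#'   `turn = 1`; TCA pools appear once per turn. The `OAA` pool at `turn = t`
#'   is the oxaloacetate produced by turn `t` (i.e. the pool entering the next
#'   turn).
#' @examples
#' pools <- propagate(tracer = "111111")
#' isotopologue_distribution(pools)
#' @export
propagate <- function(net = build_network(), tracer = "111111", n_turns = 2) {
  if (!grepl("^[01]{6}$", tracer))
    abort("tracer must be a 6-character glucose mask of 0/1")
  if (!n_turns %in% c(1, 2)) abort("n_turns must be 1 or 2")

  glc <- new_pool("GLC", tracer)
  g6p <- apply_reaction(net, "HK", glc)
  f6p <- apply_reaction(net, "PGI", g6p)
  f16bp <- apply_reaction(net, "PFK", f6p)
  trioses <- apply_reaction(net, "ALD", f16bp)
  dhap_raw <- pick_pool(trioses, "DHAP")
  ga3p_raw <- pick_pool(trioses, "GA3P")

  # complete triose-phosphate equilibration: each triose pool is the equal
  # mixture of its direct aldolase product and the isomerized other half
  ga3p <- merge_pool(dplyr::bind_rows(
    dplyr::mutate(ga3p_raw, weight = .data$weight / 2),
    dplyr::mutate(pick_pool(apply_reaction(net, "TPI", dhap_raw), "GA3P"),
                  weight = .data$weight / 2)))
  # TPI is its own inverse under the carbon map (1<->3), reused for DHAP
  dhap <- merge_pool(dplyr::bind_rows(
    dplyr::mutate(dhap_raw, weight = .data$weight / 2),
    dplyr::mutate(
      relabel_pool(
        pick_pool(apply_reaction(net, "TPI", relabel_pool(ga3p_raw, "DHAP")),
                  "GA3P"),
        "DHAP"),
      weight = .data$weight / 2)))

  pg23 <- apply_reaction(net, "GAPDH_PGM", ga3p)
  pep <- apply_reaction(net, "ENO", pg23)
  pyr <- apply_reaction(net, "PK", pep)
  accoa <- pick_pool(apply_reaction(net, "PDH", pyr), "ACCOA")

  run_turn <- function(oaa_pool) {
    cit <- pick_pool(apply_reaction(net, "CS",
                                    dplyr::bind_rows(accoa, oaa_pool)), "CIT")
    aco <- pick_pool(apply_reaction(net, "ACN", cit), "ACO")
    og2 <- pick_pool(apply_reaction(net, "IDH", aco), "OG2")
    suc <- pick_pool(apply_reaction(net, "OGDH", og2), "SUC")
    fum <- pick_pool(apply_reaction(net, "SDH", suc), "FUM")
    mal <- pick_pool(apply_reaction(net, "FH", fum), "MAL")
    oaa <- pick_pool(apply_reaction(net, "MDH", mal), "OAA")
    dplyr::bind_rows(cit, aco, og2, suc, fum, mal, oaa)
  }

  turn1 <- run_turn(unlabeled_pool(net, "OAA"))
  glyc <- dplyr::bind_rows(g6p, f6p, f16bp, dhap, ga3p, pg23, pep, pyr, accoa)
  out <- dplyr::bind_rows(
    dplyr::mutate(glyc, turn = 1L),
    dplyr::mutate(turn1, turn = 1L))
  if (n_turns == 2) {
    turn2 <- run_turn(pick_pool(turn1, "OAA"))
    out <- dplyr::bind_rows(out, dplyr::mutate(turn2, turn = 2L))
  }
  dplyr::select(out, "metabolite", "turn", "mask", "weight")
}
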