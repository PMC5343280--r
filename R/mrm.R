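# Labeled sMRM transition design from unlabeled Q1/Q3 bases and per-analyte
# fragment rules.

#' Read the packaged unlabeled transition table
#'
#' One row per analyte with the unlabeled (12C) Q1/Q3 masses and instrument
#' parameters (retention time, declustering potential, collision energy, cell
#' exit potential) for negative-mode \[M-H\]- acquisition.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return Tibble with columns Analyte, Q1, Q3, RT, DP, CE, CXP.
#' @export
unlabeled_transitions <- function(path = system.file(
    "extdata", "transitions_unlabeled.csv",
    package = "glucotrace", mustWork = TRUE)) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(Analyte = "c", .default = "d"))
}

#' Nominal integer base masses per analyte
#'
#' Rounds the unlabeled instrument Q1/Q3 values to the nearest integer; labeled
#' transition masses are computed additively on these nominal bases.
#'
#' @param table Unlabeled transition table (as from [unlabeled_transitions()]).
#' @return Tibble: analyte, base_q1, base_q3.
#' @examples
#' nominal_bases()
#' @export
nominal_bases <- function(table = unlabeled_transitions()) {
  tibble::tibble(analyte = table$Analyte,
                 base_q1 = as.integer(round(table$Q1)),
                 base_q3 = as.integer(round(table$Q3)))
}

#' Per-analyte fragment rules
#'
#' Describes which carbons are absent from the Q3 product ion. Phosphate-type
#' fragments (dihydrogen phosphate, 97 Da; phosphate, 79 Da) carry no carbon,
#' so Q3 is independent of labeling. Carboxyl-loss fragments lose exactly one
#' carboxyl group; for analytes with several carboxyls every one is an allowed
#' loss, so a labeled precursor can yield more than one product mass.
#'
#' @return Tibble: analyte, fragment ("phosphate" or "carboxyl"), lost
#'   (list column of integer vectors, the alternative lost carbon position
#'   sets; empty for phosphate fragments).
#' @export
fragment_rules <- function() {
  tibble::tibble(
    analyte = c("G6P", "F6P", "F16BP", "DHAP", "PG23", "PEP",
                "PYR", "CIT", "ACO", "OG2", "SUC", "FUM", "MAL"),
    fragment = c(rep("phosphate", 6), rep("carboxyl", 7)),
    lost = list(
      integer(0), integer(0), integer(0), integer(0), integer(0), integer(0),
      list(1L),                 # PYR: the C1 carboxyl
      list(1L, 4L, 6L),         # CIT: acetyl-derived, central, distal carboxyl
      list(1L, 4L, 6L),         # ACO: same skeleton as citrate
      list(1L, 5L),             # 2OG: either terminal carboxyl
      list(1L, 4L),             # SUC
      list(1L, 4L),             # FUM
      list(1L, 4L)))            # MAL
}

#' Derive labeled transitions for one analyte from an isotopomer pool
#'
#' For each distinct mass shift n in the pool, Q1 = base Q1 + n. Q3 values are
#' base Q3 + k for every retained-label count k achievable by removing one
#' allowed lost-carbon set from any pool mask of shift n; duplicates are
#' merged and output is sorted by (n, k). Instrument parameters are copied
#' from the unlabeled transition. An unlabeled member (n = 0) is emitted as
#' the original instrument-decimal transition.
#'
#' @param analyte Analyte id.
#' @param pool Pool tibble for that analyte (a `turn` column, if present, is
#'   carried through).
#' @param rule One row of [fragment_rules()] for the analyte (default looked
#'   up automatically).
#' @param base One row of the unlabeled transition table for the analyte.
#' @return Tibble: analyte, turn (if in pool), precursor_shift, product_shift,
#'   q1, q3, rt, dp, ce, cxp.
#' @examples
#' labeled_transitions("PYR", new_pool("PYR", "111"))
#' @export
labeled_transitions <- function(analyte, pool,
                                rule = NULL, base = NULL) {
  if (is.null(rule)) {
    rules <- fragment_rules()
    rule <- rules[rules$analyte == analyte, ]
  }
  if (is.null(base)) {
    tab <- unlabeled_transitions()
    base <- tab[tab$Analyte == analyte, ]
  }
  if (nrow(rule) != 1L) abort(sprintf("no fragment rule for analyte %s", analyte))
  if (nrow(base) != 1L) abort(sprintf("no unlabeled transition for analyte %s", analyte))
  if (!all(pool$metabolite == analyte))
    abort("pool metabolite does not match analyte")

  base_q1 <- as.integer(round(base$Q1))
  base_q3 <- as.integer(round(base$Q3))
  lost_sets <- rule$lost[[1]]

  has_turn <- "turn" %in% names(pool)
  shifts <- n_labels(pool$mask)
  if (any(shifts > nchar(pool$mask)))
    abort("pool contains shifts larger than the carbon count")

  per_mask <- function(i) {
    mask <- pool$mask[i]
    n <- n_labels(mask)
    bits <- mask_bits(mask)[[1]]
    if (rule$fragment == "phosphate") {
      k <- 0L
    } else {
      k <- vapply(lost_sets, function(ls) n - sum(bits[ls]), integer(1))
    }
    res <- tibble::tibble(precursor_shift = n, product_shift = unique(k))
    if (has_turn) res$turn <- pool$turn[i]
    res
  }

  keys <- dplyr::distinct(dplyr::bind_rows(lapply(seq_len(nrow(pool)), per_mask)))

  out <- dplyr::mutate(
    keys,
    analyte = analyte,
    q1 = ifelse(.data$precursor_shift == 0L, base$Q1,
                base_q1 + .data$precursor_shift),
    q3 = ifelse(.data$precursor_shift == 0L, base$Q3,
                base_q3 + .data$product_shift),
    rt = base$RT, dp = base$DP, ce = base$CE, cxp = base$CXP)
  cols <- c("analyte", if (has_turn) "turn", "precursor_shift",
            "product_shift", "q1", "q3", "rt", "dp", "ce", "cxp")
  dplyr::arrange(dplyr::select(out, dplyr::all_of(cols)),
                 .data$precursor_shift, .data$product_shift)
}

#' Design the full labeled transition table for a tracer experiment
#'
#' Propagates the tracer through the network and derives, for every measured
#' analyte, the unlabeled (shift 0) transition plus all labeled transitions of
#' each TCA turn. Note two deliberate rule-derived departures from common
#' printed lists: aconitate first-turn product ions are 86/87 (additive +1/+2
#' on the nominal base 85), and first-turn succinate products 74/75 are
#' included.
#'
#' @param net A `carbon_network`.
#' @param tracer Glucose mask (default \[U-13C\]glucose).
#' @param n_turns TCA turns to include (1 or 2).
#' @param table Unlabeled transition table.
#' @return Tibble: analyte, turn (0 for the unlabeled channel),
#'   precursor_shift, product_shift, q1, q3, rt, dp, ce, cxp.
#' @examples
#' design <- design_transitions()
#' design[design$analyte == "CIT", ]
#' @export
design_transitions <- function(net = build_network(), tracer = "111111",
                               n_turns = 2, table = unlabeled_transitions()) {
  pools <- propagate(net, tracer, n_turns)
  analytes <- table$Analyte
  out <- lapply(analytes, function(a) {
    base <- table[table$Analyte == a, ]
    pool <- pools[pools$metabolite == a, ]
    lab <- labeled_transitions(a, pool, base = base)
    lab <- lab[lab$precursor_shift > 0L, , drop = FALSE]
    unl <- tibble::tibble(
      analyte = a, turn = 0L, precursor_shift = 0L, product_shift = 0L,
      q1 = base$Q1, q3 = base$Q3, rt = base$RT, dp = base$DP,
      ce = base$CE, cxp = base$CXP)
    dplyr::bind_rows(unl, lab)
  })
  dplyr::bind_rows(out)
}

#' Write a transition table to CSV
#'
#' Emits the columns `Analyte, PrecursorShift, ProductShift, Q1, Q3, RT, DP,
#' CE, CXP` (comma separator, "." decimal); values round-trip exactly through
#' [read_transition_table()].
#'
#' @param specs Transition tibble (as from [design_transitions()]).
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_transition_table <- function(specs, path) {
  out <- tibble::tibble(
    Analyte = specs$analyte,
    PrecursorShift = specs$precursor_shift,
    ProductShift = specs$product_shift,
    Q1 = specs$q1, Q3 = specs$q3, RT = specs$rt,
    DP = specs$dp, CE = specs$ce, CXP = specs$cxp)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a transition table written by [write_transition_table()]
#'
#' @param path CSV path.
#' @return Transition tibble with the package's lower-case column names.
#' @export
read_transition_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(Analyte = "c", .default = "d"))
  tibble::tibble(
    analyte = x$Analyte,
    precursor_shift = as.integer(x$PrecursorShift),
    product_shift = as.integer(x$ProductShift),
    q1 = x$Q1, q3 = x$Q3, rt = x$RT, dp = x$DP, ce = x$CE, cxp = x$CXP)
}
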