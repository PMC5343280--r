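# Carbon-atom-mapped reaction network: glycolysis + two-turn TCA cycle.
#
# A network is a list with two tibbles:
#   $metabolites: id, carbon_count, symmetric
#   $maps:        reaction, substrate, sub_pos, product, prod_pos
# Carbons released as CO2 appear as product == "CO2". Positions are 1-based
# from the conventional C1 numbering of each metabolite.

#' Load a carbon-map network from plain-text tables
#'
#' Reads a metabolite table (id, carbon_count, symmetric) and an atom-map
#' table (reaction, substrate, sub_pos, product, prod_pos; one row per carbon)
#' and validates the carbon-map invariants: every substrate carbon appears
#' exactly once among product positions and CO2 losses, and every product
#' carbon is mapped exactly once.
#'
#' @param metabolites_path Path to a tab-separated metabolite table.
#' @param maps_path Path to a tab-separated atom-map table.
#' @return A `carbon_network` object (list with `$metabolites` and `$maps`).
#' @export
load_network <- function(metabolites_path, maps_path) {
  mets <- readr::read_tsv(metabolites_path, show_col_types = FALSE,
                          col_types = readr::cols(
                            id = "c", carbon_count = "i", symmetric = "l"))
  maps <- readr::read_tsv(maps_path, show_col_types = FALSE,
                          col_types = readr::cols(
                            reaction = "c", substrate = "c", sub_pos = "i",
                            product = "c", prod_pos = "i"))
  net <- structure(list(metabolites = mets, maps = maps),
                   class = "carbon_network")
  validate_network(net)
  net
}

#' Build the packaged glycolysis + TCA network
#'
#' Returns the packaged carbon-atom map: glucose -> G6P -> F6P -> F16BP ->
#' {DHAP, GA3P} (aldolase), DHAP <-> GA3P (triose phosphate isomerase),
#' GA3P -> 2+3PG -> PEP -> PYR; pyruvate dehydrogenase (PYR C1 lost as CO2,
#' C2/C3 become the acetyl carbons); citrate synthase condensation with
#' oxaloacetate; aconitase/isocitrate dehydrogenase (the CO2 released derives
#' from the OAA C1 carboxyl) and 2-oxoglutarate dehydrogenase (CO2 from the
#' OAA C4 carboxyl), so acetyl-derived carbons survive to succinate; succinate
#' and fumarate are flagged as 2-fold rotationally symmetric.
#'
#' 2- and 3-phosphoglycerate are merged into a single node `PG23` because
#' they are measured combined.
#'
#' @return A `carbon_network` object.
#' @examples
#' net <- build_network()
#' net$metabolites
#' @export
build_network <- function() {
  load_network(
    system.file("extdata", "metabolites.tsv", package = "glucotrace",
                mustWork = TRUE),
    system.file("extdata", "carbon_maps.tsv", package = "glucotrace",
                mustWork = TRUE))
}

#' Validate a carbon network
#'
#' Checks metabolite uniqueness, carbon counts, and carbon conservation for
#' every reaction (each substrate carbon mapped or lost exactly once; each
#' product carbon filled exactly once).
#'
#' @param net A `carbon_network`.
#' @return `net`, invisibly; aborts with a message on the first violation.
#' @export
validate_network <- function(net) {
  mets <- net$metabolites
  maps <- net$maps
  if (anyDuplicated(mets$id)) abort("duplicate metabolite ids in network")
  if (any(mets$carbon_count < 1)) abort("carbon_count must be >= 1")
  cc <- setNames(mets$carbon_count, mets$id)
  for (rxn in unique(maps$reaction)) {
    m <- maps[maps$reaction == rxn, ]
    for (s in unique(m$substrate)) {
      pos <- sort(m$sub_pos[m$substrate == s])
      want <- seq_len(cc[[s]])
      if (!identical(pos, want)) {
        abort(sprintf("reaction %s: substrate %s carbons not each used exactly once",
                      rxn, s))
      }
    }
    for (p in setdiff(unique(m$product), "CO2")) {
      pos <- sort(m$prod_pos[m$product == p])
      want <- seq_len(cc[[p]])
      if (!identical(pos, want)) {
        abort(sprintf("reaction %s: product %s carbons not each filled exactly once",
                      rxn, p))
      }
    }
  }
  invisible(net)
}

#' @export
print.carbon_network <- function(x, ...) {
  cat("<carbon_network> ", nrow(x$metabolites), " metabolites, ",
      length(unique(x$maps$reaction)), " reactions\n", sep = "")
  print(x$metabolites, n = Inf)
  invisible(x)
}

carbon_count <- function(net, metabolite) {
  net$metabolites$carbon_count[match(metabolite, net$metabolites$id)]
}

is_symmetric <- function(net, metabolite) {
  net$metabolites$symmetric[match(metabolite, net$metabolites$id)]
}

# ---- isotopomer pools -------------------------------------------------------

# A pool is a tibble: metabolite (chr), mask (chr of "0"/"1"), weight (dbl).

#' Construct a positional isotopomer pool
#'
#' @param metabolite Metabolite id.
#' @param masks Character vector of label masks, e.g. `"110000"` (1 = 13C).
#' @param weights Numeric weights; must sum to 1.
#' @return A pool tibble (metabolite, mask, weight).
#' @examples
#' new_pool("ACCOA", "11")
#' @export
new_pool <- function(metabolite, masks, weights = 1) {
  weights <- rep_len(weights, length(masks))
  pool <- tibble::tibble(metabolite = metabolite, mask = masks,
                         weight = as.numeric(weights))
  validate_pool(pool)
}

#' Validate an isotopomer pool
#'
#' Masks must be unique per metabolite, of equal length within a metabolite,
#' and weights must sum to 1 (tolerance 1e-9) per metabolite.
#'
#' @param pool A pool tibble.
#' @param net Optional `carbon_network`; if given, mask lengths are checked
#'   against the metabolite carbon counts.
#' @return `pool`, invisibly usable (returned).
#' @export
validate_pool <- function(pool, net = NULL) {
  stopifnot(all(c("metabolite", "mask", "weight") %in% names(pool)))
  if (!all(grepl("^[01]+$", pool$mask))) abort("masks must be strings of 0/1")
  for (m in unique(pool$metabolite)) {
    p <- pool[pool$metabolite == m, ]
    if (anyDuplicated(p$mask)) abort(sprintf("duplicate masks in pool for %s", m))
    if (length(unique(nchar(p$mask))) != 1L)
      abort(sprintf("mask lengths differ within pool for %s", m))
    if (abs(sum(p$weight) - 1) > 1e-9)
      abort(sprintf("pool weights for %s sum to %g, not 1", m, sum(p$weight)))
    if (!is.null(net)) {
      cc <- carbon_count(net, m)
      if (is.na(cc)) abort(sprintf("metabolite %s not in network", m))
      if (nchar(p$mask[1]) != cc)
        abort(sprintf("mask length %d != carbon_count %d for %s",
                      nchar(p$mask[1]), cc, m))
    }
  }
  pool
}

mask_bits <- function(mask) lapply(strsplit(mask, "", fixed = TRUE),
                                   function(x) x == "1")

mask_chr <- function(bits) paste(as.integer(bits), collapse = "")

n_labels <- function(mask) {
  vapply(strsplit(mask, "", fixed = TRUE),
         function(x) sum(x == "1"), integer(1))
}

unlabeled_pool <- function(net, metabolite) {
  new_pool(metabolite, strrep("0", carbon_count(net, metabolite)))
}

merge_pool <- function(pool) {
  out <- dplyr::summarise(dplyr::group_by(pool, .data$metabolite, .data$mask),
                          weight = sum(.data$weight), .groups = "drop")
  dplyr::arrange(out, .data$metabolite, dplyr::desc(.data$weight), .data$mask)
}

#' Apply 2-fold rotational symmetry scrambling to a pool
#'
#' For symmetric molecules (succinate, fumarate) each positional isotopomer is
#' replaced by an equal mixture of the mask and its reverse; duplicates are
#' merged. Applying the operation twice equals applying it once.
#'
#' @param pool A pool tibble for a single metabolite.
#' @return Scrambled pool tibble.
#' @export
scramble_pool <- function(pool) {
  rev_mask <- vapply(strsplit(pool$mask, "", fixed = TRUE),
                     function(x) paste(rev(x), collapse = ""), character(1))
  merge_pool(dplyr::bind_rows(
    dplyr::mutate(pool, weight = .data$weight / 2),
    dplyr::mutate(pool, mask = rev_mask, weight = .data$weight / 2)))
}

#' Apply one atom-mapped reaction to substrate pools
#'
#' Product masks are assembled carbon-by-carbon from the reaction's atom map.
#' For condensations the substrate pools are treated as independent (a product
#' isotopomer's weight is the product of its parents' weights). Labels on
#' carbons released as CO2 are discarded from the product masks but returned
#' as a `CO2` pseudo-pool so label conservation can be audited. Products of
#' symmetric metabolites are scrambled.
#'
#' @param net A `carbon_network`.
#' @param reaction Reaction name (must exist in `net$maps`).
#' @param pools A pool tibble containing one pool per substrate of the
#'   reaction.
#' @return A pool tibble with one pool per product (plus `CO2` when the
#'   reaction releases carbon).
#' @examples
#' net <- build_network()
#' apply_reaction(net, "PDH", new_pool("PYR", "111"))
#' @export
apply_reaction <- function(net, reaction, pools) {
  m <- net$maps[net$maps$reaction == reaction, ]
  if (nrow(m) == 0L) abort(sprintf("unknown reaction: %s", reaction))
  subs <- unique(m$substrate)
  missing <- setdiff(subs, unique(pools$metabolite))
  if (length(missing) > 0L)
    abort(sprintf("reaction %s: no pool supplied for substrate(s) %s",
                  reaction, paste(missing, collapse = ", ")))
  validate_pool(pools[pools$metabolite %in% subs, , drop = FALSE], net)

  sub_pools <- lapply(subs, function(s) pools[pools$metabolite == s, ])
  # cross join over substrate pool members
  idx <- expand.grid(lapply(sub_pools, function(p) seq_len(nrow(p))),
                     KEEP.OUT.ATTRS = FALSE)
  prods <- setdiff(unique(m$product), "CO2")
  lost <- m[m$product == "CO2", ]

  out <- vector("list", length(prods) + 1L)
  names(out) <- c(prods, "CO2")
  rows <- lapply(seq_len(nrow(idx)), function(i) {
    bits <- lapply(seq_along(subs), function(j)
      mask_bits(sub_pools[[j]]$mask[idx[i, j]])[[1]])
    names(bits) <- subs
    w <- prod(vapply(seq_along(subs), function(j)
      sub_pools[[j]]$weight[idx[i, j]], numeric(1)))
    masks <- vapply(prods, function(p) {
      pm <- m[m$product == p, ]
      out_bits <- logical(max(pm$prod_pos))
      out_bits[pm$prod_pos] <- mapply(function(s, sp) bits[[s]][sp],
                                      pm$substrate, pm$sub_pos)
      mask_chr(out_bits)
    }, character(1))
    co2 <- if (nrow(lost) > 0L)
      mask_chr(mapply(function(s, sp) bits[[s]][sp],
                      lost$substrate, lost$sub_pos))
    else NA_character_
    list(masks = masks, co2 = co2, weight = w)
  })

  res <- list()
  for (p in prods) {
    pool <- tibble::tibble(
      metabolite = p,
      mask = vapply(rows, function(r) r$masks[[p]], character(1)),
      weight = vapply(rows, function(r) r$weight, numeric(1)))
    pool <- merge_pool(pool)
    if (isTRUE(is_symmetric(net, p))) pool <- scramble_pool(pool)
    res[[p]] <- pool
  }
  if (nrow(lost) > 0L) {
    res[["CO2"]] <- merge_pool(tibble::tibble(
      metabolite = "CO2",
      mask = vapply(rows, function(r) r$co2, character(1)),
      weight = vapply(rows, function(r) r$weight, numeric(1))))
  }
  dplyr::bind_rows(res)
}

#' Collapse a positional pool to its isotopologue (mass-shift) distribution
#'
#' @param pool A pool tibble; may contain several metabolites and an optional
#'   `turn` column, which are kept as grouping variables.
#' @return Tibble with columns `metabolite` (and `turn` if present), `shift`
#'   (number of 13C labels, M+n) and `fraction`; fractions sum to 1 within
#'   each group.
#' @examples
#' isotopologue_distribution(new_pool("ACCOA", "11"))
#' @export
isotopologue_distribution <- function(pool) {
  grp <- intersect(c("metabolite", "turn"), names(pool))
  out <- dplyr::mutate(pool, shift = n_labels(.data$mask))
  out <- dplyr::summarise(
    dplyr::group_by(out, dplyr::across(dplyr::all_of(c(grp, "shift")))),
    fraction = sum(.data$weight), .groups = "drop_last")
  out <- dplyr::mutate(out, fraction = .data$fraction / sum(.data$fraction))
  dplyr::arrange(dplyr::ungroup(out),
                 dplyr::across(dplyr::all_of(c(grp, "shift"))))
}
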