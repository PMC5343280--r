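# Independent brute-force oracle for tracer propagation.
#
# Enumerates every positional path of a glucose label mask through glycolysis
# and up to two TCA turns using hard-coded index permutations (no use of the
# package's CarbonMap machinery), accumulating leaf probabilities per
# positional isotopomer.

# distribution = named numeric vector, names are mask strings like "0110"
dist_new <- function(mask, p = 1) setNames(p, paste(as.integer(mask), collapse = ""))

dist_merge <- function(...) {
  v <- c(...)
  tapply(v, names(v), sum)
}

dist_map <- function(d, f) {
  out <- numeric(0)
  for (k in names(d)) {
    m <- as.integer(strsplit(k, "")[[1]]) == 1L
    r <- f(m)
    out <- c(out, setNames(d[[k]], paste(as.integer(r), collapse = "")))
  }
  dist_merge(out)
}

dist_scramble <- function(d) {
  dist_merge(dist_map(d, identity) / 2, dist_map(d, rev) / 2)
}

# condense two distributions with a combiner f(mask1, mask2) -> mask
dist_cross <- function(d1, d2, f) {
  out <- numeric(0)
  for (k1 in names(d1)) for (k2 in names(d2)) {
    m1 <- as.integer(strsplit(k1, "")[[1]]) == 1L
    m2 <- as.integer(strsplit(k2, "")[[1]]) == 1L
    r <- f(m1, m2)
    out <- c(out, setNames(d1[[k1]] * d2[[k2]],
                           paste(as.integer(r), collapse = "")))
  }
  dist_merge(out)
}

oracle_tca_turn <- function(accoa, oaa) {
  cit <- dist_cross(accoa, oaa,
                    function(a, o) c(a[1], a[2], o[2], o[1], o[3], o[4]))
  aco <- cit
  og2 <- dist_map(cit, function(m) c(m[6], m[5], m[3], m[2], m[1]))
  suc <- dist_scramble(dist_map(og2, function(m) m[2:5]))
  fum <- dist_scramble(suc)
  mal <- fum
  oaa_out <- mal
  list(CIT = cit, ACO = aco, OG2 = og2, SUC = suc, FUM = fum, MAL = mal,
       OAA = oaa_out)
}

# full oracle: list turn1 = list(met = dist), turn2 = ...
oracle_propagate <- function(glc_mask) {
  g <- glc_mask
  dhap_raw <- dist_new(g[1:3])
  ga3p_raw <- dist_new(g[4:6])
  ga3p <- dist_merge(ga3p_raw / 2, dist_map(dhap_raw, rev) / 2)
  dhap <- dist_merge(dhap_raw / 2, dist_map(ga3p_raw, rev) / 2)
  pyr <- ga3p
  accoa <- dist_map(pyr, function(m) m[2:3])
  t1 <- oracle_tca_turn(accoa, dist_new(c(FALSE, FALSE, FALSE, FALSE)))
  t2 <- oracle_tca_turn(accoa, t1$OAA)
  glyc <- list(G6P = dist_new(g), F6P = dist_new(g), F16BP = dist_new(g),
               DHAP = dhap, GA3P = ga3p, PG23 = ga3p, PEP = ga3p, PYR = pyr,
               ACCOA = accoa)
  list(turn1 = c(glyc, t1), turn2 = t2)
}

# convert a propagate() pool subset to the oracle's named-vector form
pool_as_dist <- function(pools, metabolite, turn) {
  p <- pools[pools$metabolite == metabolite & pools$turn == turn, ]
  setNames(p$weight, p$mask)
}

expect_dist_equal <- function(actual, expected, tol = 1e-12) {
  expect_setequal(names(actual), names(expected))
  expected <- expected[names(actual)]
  expect_true(all(abs(actual - expected) < tol))
}
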