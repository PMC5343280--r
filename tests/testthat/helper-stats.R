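# closed-form balanced two-way decomposition (independent ANOVA oracle)
balanced_twoway_ss <- function(y, A, B) {
  ga <- tapply(y, A, mean); gb <- tapply(y, B, mean)
  gab <- tapply(y, list(A, B), mean)
  gm <- mean(y)
  r <- length(y) / (length(ga) * length(gb))  # replicates per cell
  ss_a <- r * length(gb) * sum((ga - gm)^2)
  ss_b <- r * length(ga) * sum((gb - gm)^2)
  ss_cells <- r * sum((gab - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_res <- sum((y - gab[cbind(as.character(A), as.character(B))])^2)
  list(a = ss_a, b = ss_b, ab = ss_ab, resid = ss_res)
}
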