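# Minimal exact-rational helpers for gamete/class probabilities.
# Denominators stay tiny (products of 2 and 6 per locus, squared for a gamete
# pair), so plain integer arithmetic is exact.

.gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

.gcd_vec <- function(x) Reduce(.gcd, x)

# reduce a vector of numerators over one common denominator
.reduce_frac <- function(num, den) {
  stopifnot(den > 0, all(num >= 0))
  g <- .gcd(.gcd_vec(num), den)
  if (g > 1) { num <- num / g; den <- den / g }
  list(num = as.integer(round(num)), den = as.integer(round(den)))
}

.frac_label <- function(num, den) {
  ifelse(num == 0, "0", paste0(num, "/", den))
}
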