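# Independent oracles, written from first principles and kept free of the
# package's own solver internals.

# One-site binding: closed-form quadratic for the complex concentration,
# PL = ((P + L + Kd) - sqrt((P + L + Kd)^2 - 4 P L)) / 2.
oracle_one_site <- function(kd, p_total, l_total) {
  s <- p_total + l_total + kd
  pl <- (s - sqrt(s^2 - 4 * p_total * l_total)) / 2
  list(pl = pl, l_free = l_total - pl,
       f = c(1 - pl / p_total, pl / p_total))
}

# Direct binding-polynomial mole fractions (plain arithmetic, no logs).
oracle_fractions <- function(l_free, kd) {
  terms <- c(1, cumprod(l_free / kd))
  terms / sum(terms)
}

# Free lipid by brute-force root finding of the mass-balance residual.
oracle_free_lipid <- function(kd, p_total, l_total) {
  if (l_total == 0) return(0)
  g <- function(L) {
    f <- oracle_fractions(L, kd)
    L + p_total * sum((0:length(kd)) * f) - l_total
  }
  stats::uniroot(g, c(0, l_total), tol = 1e-13 * max(1, l_total))$root
}

# Deterministic titration grid used across fitting tests (uM).
default_l_totals <- c(0, 1, 2.5, 5, 10, 15, 20, 25)
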