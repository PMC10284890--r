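# Independent oracles used across the test files.

# Brute-force CHONS enumerator, structured differently from the package's
# vectorised single-rounding implementation: nested loops over N, S, O, C
# with the hydrogen count enumerated via floor and ceiling of the solved
# value, each candidate checked against the mass window explicitly.
oracle_enumerate <- function(neutral_mass, tol_ppm) {
  m_h <- 1.00782503207; m_o <- 15.99491461956
  m_n <- 14.0030740048; m_s <- 31.97207100
  tol <- tol_ppm * 1e-6 * neutral_mass
  rows <- list()
  for (n in 0:1) for (s in 0:1) {
    for (o in 0:floor(neutral_mass / 15.994)) {
      base_nos <- m_o * o + m_n * n + m_s * s
      for (cc in 1:floor(neutral_mass / 12)) {
        rem <- neutral_mass - 12 * cc - base_nos
        if (rem < -tol) next
        h_star <- rem / m_h
        for (h in unique(c(floor(h_star), ceiling(h_star)))) {
          if (h < 0) next
          mass <- 12 * cc + m_h * h + base_nos
          if (abs(mass - neutral_mass) <= tol)
            rows[[length(rows) + 1]] <- c(c = cc, h = h, o = o, n = n, s = s)
        }
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(c = integer(0), h = integer(0), o = integer(0),
                      n = integer(0), s = integer(0)))
  out <- unique(as.data.frame(do.call(rbind, rows)))
  out <- out[order(out$c, out$h, out$o, out$n, out$s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# trapezoid rule written directly (for checking HIX band integrals)
oracle_trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# composition key for set comparisons
comp_key <- function(df) paste(df$c, df$h, df$o, df$n, df$s, sep = "_")
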