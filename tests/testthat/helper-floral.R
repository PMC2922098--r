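# Shared fixtures, built in code.

ref_topology <- default_topology()
ref_params <- reference_params()

# topology in which all affinities are negligible except the named ones:
# used for hand-computable mass-balance checks
sparse_gamma_topology <- function(...) {
  keep <- c(...)
  g <- stats::setNames(rep(1e-15, length(FLORAL_DIMERS)), FLORAL_DIMERS)
  g[names(keep)] <- keep
  default_topology(gamma = g)
}

# parameters with production, decay and triggers switched (almost) off,
# for conservation-law checks of the raw mass-action bookkeeping
inert_params <- function() {
  p <- reference_params()
  floral_params(beta = lapply(p$beta, function(b) b * 0 + 1e-12),
                km = p$km,
                dc = rep(1e-12, 6), p2 = 1e-12, p4 = 1e-12)
}

# plain fixed-step RK4 integrator, used as an independent oracle
rk4 <- function(f, y0, times) {
  out <- matrix(NA_real_, length(times), length(y0))
  out[1, ] <- y0
  y <- y0
  for (k in seq_len(length(times) - 1)) {
    h0 <- times[k + 1] - times[k]
    nsub <- max(1L, ceiling(h0 / 0.002))
    h <- h0 / nsub
    t <- times[k]
    for (s in seq_len(nsub)) {
      k1 <- f(t, y); k2 <- f(t + h / 2, y + h / 2 * k1)
      k3 <- f(t + h / 2, y + h / 2 * k2); k4 <- f(t + h, y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    out[k + 1, ] <- y
  }
  out
}

# day-5 on/off truth table of the expression pattern (gene x whorl)
table2_day5 <- function() {
  m <- matrix(FALSE, 6, 4, dimnames = list(FLORAL_GENES, paste0("w", 1:4)))
  m["AP1", 1:2] <- TRUE
  m["AP3", 2:3] <- TRUE
  m["PI", 2:3] <- TRUE
  m["AG", 3:4] <- TRUE
  m["SHP", 4] <- TRUE
  m["SEP", ] <- TRUE
  m
}
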