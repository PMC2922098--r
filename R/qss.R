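# Quasi-steady-state reduction: dimers equilibrate on a timescale of minutes
# while monomer turnover acts on hours-to-days, so each dimer concentration
# is slaved to the instantaneous monomer concentrations.

#' Quasi-steady-state dimer concentration
#'
#' At dimer equilibrium the association and dissociation fluxes balance, so
#' \[xi xj\] = gamma * xi * xj (gamma * xi^2 for a homodimer), with gamma the
#' affinity ratio Kon/Koff in nM^-1.
#'
#' @param xi,xj Monomer concentrations in nM (equal arguments for a
#'   homodimer).
#' @param gamma Affinity ratio in nM^-1.
#' @return Dimer concentration in nM.
#' @export
#' @examples
#' qss_dimer(10, 20, 0.1)   # 20 nM
#' qss_dimer(100, 100, 0.01) # homodimer: 100 nM
qss_dimer <- function(xi, xj, gamma) {
  if (any(xi < 0) || any(xj < 0)) stop("monomer concentrations must be >= 0")
  gamma * xi * xj
}

# internal: all QSS dimer concentrations for a monomer state vector
qss_dimer_vec <- function(x, env) {
  env$gamma * x[env$i1] * x[env$i2]
}

#' Total (monomer + dimer-bound) concentrations from monomers
#'
#' Mass balance per gene: the measurable total is the free monomer plus one
#' unit for every heterodimer containing the gene and two units for every
#' homodimer (each homodimer consumes two monomers).
#'
#' @param x Numeric 6-vector of monomer concentrations (nM), gene order.
#' @param topology A `floral_topology`.
#' @return Named 6-vector of total concentrations.
#' @export
#' @examples
#' totals_from_monomers(rep(100, 6))
totals_from_monomers <- function(x, topology = default_topology()) {
  if (any(x < 0)) stop("monomer concentrations must be >= 0")
  env <- if (inherits(topology, "floral_topology")) topology_env(topology) else topology
  D <- qss_dimer_vec(x, env)
  tot <- as.numeric(x)
  for (k in seq_along(D)) {
    if (env$homo[k]) tot[env$i1[k]] <- tot[env$i1[k]] + 2 * D[k]
    else {
      tot[env$i1[k]] <- tot[env$i1[k]] + D[k]
      tot[env$i2[k]] <- tot[env$i2[k]] + D[k]
    }
  }
  stats::setNames(tot, FLORAL_GENES)
}

#' State-dependent mass matrix of the reduced model
#'
#' Eliminating the dimers by the chain rule turns the six monomer balances
#' into M(x) dx/dt = g(x, t), where g collects production, trigger and decay
#' and M absorbs the dimerization fluxes:
#' M_ii = 1 + sum over heterodimer partners j of gamma_ij xj + 4 gamma_ii xi,
#' M_ij = gamma_ij xi for heterodimer partners, 0 otherwise. M is strictly
#' diagonally dominant by columns for non-negative states, hence always
#' invertible; it is also the Jacobian of [totals_from_monomers()], which
#' the Newton inversion exploits.
#'
#' @param x Numeric 6-vector of monomer concentrations (nM).
#' @param topology A `floral_topology`.
#' @return A 6 x 6 numeric matrix (dimensionless).
#' @export
#' @examples
#' mass_matrix(rep(0, 6))  # identity: no dimer load at zero concentration
mass_matrix <- function(x, topology = default_topology()) {
  env <- if (inherits(topology, "floral_topology")) topology_env(topology) else topology
  M <- diag(6)
  for (k in seq_along(env$gamma)) {
    i <- env$i1[k]; j <- env$i2[k]; g <- env$gamma[k]
    if (env$homo[k]) {
      M[i, i] <- M[i, i] + 4 * g * x[i]
    } else {
      M[i, i] <- M[i, i] + g * x[j]
      M[i, j] <- M[i, j] + g * x[i]
      M[j, j] <- M[j, j] + g * x[i]
      M[j, i] <- M[j, i] + g * x[j]
    }
  }
  M
}

#' Invert the mass balance: monomers from measured totals
#'
#' Solves totals_from_monomers(x) = totals for the unique non-negative
#' monomer vector by damped Newton iteration with positivity projection.
#' The Jacobian of the forward map is the mass matrix, strictly diagonally
#' dominant, so the iteration is well conditioned; damping halves the step
#' whenever the residual fails to decrease.
#'
#' @param totals Numeric 6-vector of total concentrations (nM).
#' @param topology A `floral_topology`.
#' @param tol Relative residual tolerance.
#' @param max_iter Maximum Newton iterations.
#' @return Named 6-vector of monomer concentrations.
#' @export
#' @examples
#' x <- c(100, 5, 5, 50, 5, 200)
#' xr <- monomers_from_totals(totals_from_monomers(x))
#' max(abs(xr - x) / x)  # ~1e-12
monomers_from_totals <- function(totals, topology = default_topology(),
                                 tol = 1e-10, max_iter = 100L) {
  if (any(totals < 0)) stop("total concentrations must be >= 0")
  env <- if (inherits(topology, "floral_topology")) topology_env(topology) else topology
  x <- as.numeric(totals)
  scale <- 1 + max(totals)
  fwd <- function(x) totals_from_monomers(x, env)
  r <- fwd(x) - totals
  for (it in seq_len(max_iter)) {
    if (max(abs(r)) <= tol * scale) break
    step <- solve(mass_matrix(x, env), r)
    lambda <- 1
    repeat {
      xn <- pmax(x - lambda * step, 0)
      rn <- fwd(xn) - totals
      if (max(abs(rn)) < max(abs(r)) || lambda < 1e-10) break
      lambda <- lambda / 2
    }
    x <- xn; r <- rn
  }
  if (max(abs(r)) > tol * scale)
    stop(sprintf("mass-balance inversion did not converge: residual %.3e after %d iterations",
                 max(abs(r)), max_iter))
  stats::setNames(x, FLORAL_GENES)
}
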