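# Transcription kinetics and the two dynamical models: the full coupled
# monomer+dimer system (13 states per whorl) and its quasi-steady-state
# reduction (6 states, state-dependent mass matrix).

#' Transcriptional production rate of one gene
#'
#' Regulation follows the occupancy logic that transcription proceeds when
#' at least one activation site is bound and every repression site is empty:
#' a sum of Michaelis-Menten activation terms, one beta and Km per
#' activating dimer, multiplied by a repression factor Km/(Km + R) per
#' repressing dimer. The result lies in \[0, sum(beta)\].
#'
#' @param gene Gene name or index.
#' @param dimer_conc Named numeric vector of dimer concentrations (nM),
#'   names as in `FLORAL_DIMERS`.
#' @param params A `floral_params`.
#' @param topology A `floral_topology`.
#' @return Production rate in nM/day.
#' @export
#' @examples
#' # half-maximal activation: SHP at [AG SEP] = Km with no repressor bound
#' p <- reference_params()
#' production_rate("SHP", c("AG:SEP" = p$km$SHP[1], "AP3:PI" = 0), p)  # beta/2
production_rate <- function(gene, dimer_conc, params = reference_params(),
                            topology = default_topology()) {
  i <- gene_index(gene)
  g <- FLORAL_GENES[i]
  acts <- topology$activators[[g]]
  reps <- topology$repressors[[g]]
  need <- c(acts, reps)
  if (!all(need %in% names(dimer_conc)))
    stop("missing dimer concentration(s): ",
         paste(setdiff(need, names(dimer_conc)), collapse = ", "))
  A <- dimer_conc[acts]
  if (any(A < 0) || any(dimer_conc[need] < 0)) stop("dimer concentrations must be >= 0")
  kma <- params$km[[g]][seq_along(acts)]
  out <- sum(params$beta[[g]] * A / (kma + A))
  if (length(reps)) {
    kmr <- params$km[[g]][length(acts) + seq_along(reps)]
    out <- out * prod(kmr / (kmr + dimer_conc[reps]))
  }
  unname(out)
}

# internal: vectorized production for all six genes given dimer vector D
production_vec <- function(D, env, beta, km) {
  out <- numeric(6)
  for (i in 1:6) {
    a <- env$aidx[[i]]
    kmi <- km[[i]]
    s <- sum(beta[[i]] * D[a] / (kmi[seq_along(a)] + D[a]))
    r <- env$ridx[[i]]
    if (length(r))
      s <- s * prod(kmi[length(a) + seq_along(r)] / (kmi[length(a) + seq_along(r)] + D[r]))
    out[i] <- s
  }
  out
}

# internal: trigger vector at time t in whorl w
trigger_vec <- function(t, whorl, schedule, params) {
  v <- numeric(6)
  if (t >= schedule$t_on && t < schedule$t_off) {
    if (whorl %in% schedule$p2_whorls) v[2] <- params$p2
    if (whorl %in% schedule$p4_whorls) v[4] <- params$p4
  }
  v
}

#' Right-hand side of the full coupled monomer+dimer model
#'
#' State: 6 monomers followed by the 7 dimers (topology order), 13 variables
#' in all. Dimer rates are mass action, Kon xi xj - Koff \[xi xj\]; monomer
#' rates are production + trigger - decay minus the dimerization fluxes
#' (with stoichiometry 2 for homodimers). Kon is gamma * Koff per dimer, so
#' the reduced model's affinities are recovered in the fast-dimerization
#' limit.
#'
#' @param state Numeric 13-vector (monomers then dimers), all >= 0.
#' @param t Time in days.
#' @param whorl Whorl id 1..4.
#' @param topology,params,schedule Model specification.
#' @param koff Dissociation rate in 1/day (default 1440, i.e. 1/min).
#' @return Numeric 13-vector of time derivatives (nM/day).
#' @export
coupled_rhs <- function(state, t, whorl, topology = default_topology(),
                        params = reference_params(),
                        schedule = trigger_schedule(), koff = 1440) {
  if (any(state < 0)) stop("negative concentrations are not admissible")
  env <- if (inherits(topology, "floral_topology")) topology_env(topology) else topology
  x <- state[1:6]
  D <- state[7:13]
  kon <- env$gamma * koff
  flux <- kon * x[env$i1] * x[env$i2] - koff * D
  dx <- production_vec(D, env, params$beta, params$km) +
    trigger_vec(t, whorl, schedule, params) - params$dc * x
  for (k in seq_along(flux)) {
    if (env$homo[k]) dx[env$i1[k]] <- dx[env$i1[k]] - 2 * flux[k]
    else {
      dx[env$i1[k]] <- dx[env$i1[k]] - flux[k]
      dx[env$i2[k]] <- dx[env$i2[k]] - flux[k]
    }
  }
  c(dx, flux)
}

#' Simulate the full coupled model in one whorl
#'
#' Adaptive integration (lsoda) of the 13-state system, restarted at the
#' trigger window edges so the day-scale discontinuities do not degrade the
#' step control.
#'
#' @param initial Numeric 13-vector (monomers then dimers) or a 6-vector of
#'   monomers (dimers then start at their QSS values).
#' @param times Output times in days (within \[0, 10\]).
#' @param whorl Whorl id 1..4.
#' @param topology,params,schedule Model specification.
#' @param koff Dissociation rate (1/day).
#' @param rtol,atol Solver tolerances.
#' @return Matrix with a `time` column, 6 monomer and 7 dimer columns.
#' @export
simulate_full <- function(initial, times, whorl, topology = default_topology(),
                          params = reference_params(),
                          schedule = trigger_schedule(), koff = 1440,
                          rtol = 1e-7, atol = 1e-6) {
  if (max(times) > 10 || min(times) < 0) stop("times must lie within [0, 10] days")
  env <- topology_env(topology)
  if (length(initial) == 6) initial <- c(initial, qss_dimer_vec(initial, env))
  stopifnot(length(initial) == 13)
  rhs <- function(t, y, p) {
    y <- pmax(y, 0)
    list(coupled_rhs(y, t, whorl, env, params, schedule, koff))
  }
  out <- integrate_piecewise(rhs, initial, times,
                             breaks = c(schedule$t_on, schedule$t_off),
                             rtol = rtol, atol = atol)
  colnames(out) <- c("time", FLORAL_GENES, env$dnames)
  out
}

# internal: lsoda with restarts at interior break points (trigger edges)
integrate_piecewise <- function(rhs, y0, times, breaks, rtol, atol) {
  breaks <- sort(unique(breaks[breaks > min(times) & breaks < max(times)]))
  edges <- c(min(times), breaks, max(times))
  rows <- NULL
  y <- y0
  for (s in seq_len(length(edges) - 1)) {
    t0 <- edges[s]; t1 <- edges[s + 1]
    tt <- sort(unique(c(t0, times[times > t0 & times <= t1], t1)))
    seg <- deSolve::ode(y = y, times = tt, func = rhs, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol,
                        maxsteps = 1e5)
    if (attr(seg, "istate")[1] < 0)
      stop(sprintf("solver failure near t = %.4f days", seg[nrow(seg), 1]))
    y <- pmax(as.numeric(seg[nrow(seg), -1]), 0)
    keep <- seg[, 1] %in% times & !(seg[, 1] %in% (if (is.null(rows)) numeric(0) else rows[, 1]))
    rows <- rbind(rows, seg[keep, , drop = FALSE])
  }
  rows <- rows[order(rows[, 1]), , drop = FALSE]
  unclass(rows)
}

#' Right-hand side of the reduced six-variable model
#'
#' @param x Monomer 6-vector (nM).
#' @param t Time in days.
#' @param whorl Whorl id 1..4.
#' @param topology,params,schedule Model specification.
#' @return Numeric 6-vector dx/dt obtained by solving M(x) dx/dt = g(x, t).
#' @export
reduced_rhs <- function(x, t, whorl, topology = default_topology(),
                        params = reference_params(),
                        schedule = trigger_schedule()) {
  env <- if (inherits(topology, "floral_topology")) topology_env(topology) else topology
  x <- pmax(x, 0)
  D <- qss_dimer_vec(x, env)
  g <- production_vec(D, env, params$beta, params$km) +
    trigger_vec(t, whorl, schedule, params) - params$dc * x
  as.numeric(solve(mass_matrix(x, env), g))
}

#' Simulate the reduced model in one whorl
#'
#' Integrates M(x) dx/dt = production + trigger - decay with the same solver
#' contract as [simulate_full()]. Dimer and total trajectories are derived
#' from the monomers through the quasi-steady-state relations.
#'
#' @param initial Monomer 6-vector (nM).
#' @param times Output times in days.
#' @param whorl Whorl id 1..4.
#' @param topology,params,schedule Model specification.
#' @param rtol,atol Solver tolerances.
#' @param knockout Optional gene names whose production and concentration
#'   are clamped to zero (in-silico null mutants).
#' @param pin Optional named vector of monomer levels (nM) held constant
#'   (in-silico ectopic expression).
#' @return Object of class `whorl_trajectory`: list with `times`, `whorl`,
#'   `monomers` (time x gene matrix), `dimers`, `totals`.
#' @export
#' @examples
#' x0 <- monomers_from_totals(c(1e3, 10, 10, 10, 10, 1e3))
#' tr <- simulate_reduced(x0, 0:5, whorl = 1)
#' tr$totals[6, ]  # day-5 totals: AP1 and SEP high, rest low
simulate_reduced <- function(initial, times, whorl,
                             topology = default_topology(),
                             params = reference_params(),
                             schedule = trigger_schedule(),
                             rtol = 1e-7, atol = 1e-6,
                             knockout = NULL, pin = NULL) {
  if (max(times) > 10 || min(times) < 0) stop("times must lie within [0, 10] days")
  stopifnot(length(initial) == 6)
  env <- topology_env(topology)
  ko <- if (length(knockout)) gene_index(knockout) else integer(0)
  pidx <- if (length(pin)) gene_index(names(pin)) else integer(0)
  initial <- as.numeric(initial)
  initial[ko] <- 0
  initial[pidx] <- as.numeric(pin)
  rhs <- function(t, y, p) {
    y <- pmax(y, 0)
    y[ko] <- 0
    D <- qss_dimer_vec(y, env)
    g <- production_vec(D, env, params$beta, params$km) +
      trigger_vec(t, whorl, schedule, params) - params$dc * y
    g[ko] <- 0
    dx <- as.numeric(solve(mass_matrix(y, env), g))
    dx[ko] <- 0
    dx[pidx] <- 0
    list(dx)
  }
  out <- integrate_piecewise(rhs, as.numeric(initial), times,
                             breaks = c(schedule$t_on, schedule$t_off),
                             rtol = rtol, atol = atol)
  mono <- pmax(out[, -1, drop = FALSE], 0)
  colnames(mono) <- FLORAL_GENES
  dim_m <- t(apply(mono, 1, qss_dimer_vec, env = env))
  colnames(dim_m) <- env$dnames
  tot <- t(apply(mono, 1, totals_from_monomers, topology = env))
  structure(list(times = out[, 1], whorl = whorl, monomers = mono,
                 dimers = dim_m, totals = tot),
            class = "whorl_trajectory")
}

#' Simulate all four whorls of the reduced model
#'
#' @param initial_totals Named 6-vector of day-0 total concentrations;
#'   monomer initial conditions come from the mass-balance inversion.
#' @param times Output times in days.
#' @param topology,params,schedule,rtol,atol As [simulate_reduced()].
#' @return Object of class `flower_trajectory`: list of four
#'   `whorl_trajectory` objects.
#' @export
simulate_flower <- function(initial_totals = default_initial_totals(),
                            times = 0:5,
                            topology = default_topology(),
                            params = reference_params(),
                            schedule = trigger_schedule(),
                            rtol = 1e-7, atol = 1e-6) {
  x0 <- monomers_from_totals(initial_totals, topology)
  out <- lapply(1:4, function(w)
    simulate_reduced(x0, times, w, topology, params, schedule, rtol, atol))
  structure(out, class = "flower_trajectory")
}

#' Day-0 total concentrations of the reference conditions
#'
#' AP1 is induced at time zero and the E-class SEP is abundant everywhere at
#' all times, so both start at the data on-level (1000 nM total); the other
#' genes start at the 1% off-level (10 nM). Identical across whorls: before
#' the triggers act the meristem is spatially uniform.
#'
#' @param on_level On-level total concentration in nM.
#' @return Named 6-vector of totals.
#' @export
default_initial_totals <- function(on_level = 1e3) {
  stats::setNames(c(on_level, rep(on_level / 100, 4), on_level), FLORAL_GENES)
}
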