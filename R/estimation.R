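# Decoupling-based parameter identification. Each gene's equation contains
# only its own parameters, so after replacing the other five concentrations
# (and their derivatives) by interpolated data the six equations can be
# fitted independently by bounded nonlinear least squares.

#' Monomer data grid from measured totals
#'
#' Applies the mass-balance inversion independently at every (whorl, day)
#' grid point, converting measured total concentrations into the free
#' monomer concentrations the reduced model evolves.
#'
#' @param totals Numeric array gene x whorl x day of totals (nM).
#' @param topology A `floral_topology`.
#' @return Array of the same shape with monomer concentrations.
#' @export
monomer_data <- function(totals, topology = default_topology()) {
  env <- topology_env(topology)
  out <- totals
  for (w in seq_len(dim(totals)[2])) for (d in seq_len(dim(totals)[3])) {
    out[, w, d] <- tryCatch(
      monomers_from_totals(totals[, w, d], env),
      error = function(e) stop("inversion failed at whorl ", w, ", day index ", d,
                               ": ", conditionMessage(e)))
  }
  out
}

#' Piecewise-linear interpolant and forward-difference derivative
#'
#' Interpolates a daily series linearly and estimates its derivative by the
#' forward difference on each day interval, right-continuous at the knots
#' (the simple Euler-style interpolation used for the fixed inputs of the
#' decoupled equations).
#'
#' @param days Numeric vector of sample times (>= 2 points, increasing).
#' @param values Numeric vector of the same length.
#' @return List with functions `value(t)` and `deriv(t)`.
#' @export
#' @examples
#' f <- interpolate_fixed(c(0, 1), c(0, 100))
#' f$value(0.5)  # 50
#' f$deriv(0.2)  # 100 on the whole interval
interpolate_fixed <- function(days, values) {
  if (length(days) < 2) stop("need at least two time points")
  if (is.unsorted(days, strictly = TRUE)) stop("days must be strictly increasing")
  vf <- stats::approxfun(days, values, rule = 2)
  slopes <- diff(values) / diff(days)
  df <- function(t) {
    k <- findInterval(t, days, rightmost.closed = FALSE)
    k <- pmin(pmax(k, 1L), length(slopes))
    slopes[k]
  }
  list(value = vf, deriv = df)
}

#' Assemble the decoupled estimation problem for one gene
#'
#' @param gene Gene name or index.
#' @param monomers Numeric array gene x whorl x day of monomer data (nM).
#' @param days Numeric vector of the sampled days.
#' @param topology,schedule Model structure.
#' @param bounds Bounds list from [parameter_bounds()].
#' @return Object of class `estimation_problem`.
#' @export
estimation_problem <- function(gene, monomers, days = 0:5,
                               topology = default_topology(),
                               schedule = trigger_schedule(),
                               bounds = parameter_bounds()) {
  i <- gene_index(gene)
  stopifnot(dim(monomers)[1] == 6, dim(monomers)[3] == length(days))
  fixed <- lapply(seq_len(dim(monomers)[2]), function(w)
    lapply(1:6, function(j) interpolate_fixed(days, monomers[j, w, ])))
  structure(list(gene = i, monomers = monomers, days = days,
                 fixed = fixed, topology = topology, env = topology_env(topology),
                 schedule = schedule, bounds = bounds),
            class = "estimation_problem")
}

# internal: integrate the decoupled scalar equation of problem$gene in one
# whorl, given a candidate parameter set, returning values at problem$days.
integrate_decoupled <- function(problem, params, whorl) {
  i <- problem$gene
  env <- problem$env
  fx <- problem$fixed[[whorl]]
  days <- problem$days
  # heterodimer partners of gene i (for mass-matrix row terms)
  het <- which((env$i1 == i | env$i2 == i) & !env$homo)
  het_partner <- ifelse(env$i1[het] == i, env$i2[het], env$i1[het])
  het_gamma <- env$gamma[het]
  homo_k <- which(env$i1 == i & env$homo)
  homo_gamma <- if (length(homo_k)) env$gamma[homo_k] else 0
  sched <- problem$schedule
  rhs <- function(t, y, p) {
    xi <- max(y[1], 0)
    x <- vapply(1:6, function(j) if (j == i) xi else max(fx[[j]]$value(t), 0), numeric(1))
    D <- qss_dimer_vec(x, env)
    a <- env$aidx[[i]]
    kmi <- params$km[[FLORAL_GENES[i]]]
    g <- sum(params$beta[[FLORAL_GENES[i]]] * D[a] / (kmi[seq_along(a)] + D[a]))
    r <- env$ridx[[i]]
    if (length(r))
      g <- g * prod(kmi[length(a) + seq_along(r)] / (kmi[length(a) + seq_along(r)] + D[r]))
    g <- g + trigger_vec(t, whorl, sched, params)[i] - params$dc[i] * xi
    if (length(het))
      g <- g - xi * sum(het_gamma * vapply(het_partner, function(j) fx[[j]]$deriv(t), numeric(1)))
    Mii <- 1 + 4 * homo_gamma * xi +
      (if (length(het)) sum(het_gamma * x[het_partner]) else 0)
    list(g / Mii)
  }
  y0 <- problem$monomers[i, whorl, 1]
  out <- integrate_piecewise(rhs, y0, days, breaks = c(sched$t_on, sched$t_off),
                             rtol = 1e-6, atol = 1e-6)
  pmax(out[, 2], 0)
}

# internal: residual vector (model - data) over all whorls, days > day 0
decoupled_residuals <- function(problem, params) {
  i <- problem$gene
  unlist(lapply(seq_len(dim(problem$monomers)[2]), function(w) {
    sim <- integrate_decoupled(problem, params, w)
    (sim - problem$monomers[i, w, ])[-1]
  }))
}

#' Initialize half-maximal constants at typical dimer signals
#'
#' A Michaelis-Menten function is most sensitive to its Km when the input
#' sits at the half-maximal point, so each Km starts at the typical
#' concentration of its governing dimer signal (computed from typical
#' monomer on-levels through the quasi-steady-state relation), clipped to
#' the nominal Km range.
#'
#' @param typical Named 6-vector of typical monomer concentrations (nM).
#' @param topology A `floral_topology`.
#' @param clip Length-2 range to clip to (nominal Km bounds).
#' @return Named list gene -> Km initial vector (activator slots first,
#'   then repressor slots).
#' @export
initialize_km <- function(typical, topology = default_topology(),
                          clip = parameter_bounds()$nominal$km) {
  env <- topology_env(topology)
  D <- qss_dimer_vec(as.numeric(typical[FLORAL_GENES]), env)
  out <- lapply(FLORAL_GENES, function(g) {
    slots <- c(match(topology$activators[[g]], env$dnames),
               match(topology$repressors[[g]], env$dnames))
    pmin(pmax(D[slots], clip[1]), clip[2])
  })
  stats::setNames(out, FLORAL_GENES)
}

#' Perturb a parameter set multiplicatively
#'
#' Standard starting point for recovery experiments: every parameter of the
#' given set is multiplied by a seeded random factor drawn log-uniformly in
#' \[1/factor, factor\], so the optimizer must travel up to `factor`-fold in
#' every coordinate to recover the generating trajectories.
#'
#' @param params A `floral_params`.
#' @param factor Maximal multiplicative perturbation (> 1).
#' @param seed Integer seed.
#' @return A perturbed `floral_params`.
#' @export
perturb_params <- function(params, factor = 3, seed = 1L) {
  if (factor <= 1) stop("factor must be > 1")
  set.seed(seed)
  jit <- function(v) v * exp(stats::runif(length(v), -log(factor), log(factor)))
  floral_params(beta = lapply(params$beta, jit), km = lapply(params$km, jit),
                dc = jit(params$dc), p2 = jit(params$p2), p4 = jit(params$p4))
}

# internal: default initial parameter guess for one gene's fit
default_init <- function(problem, params_template = NULL) {
  i <- problem$gene
  g <- FLORAL_GENES[i]
  topo <- problem$topology
  na <- length(topo$activators[[g]]); nr <- length(topo$repressors[[g]])
  b <- parameter_bounds()
  # typical on-levels: mean of each gene's day>=2 data over its loudest whorl
  typ <- vapply(1:6, function(j) max(apply(problem$monomers[j, , -(1:2), drop = FALSE], 1, mean)),
                numeric(1))
  km0 <- initialize_km(stats::setNames(typ, FLORAL_GENES), topo)[[g]]
  beta0 <- rep(exp(mean(log(b$nominal$beta_sum))) / na, na)
  dc0 <- exp(mean(log(b$nominal$dc)))
  v <- c(stats::setNames(beta0, paste0("beta", seq_len(na))),
         stats::setNames(km0, paste0("km", seq_len(na + nr))),
         dc = dc0)
  if (i %in% c(2L, 4L)) v <- c(v, p = 1e4)
  v
}

#' Fit the decoupled equation of one gene
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt on log10-scaled
#' parameters) of the gene's scalar equation against its monomer data in
#' all whorls. The day-0 points serve as initial conditions and are not part
#' of the residual. Multi-start: `restarts` seeded re-initializations jitter
#' the starting point by up to a factor two per parameter; the best
#' objective wins.
#'
#' @param problem An [estimation_problem()].
#' @param init Named initial parameter vector (see [gene_free_params()]);
#'   default built from [initialize_km()] and mid-range rates.
#' @param restarts Number of jittered restarts (0 = single run).
#' @param seed Integer seed controlling the jitter.
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @return Object of class `fit_result`: fitted `params_vector`, `objective`
#'   (residual sum of squares), `epsilon` (gene's signed mean relative error
#'   per whorl), `at_nominal_bound` flags, convergence info.
#' @export
fit_equation <- function(problem, init = NULL, restarts = 2L, seed = 1L,
                         maxiter = 60L) {
  i <- problem$gene
  g <- FLORAL_GENES[i]
  if (is.null(init)) init <- default_init(problem)
  b <- parameter_bounds()$fit
  topo <- problem$topology
  na <- length(topo$activators[[g]]); nr <- length(topo$repressors[[g]])
  lower <- c(rep(b$beta[1], na), rep(b$km[1], na + nr), b$dc[1])
  upper <- c(rep(b$beta[2], na), rep(b$km[2], na + nr), b$dc[2])
  if (i %in% c(2L, 4L)) { lower <- c(lower, b$trigger[1]); upper <- c(upper, b$trigger[2]) }
  init <- pmin(pmax(init, lower), upper)

  template <- reference_params()
  resid_fn <- function(lpar) {
    pv <- 10^lpar
    pars <- set_gene_params(template, g, pv)
    r <- try(decoupled_residuals(problem, pars), silent = TRUE)
    if (inherits(r, "try-error")) rep(1e6, 4 * (length(problem$days) - 1)) else r
  }
  starts <- list(log10(init))
  if (restarts > 0) {
    set.seed(seed)
    for (k in seq_len(restarts))
      starts[[k + 1]] <- log10(init) + stats::runif(length(init), -log10(2), log10(2))
  }
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, log10(lower)), log10(upper))
    fit <- minpack.lm::nls.lm(par = s, fn = resid_fn,
                              lower = log10(lower), upper = log10(upper),
                              control = minpack.lm::nls.lm.control(maxiter = maxiter))
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  pv <- stats::setNames(10^best$par, names(init))
  fitted_params <- set_gene_params(template, g, pv)
  eps <- vapply(seq_len(dim(problem$monomers)[2]), function(w) {
    sim <- integrate_decoupled(problem, fitted_params, w)
    d <- problem$monomers[i, w, ][-1]
    mean((sim[-1] - d) / d)
  }, numeric(1))
  nom <- parameter_bounds()$nominal
  flags <- c(beta_sum_in_nominal = {
    s <- sum(pv[seq_len(na)]); s >= nom$beta_sum[1] && s <= nom$beta_sum[2] },
    km_in_nominal = all(pv[na + seq_len(na + nr)] >= nom$km[1] &
                        pv[na + seq_len(na + nr)] <= nom$km[2]),
    dc_in_nominal = pv[["dc"]] >= nom$dc[1] && pv[["dc"]] <= nom$dc[2])
  structure(list(gene = g, params_vector = pv, params = fitted_params,
                 objective = best$deviance, epsilon = eps,
                 in_nominal_range = flags, niter = best$niter,
                 converged = best$info %in% 1:4),
            class = "fit_result")
}

#' Fit all six decoupled equations
#'
#' Runs the six independent fits (order-independent by construction, since
#' no parameter appears in more than one equation) and reassembles a full
#' kinetic parameter set.
#'
#' @param totals Numeric array gene x whorl x day of measured totals (nM).
#' @param days Sampled days.
#' @param topology,schedule Model structure.
#' @param init Optional `floral_params` supplying initial values per gene
#'   (e.g. a perturbed reference set); default data-driven.
#' @param restarts,seed,maxiter Passed to [fit_equation()].
#' @return List with `params` (assembled `floral_params`), `fits` (per-gene
#'   `fit_result`), `objective` (summed), and the monomer data used.
#' @export
fit_all <- function(totals, days = 0:5, topology = default_topology(),
                    schedule = trigger_schedule(), init = NULL,
                    restarts = 2L, seed = 1L, maxiter = 60L) {
  mono <- monomer_data(totals, topology)
  fits <- list()
  assembled <- reference_params()
  for (g in FLORAL_GENES) {
    pb <- estimation_problem(g, mono, days, topology, schedule)
    init_g <- if (!is.null(init)) gene_free_params(init, g) else NULL
    fits[[g]] <- fit_equation(pb, init = init_g, restarts = restarts,
                              seed = seed + gene_index(g), maxiter = maxiter)
    assembled <- set_gene_params(assembled, g, fits[[g]]$params_vector)
  }
  list(params = assembled, fits = fits,
       objective = sum(vapply(fits, `[[`, numeric(1), "objective")),
       monomers = mono, free_parameter_count = sum(lengths(lapply(fits, `[[`, "params_vector"))))
}
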