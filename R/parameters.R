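#' Construct a kinetic parameter set
#'
#' Holds, per gene, the maximal transcription rates `beta` (nM/day, one per
#' activator slot), the half-maximal constants `km` (nM, activator slots
#' first then repressor slots), the decay rates `dc` (1/day), and the two
#' trigger magnitudes `p2` (AP3, nM/day) and `p4` (AG, nM/day).
#'
#' @param beta Named list, one numeric vector per gene.
#' @param km Named list, one numeric vector per gene.
#' @param dc Numeric vector of six decay rates, gene order.
#' @param p2,p4 Trigger production rates in nM/day.
#' @param topology Topology used to validate slot counts.
#' @return An object of class `floral_params`.
#' @export
floral_params <- function(beta, km, dc, p2, p4, topology = default_topology()) {
  for (g in FLORAL_GENES) {
    na <- length(topology$activators[[g]])
    nr <- length(topology$repressors[[g]])
    if (length(beta[[g]]) != na)
      stop("gene ", g, ": expected ", na, " beta value(s), got ", length(beta[[g]]))
    if (length(km[[g]]) != na + nr)
      stop("gene ", g, ": expected ", na + nr, " Km value(s), got ", length(km[[g]]))
  }
  stopifnot(length(dc) == 6)
  vals <- c(unlist(beta), unlist(km), dc, p2, p4)
  if (any(vals <= 0)) stop("all kinetic parameters must be strictly positive")
  structure(list(beta = beta[FLORAL_GENES], km = km[FLORAL_GENES],
                 dc = stats::setNames(as.numeric(dc), FLORAL_GENES),
                 p2 = p2, p4 = p4),
            class = "floral_params")
}

#' The packaged reference parameter set
#'
#' The identified kinetic parameters of the reduced model: 13 maximal rates,
#' 16 half-maximal constants, 6 decay rates and the two trigger magnitudes,
#' in days and nM. The per-gene value sets are fixed; their pairing with
#' activator slots (which beta/Km belongs to which dimer input) is the
#' package's reconstruction, chosen together with the affinity assignment so
#' that the reference model reproduces the published wild-type and mutant
#' phenotypes (methods vignette, "Slot pairing").
#'
#' Slot order per gene follows the activator lists of [default_topology()],
#' repressor slots last:
#' AP1: \[AP1 SEP\] then repressor \[AG AG\];
#' AP3/PI: \[AP1 SEP\], \[AG SEP\], \[AP3 PI\];
#' AG: \[AG SEP\], \[AG AG\], repressor \[AP1 AP1\];
#' SHP: \[AG SEP\], repressor \[AP3 PI\];
#' SEP: \[AG SEP\], \[AP1 SEP\], \[SEP SEP\].
#'
#' @return A `floral_params`.
#' @export
#' @examples
#' p <- reference_params()
#' sum(lengths(p$beta))  # 13 maximal transcription rates
reference_params <- function() {
  floral_params(
    beta = list(AP1 = 6.6e4,
                AP3 = c(1.2e2, 1.2e2, 3.3e4),
                PI  = c(38, 38, 1.5e3),
                AG  = c(1.5e4, 8.8e3),
                SHP = 4.1e2,
                SEP = c(2.3e3, 44, 6e3)),
    km   = list(AP1 = c(3.7e2, 10),
                AP3 = c(6.1e2, 1.1e2, 1.1e3),
                PI  = c(6.3e2, 3.1e2, 63),
                AG  = c(10, 1.1e3, 1e2),
                SHP = c(1e3, 10),
                SEP = c(5.7e2, 20, 47)),
    dc   = c(71, 3, 48, 500, 4, 16),
    p2   = 4.5e4,
    p4   = 3.4e3)
}

#' Trigger schedule
#'
#' The two timed, whorl-specific production inputs that stand in for the
#' non-MADS activators (LFY/UFO for AP3; WUS/LFY for AG). Both act as
#' constant rates during a one-day window and are the only whorl-dependent
#' terms of the model, so they alone differentiate the four whorl fates.
#'
#' @param t_on,t_off Half-open activity window \[t_on, t_off) in days.
#' @param p2_whorls Whorls receiving the AP3 trigger.
#' @param p4_whorls Whorls receiving the AG trigger.
#' @return An object of class `trigger_schedule`.
#' @export
trigger_schedule <- function(t_on = 1, t_off = 2,
                             p2_whorls = c(2L, 3L), p4_whorls = c(3L, 4L)) {
  if (!(t_on < t_off)) stop("t_on must be < t_off")
  if (!all(c(p2_whorls, p4_whorls) %in% 1:4)) stop("whorl ids must be in 1..4")
  structure(list(t_on = t_on, t_off = t_off,
                 p2_whorls = as.integer(p2_whorls),
                 p4_whorls = as.integer(p4_whorls)),
            class = "trigger_schedule")
}

#' Trigger input for one gene at one time in one whorl
#'
#' @param gene Gene name or index.
#' @param t Time in days.
#' @param whorl Whorl id 1..4 (1 = outermost).
#' @param schedule A [trigger_schedule()].
#' @param params A `floral_params`.
#' @return Production input in nM/day.
#' @export
#' @examples
#' trigger_input("AP3", 1.5, 3, trigger_schedule(), reference_params())  # 4.5e4
trigger_input <- function(gene, t, whorl, schedule = trigger_schedule(),
                          params = reference_params()) {
  i <- gene_index(gene)
  active <- t >= schedule$t_on & t < schedule$t_off
  if (i == 2L && whorl %in% schedule$p2_whorls) return(ifelse(active, params$p2, 0))
  if (i == 4L && whorl %in% schedule$p4_whorls) return(ifelse(active, params$p4, 0))
  0
}

#' Literature parameter bounds with unit conversion
#'
#' Literature ranges are quoted per minute; the model runs in days, so rate
#' bounds convert by a factor 1440. The nominal ranges exclude a few of the
#' reference values (notably the SHP maximal rate, a factor 3.5 below the
#' converted lower bound of the per-equation beta sum), so the fitting
#' bounds are deliberately wider; fits flag any value outside the nominal
#' range.
#'
#' @return List with `nominal` and `fit` ranges (each a list of length-2
#'   numeric vectors for beta, km, dc, trigger) and the conversion factor.
#' @export
parameter_bounds <- function() {
  list(minutes_per_day = 1440,
       nominal = list(beta_sum = c(1, 50) * 1440,   # nM/day, per-equation sum
                      km       = c(10, 1e3),         # nM
                      dc       = c(1e-3, 1e-1) * 1440),
       fit     = list(beta = c(1, 7.2e4),
                      km   = c(1, 1e4),
                      dc   = c(0.1, 1e3),
                      trigger = c(1, 1e6)))
}

#' Flatten a parameter set to the named free-parameter vector of one gene
#'
#' The decoupled estimation fits, per gene, exactly the parameters appearing
#' in that gene's equation: its betas, its Kms, its decay rate, and (for AP3
#' and AG) its trigger magnitude. No parameter appears in more than one
#' gene's equation, which is what makes the decoupling exact.
#'
#' @param params A `floral_params`.
#' @param gene Gene name or index.
#' @return Named numeric vector.
#' @export
gene_free_params <- function(params, gene) {
  i <- gene_index(gene)
  g <- FLORAL_GENES[i]
  v <- c(stats::setNames(params$beta[[g]], paste0("beta", seq_along(params$beta[[g]]))),
         stats::setNames(params$km[[g]],   paste0("km",   seq_along(params$km[[g]]))),
         dc = unname(params$dc[g]))
  if (i == 2L) v <- c(v, p = params$p2)
  if (i == 4L) v <- c(v, p = params$p4)
  v
}

# internal: write a per-gene free-parameter vector back into a params object
set_gene_params <- function(params, gene, v) {
  i <- gene_index(gene)
  g <- FLORAL_GENES[i]
  nb <- length(params$beta[[g]]); nk <- length(params$km[[g]])
  params$beta[[g]] <- unname(v[seq_len(nb)])
  params$km[[g]]   <- unname(v[nb + seq_len(nk)])
  params$dc[g]     <- unname(v[nb + nk + 1])
  if (i == 2L && length(v) > nb + nk + 1) params$p2 <- unname(v[nb + nk + 2])
  if (i == 4L && length(v) > nb + nk + 1) params$p4 <- unname(v[nb + nk + 2])
  params
}
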