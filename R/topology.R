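#' The six MADS-box organ-identity genes in canonical state order
#'
#' The ordering is load-bearing: decay rates, slot tables and all state
#' vectors follow it (x1 = AP1 ... x6 = SEP).
#' @export
FLORAL_GENES <- c("AP1", "AP3", "PI", "AG", "SHP", "SEP")

#' The seven dimer species of the reference network
#'
#' Names are "A:B" with the partners in [FLORAL_GENES] order.
#' @export
FLORAL_DIMERS <- c("AP1:SEP", "AG:AG", "AG:SEP", "AP3:PI",
                   "AP1:AP1", "SEP:SEP", "SHP:SEP")

#' Resolve a gene name or index to its state index
#'
#' @param gene A gene name (`"AP1"`, ..., `"SEP"`) or an integer 1..6.
#' @return Integer index into the canonical gene order.
#' @export
gene_index <- function(gene) {
  if (is.numeric(gene)) {
    idx <- as.integer(gene)
    if (any(idx < 1L | idx > 6L)) stop("gene index must be in 1..6")
    return(idx)
  }
  idx <- match(gene, FLORAL_GENES)
  if (anyNA(idx)) stop("unknown gene: ", paste(gene[is.na(idx)], collapse = ", "))
  idx
}

dimer_name <- function(i, j) {
  p <- sort(c(i, j))
  paste(FLORAL_GENES[p[1]], FLORAL_GENES[p[2]], sep = ":")
}

#' Construct a gene/dimer network topology
#'
#' A topology holds the six genes, the dimer species with their affinity
#' ratios gamma = Kon/Koff (nM^-1), and the activator/repressor wiring:
#' which dimers occupy activation and repression sites on each gene's
#' promoter. Transcription requires at least one occupied activation site
#' and all repression sites empty.
#'
#' @param dimers Data frame with columns `name`, `i`, `j` (partner state
#'   indices, `i <= j`) and `gamma` (nM^-1, positive).
#' @param activators,repressors Named lists (one entry per gene) of dimer
#'   names, in slot order.
#' @return An object of class `floral_topology`.
#' @export
floral_topology <- function(dimers, activators, repressors) {
  stopifnot(is.data.frame(dimers),
            all(c("name", "i", "j", "gamma") %in% names(dimers)))
  if (any(dimers$gamma <= 0)) stop("all gamma values must be positive")
  if (any(dimers$i > dimers$j)) stop("dimer partners must satisfy i <= j")
  for (g in FLORAL_GENES) {
    for (d in c(activators[[g]], repressors[[g]])) {
      if (!d %in% dimers$name) stop("regulating dimer not in dimer list: ", d)
    }
  }
  structure(list(genes = FLORAL_GENES,
                 dimers = dimers,
                 activators = activators[FLORAL_GENES],
                 repressors = repressors[FLORAL_GENES]),
            class = "floral_topology")
}

#' The reference network topology
#'
#' Wiring of the six-gene network: each gene's activating and repressing
#' dimers, and the affinity ratio gamma assigned to each of the seven dimer
#' species. The wiring is fixed by genetic evidence; the within-network
#' assignment of the relative affinity values \{1, 0.1, 0.1, 0.01, 0.01,
#' 5e-3, 5e-3\} nM^-1 to the seven dimers is a reconstruction chosen so that
#' the packaged kinetic parameters reproduce the wild-type whorl fates, the
#' five classical homeotic mutants and the dimer-removal phenotypes (see the
#' methods vignette). Pass `gamma` to override the assignment.
#'
#' @param gamma Optional named numeric vector (names in `FLORAL_DIMERS`)
#'   overriding the default affinity assignment.
#' @return A `floral_topology`.
#' @export
#' @examples
#' topo <- default_topology()
#' topo$activators$AP3   # the three activating dimers of AP3
default_topology <- function(gamma = NULL) {
  gdef <- c("AP1:SEP" = 1e-2, "AG:AG" = 1, "AG:SEP" = 5e-3, "AP3:PI" = 1e-2,
            "AP1:AP1" = 5e-3, "SEP:SEP" = 1e-1, "SHP:SEP" = 1e-1)
  if (!is.null(gamma)) {
    bad <- setdiff(names(gamma), names(gdef))
    if (length(bad)) stop("unknown dimer in gamma override: ", paste(bad, collapse = ", "))
    gdef[names(gamma)] <- gamma
  }
  dimers <- data.frame(
    name  = FLORAL_DIMERS,
    i     = c(1L, 4L, 4L, 2L, 1L, 6L, 5L),
    j     = c(6L, 4L, 6L, 3L, 1L, 6L, 6L),
    gamma = unname(gdef[FLORAL_DIMERS]),
    stringsAsFactors = FALSE)
  activators <- list(
    AP1 = "AP1:SEP",
    AP3 = c("AP1:SEP", "AG:SEP", "AP3:PI"),
    PI  = c("AP1:SEP", "AG:SEP", "AP3:PI"),
    AG  = c("AG:SEP", "AG:AG"),
    SHP = "AG:SEP",
    SEP = c("AG:SEP", "AP1:SEP", "SEP:SEP"))
  repressors <- list(
    AP1 = "AG:AG",
    AP3 = character(0),
    PI  = character(0),
    AG  = "AP1:AP1",
    SHP = "AP3:PI",
    SEP = character(0))
  floral_topology(dimers, activators, repressors)
}

#' Structural parameter and state census of a topology
#'
#' Counts the states and parameters of the coupled monomer+dimer model and of
#' the quasi-steady-state reduced model: one maximal rate beta per activator
#' slot, one half-maximal constant Km per activator and per repressor slot,
#' one decay rate per gene, two trigger magnitudes, and per dimer one
#' association and one dissociation rate (full model) collapsing to the fixed
#' affinity ratios gamma in the reduced model.
#'
#' @param topology A `floral_topology`.
#' @return Named list of integer counts.
#' @export
#' @examples
#' parameter_census(default_topology())
parameter_census <- function(topology) {
  n_act <- sum(lengths(topology$activators))
  n_rep <- sum(lengths(topology$repressors))
  n_dim <- nrow(topology$dimers)
  list(states_full      = 6L + n_dim,
       states_reduced   = 6L,
       n_beta           = n_act,
       n_km             = n_act + n_rep,
       n_decay          = 6L,
       n_trigger        = 2L,
       params_full      = n_act + (n_act + n_rep) + 6L + 2L + 2L * n_dim,
       params_reduced_free = n_act + (n_act + n_rep) + 6L + 2L)
}

# internal: fast numeric representation of a topology used by the solvers
topology_env <- function(topology) {
  d <- topology$dimers
  list(i1 = d$i, i2 = d$j, homo = d$i == d$j,
       gamma = d$gamma,
       aidx = lapply(topology$activators, function(a) match(a, d$name)),
       ridx = lapply(topology$repressors, function(r) match(r, d$name)),
       dnames = d$name)
}
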