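# Conversion of meristem-averaged expression intensities into whorl-resolved
# protein concentrations: uniform intensity-to-concentration scaling, the
# on/off expression pattern, whorl volumes, and the volume-weighted mass
# balance that fixes the per-gene scaling factor alpha.

#' The on/off expression pattern of the six genes across whorls and days
#'
#' Whorl-resolved qualitative expression from day 2 to day 5 of meristem
#' development ("day k" = end of day k): whorl 1 expresses AP1; whorl 2
#' AP1, AP3, PI; whorl 3 AP3, PI, AG; whorl 4 AG, joined by SHP from day 4.
#' SEP is on everywhere at all times. Before day 2 no organ primordia exist
#' and expression is spatially uniform, encoded as "on" in all whorls for
#' days 0 and 1.
#'
#' @return Object of class `expression_pattern`: logical array
#'   gene x whorl x day (days 0..5).
#' @export
expression_pattern <- function() {
  days <- 0:5
  arr <- array(FALSE, dim = c(6, 4, length(days)),
               dimnames = list(FLORAL_GENES, paste0("w", 1:4), paste0("d", days)))
  on_at <- function(gene, whorls, day) arr[gene, whorls, paste0("d", day)] <<- TRUE
  for (d in 2:5) {
    on_at("AP1", 1:2, d)
    on_at("AP3", 2:3, d)
    on_at("PI", 2:3, d)
    on_at("AG", 3:4, d)
    if (d >= 4) on_at("SHP", 4, d)
    on_at("SEP", 1:4, d)
  }
  arr[, , c("d0", "d1")] <- TRUE  # uniform pre-differentiation expression
  structure(arr, class = c("expression_pattern", "array"))
}

#' Expression fraction of a gene in a whorl on a day
#'
#' A gene scored "off" in a whorl carries 1% of the concentration of an
#' expressed gene, so the fraction is 1 when the pattern says on and 0.01
#' otherwise.
#'
#' @param gene Gene name or index.
#' @param whorl Whorl id 1..4.
#' @param day Integer day 0..5.
#' @param pattern An [expression_pattern()].
#' @return 1.0 or 0.01.
#' @export
#' @examples
#' expression_fraction("SHP", 4, 4)  # 1: SHP has switched on in the carpels
#' expression_fraction("AP1", 3, 3)  # 0.01: no A function in the stamens
expression_fraction <- function(gene, whorl, day, pattern = expression_pattern()) {
  i <- gene_index(gene)
  if (!whorl %in% 1:4) stop("whorl must be in 1..4")
  if (!day %in% 0:5) stop("day must be in 0..5")
  if (pattern[i, whorl, paste0("d", day)]) 1.0 else 0.01
}

#' Whorl geometry
#'
#' Volumes of the four whorl primordia at the end of day 2 (sepals, petals,
#' stamens, carpels), treated as constant from day 2 to 5 since shapes and
#' relative sizes change little over that window.
#'
#' @param volumes Numeric 4-vector of volumes in um^3.
#' @return Object of class `whorl_geometry`.
#' @export
whorl_geometry <- function(volumes = c(1.1e4, 2.7e4, 2.9e4, 1.1e4)) {
  if (length(volumes) != 4 || any(volumes <= 0)) stop("need 4 positive volumes")
  structure(list(volumes = stats::setNames(volumes, paste0("w", 1:4))),
            class = "whorl_geometry")
}

#' Scale raw intensities to protein concentrations
#'
#' A single multiplicative factor maps summarized mRNA intensities to
#' protein concentrations such that the grand mean over all genes and days
#' equals `target_mean` (1000 nM, the typical transcription-factor
#' concentration scale). Linearity of intensity in concentration is assumed
#' throughout.
#'
#' @param raw Numeric matrix gene x day of positive intensities
#'   (rownames = genes, columns = days 0..5).
#' @param target_mean Target grand mean in nM.
#' @return Matrix of the same shape in nM, with the factor as attribute
#'   `"scale_factor"`.
#' @export
scale_intensities <- function(raw, target_mean = 1e3) {
  raw <- as.matrix(raw)
  if (any(raw <= 0)) stop("intensities must be strictly positive")
  f <- target_mean / mean(raw)
  structure(raw * f, scale_factor = f)
}

#' Whorl-resolved concentrations from meristem averages
#'
#' For each gene and day the meristem average is split over whorls according
#' to the on/off pattern: concentrations are e * alpha with e the expression
#' fraction (1 or 0.01) and alpha the per-gene, per-day scaling factor
#' alpha = average * sum(V) / sum(e * V), so that the volume-weighted mean
#' over whorls reproduces the measured average exactly.
#'
#' @param series Numeric matrix gene x day (nM), e.g. from
#'   [scale_intensities()]; columns are days 0..5.
#' @param pattern An [expression_pattern()].
#' @param geometry A [whorl_geometry()].
#' @return Object of class `transform_record`: list with `concentrations`
#'   (gene x whorl x day array, nM), `alpha` (gene x day matrix), plus the
#'   pattern and geometry used.
#' @export
#' @examples
#' series <- matrix(1e3, 6, 6, dimnames = list(FLORAL_GENES, paste0("d", 0:5)))
#' rec <- whorl_concentrations(series)
#' rec$concentrations["AP1", , "d3"]  # on in whorls 1-2, 1% elsewhere
whorl_concentrations <- function(series, pattern = expression_pattern(),
                                 geometry = whorl_geometry()) {
  series <- as.matrix(series)
  if (nrow(series) != 6) stop("series must have one row per gene")
  days <- 0:5
  if (ncol(series) != length(days)) stop("series must cover days 0..5")
  V <- geometry$volumes
  conc <- array(NA_real_, dim = c(6, 4, length(days)),
                dimnames = list(FLORAL_GENES, paste0("w", 1:4), paste0("d", days)))
  alpha <- matrix(NA_real_, 6, length(days),
                  dimnames = list(FLORAL_GENES, paste0("d", days)))
  for (i in 1:6) for (d in seq_along(days)) {
    e <- vapply(1:4, function(w) expression_fraction(i, w, days[d], pattern), numeric(1))
    a <- series[i, d] * sum(V) / sum(e * V)
    alpha[i, d] <- a
    conc[i, , d] <- e * a
  }
  structure(list(concentrations = conc, alpha = alpha,
                 pattern = pattern, geometry = geometry),
            class = "transform_record")
}

#' Volume-weighted meristem average of a whorl-resolved grid
#'
#' The forward map that [whorl_concentrations()] inverts: the mass balance
#' average_i(day) = sum_w V_w c_i^w(day) / sum_w V_w.
#'
#' @param grid Numeric array gene x whorl x day (nM).
#' @param geometry A [whorl_geometry()].
#' @return Matrix gene x day of averages (nM).
#' @export
meristem_average <- function(grid, geometry = whorl_geometry()) {
  V <- geometry$volumes
  out <- apply(grid, c(1, 3), function(cw) sum(cw * V) / sum(V))
  out
}
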