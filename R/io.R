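# Tidy CSV readers/writers shared by all stages. The trajectory dialect has
# columns (whorl, gene, time_days, concentration_nM, species) with species
# one of "monomer", "total", or "dimer:<pair>".

#' Write a flower trajectory to tidy CSV
#'
#' @param flower A `flower_trajectory` (list of four `whorl_trajectory`).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(flower, path) {
  rows <- list()
  for (w in seq_along(flower)) {
    tr <- flower[[w]]
    for (g in FLORAL_GENES) {
      rows[[length(rows) + 1]] <- data.frame(
        whorl = tr$whorl, gene = g, time_days = tr$times,
        concentration_nM = tr$monomers[, g], species = "monomer",
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        whorl = tr$whorl, gene = g, time_days = tr$times,
        concentration_nM = tr$totals[, g], species = "total",
        stringsAsFactors = FALSE)
    }
    for (d in colnames(tr$dimers)) {
      g1 <- strsplit(d, ":", fixed = TRUE)[[1]][1]
      rows[[length(rows) + 1]] <- data.frame(
        whorl = tr$whorl, gene = g1, time_days = tr$times,
        concentration_nM = tr$dimers[, d], species = paste0("dimer:", d),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$concentration_nM <- signif(out$concentration_nM, 12)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tidy trajectory CSV
#'
#' Validates the dialect: known header, known gene names, non-negative
#' concentrations. Errors name the offending row.
#'
#' @param path Input file path.
#' @return Data frame with the trajectory in tidy form.
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty trajectory file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("whorl", "gene", "time_days", "concentration_nM", "species")
  if (!identical(sort(names(df)), sort(need)))
    stop("malformed header: expected columns ", paste(need, collapse = ", "))
  if (nrow(df) == 0) stop("empty trajectory file: ", path)
  bad <- which(!df$gene %in% FLORAL_GENES)
  if (length(bad))   # +1: report file line numbers, counting the header
    stop("unknown gene '", df$gene[bad[1]], "' at row ", bad[1] + 1L)
  neg <- which(df$concentration_nM < 0)
  if (length(neg))
    stop("negative concentration at row ", neg[1] + 1L)
  if (!all(df$whorl %in% 1:4)) stop("whorl ids must be in 1..4")
  df
}

#' Write a synthetic data set to plain-text files
#'
#' Truth grid, noisy grid and averaged series as CSV plus the generating
#' configuration as JSON (seed, sigma, sampling days, affinity assignment),
#' so any output is reproducible from its manifest.
#'
#' @param dataset Result of [synthetic_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid_df <- function(grid) {
    dn <- dimnames(grid)
    expand <- expand.grid(gene = dn[[1]], whorl = 1:4,
                          day = as.numeric(sub("^d", "", dn[[3]])),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    expand$concentration_nM <- as.vector(grid)
    expand
  }
  utils::write.csv(grid_df(dataset$truth), file.path(dir, "truth_grid.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(grid_df(dataset$noisy), file.path(dir, "noisy_grid.csv"),
                   row.names = FALSE, quote = FALSE)
  avg <- as.data.frame(dataset$averages)
  avg <- cbind(gene = rownames(dataset$averages), avg)
  utils::write.csv(avg, file.path(dir, "meristem_averages.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg <- dataset$config
  manifest <- list(seed = cfg$seed, sigma = cfg$sigma,
                   sampling_days = cfg$sampling_days, on_level = cfg$on_level,
                   gamma = stats::setNames(cfg$topology$dimers$gamma,
                                           cfg$topology$dimers$name),
                   volumes = dataset$geometry$volumes)
  writeLines(manifest_json(manifest), file.path(dir, "manifest.json"))
  invisible(dir)
}

# minimal JSON writer for flat manifests (numbers, numeric vectors, strings)
manifest_json <- function(x) {
  enc <- function(v) {
    if (is.character(v)) paste0("\"", v, "\"")
    else format(v, digits = 15, scientific = TRUE, trim = TRUE)
  }
  items <- vapply(names(x), function(nm) {
    v <- x[[nm]]
    if (length(v) == 1 && is.null(names(v)))
      paste0("\"", nm, "\": ", enc(v))
    else if (!is.null(names(v)))
      paste0("\"", nm, "\": {",
             paste0("\"", names(v), "\": ", enc(unname(v)), collapse = ", "), "}")
    else
      paste0("\"", nm, "\": [", paste0(enc(v), collapse = ", "), "]")
  }, character(1))
  paste0("{\n  ", paste(items, collapse = ",\n  "), "\n}")
}
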