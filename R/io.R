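# Result serialisation: tidy long-format TSV tables plus JSON run manifests
# sufficient to re-run a job exactly.

#' Export a trajectory as tidy TSV
#'
#' Long format (time_ms, species, value_nM), interoperable with any
#' plotting stack.
#'
#' @param trajectory a \code{trajectory_result}.
#' @param path output file.
#' @param species optional subset of species to export.
#' @export
write_trajectory_tsv <- function(trajectory, path, species = NULL) {
  conc <- trajectory$concentrations
  if (!is.null(species)) conc <- conc[, species, drop = FALSE]
  long <- data.frame(
    time_ms = rep(trajectory$times, times = ncol(conc)),
    species = rep(colnames(conc), each = nrow(conc)),
    value_nM = as.vector(conc))
  utils::write.table(long, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to repeat a run: package version, network
#' fingerprint, solver settings, seed and free-form configuration.
#'
#' @param path output JSON file.
#' @param network the network used.
#' @param config solver configuration.
#' @param seed RNG seed (or NULL for deterministic runs).
#' @param extra named list of additional fields.
#' @export
write_run_manifest <- function(path, network, config = solver_config(),
                               seed = NULL, extra = list()) {
  man <- c(list(
    package = "spinedyn",
    version = as.character(utils::packageVersion("spinedyn")),
    network_fingerprint = network_fingerprint(network),
    n_species = nrow(network$species),
    n_reactions = nrow(network$reactions),
    volume_um3 = network$volume,
    solver = unclass(config),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
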