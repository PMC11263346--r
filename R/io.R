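#' Save a network to a JSON checkpoint
#'
#' Serializes every weight matrix and bias (17 significant digits, enough for
#' an exact double round trip) together with the architecture metadata.
#'
#' @param net An `ff_net` or `gru_net`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "ff_net") || inherits(net, "gru_net"))
  obj <- lapply(net, function(v) {
    if (is.matrix(v)) list(kind = "matrix", dim = dim(v), data = as.numeric(v))
    else if (is.numeric(v)) list(kind = "numeric", data = as.numeric(v))
    else list(kind = "scalar", data = v)
  })
  jsonlite::write_json(list(class = class(net), fields = obj), path,
                       auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a network from a JSON checkpoint
#'
#' @param path File written by [write_network()].
#' @return The reconstructed network; round-trips exactly.
#' @export
read_network <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  fields <- lapply(raw$fields, function(f) {
    switch(f$kind,
           matrix = matrix(as.numeric(f$data), f$dim[1], f$dim[2]),
           numeric = as.numeric(f$data),
           f$data)
  })
  for (nm in c("input_dim", "context_dim", "hidden_dim", "output_dim"))
    if (!is.null(fields[[nm]])) fields[[nm]] <- as.integer(fields[[nm]])
  structure(fields, class = raw$class)
}

#' Read an experiment configuration file
#'
#' Configurations are flat YAML (or JSON) mappings; keys mirror the arguments
#' of [default_config()] and include `alpha`, `stickiness`, `temperature`,
#' `context_dim`, and `seed`.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A named list merged over the simulation's defaults.
#' @export
read_experiment_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg$simulation))
    stop("config must contain a `simulation` field (1, 2, or 3)")
  utils::modifyList(default_config(cfg$simulation), cfg)
}

#' Write an experiment configuration file
#'
#' @param config Named list as returned by [default_config()].
#' @param path Output `.yaml` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_experiment_config <- function(config, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(config, path)
  invisible(path)
}
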