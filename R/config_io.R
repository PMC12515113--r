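#' Read pipeline / network / training configuration from YAML
#'
#' The YAML file may contain any of the top-level blocks `net`, `train`,
#' `augment`, `pipeline`; each block's fields are passed to the matching
#' constructor ([net_config()], [train_config()], [augment_config()],
#' [pipeline_config()]), so unknown fields are rejected and defaults fill the
#' rest.
#'
#' @param path YAML file path.
#' @return named list of the config objects present in the file.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(y$net)) out$net <- do.call(net_config, y$net)
  if (!is.null(y$train)) out$train <- do.call(train_config, y$train)
  if (!is.null(y$augment)) out$augment <- do.call(augment_config, y$augment)
  if (!is.null(y$pipeline)) out$pipeline <- do.call(pipeline_config, y$pipeline)
  out
}
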