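#' Load run parameters from a YAML configuration file
#'
#' The file may contain `scoring:`, `qualification:` and `scheduler:`
#' sections whose fields mirror [scoring_params()], [qual_params()] and
#' [scheduler_config()], plus top-level `min_mem_length` and `k`.  Missing
#' fields keep their defaults.
#'
#' @param path YAML file.
#' @return List with `scoring`, `qp`, `config`, `min_mem_length`, `k`.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  scoring <- do.call(scoring_params, as.list(y$scoring))
  qp <- do.call(qual_params, as.list(y$qualification))
  config <- do.call(scheduler_config, as.list(y$scheduler))
  list(scoring = scoring, qp = qp, config = config,
       min_mem_length = if (is.null(y$min_mem_length)) 19L
                        else as.integer(y$min_mem_length),
       k = if (is.null(y$k)) 13L else as.integer(y$k))
}
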