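#' @include AllClasses.R
NULL

#' Load the toolbox configuration
#'
#' Reads the package's default YAML configuration (enzyme geometries, the
#' fusion-site / overhang table, braid overhangs, scaffold/tRNA/promoter
#' sequences and policies) and, when `path` is given, merges the user file
#' over the defaults (recursively, so single keys can be overridden).
#'
#' @param path optional path to a user YAML configuration.
#' @return a nested list; see the packaged `gb_config.yaml` for the schema.
#' @examples
#' cfg <- gbConfig()
#' names(cfg)
#' @export
gbConfig <- function(path = NULL) {
  default <- system.file("extdata", "gb_config.yaml", package = "gbcrispr")
  cfg <- yaml::read_yaml(default)
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

## fusion span (left, right) for a run of syntax codes
.fusionSpan <- function(codes, cfg) {
  syn <- cfg$syntax
  missing <- setdiff(codes, names(syn))
  if (length(missing))
    .gbValidationError(paste0("unknown syntax code(s): ",
                              paste(missing, collapse = ", ")))
  c(syn[[codes[1L]]]$left, syn[[codes[length(codes)]]]$right)
}

#' The fusion-site (overhang) table
#'
#' @param cfg a configuration from [gbConfig()].
#' @return data.frame with columns `code`, `left`, `right`.
#' @export
overhangTable <- function(cfg = gbConfig()) {
  codes <- names(cfg$syntax)
  data.frame(code = codes,
             left = vapply(cfg$syntax, function(x) x$left, character(1L)),
             right = vapply(cfg$syntax, function(x) x$right, character(1L)),
             row.names = NULL, stringsAsFactors = FALSE)
}
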