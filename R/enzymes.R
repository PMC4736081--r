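#' @include AllClasses.R config.R
NULL

#' Enzymes defined in a configuration
#'
#' @param cfg a configuration from [gbConfig()].
#' @return named list of [EnzymeSpec-class] objects.
#' @examples
#' names(defaultEnzymes())
#' @export
defaultEnzymes <- function(cfg = gbConfig()) {
  out <- lapply(cfg$enzymes, function(e)
    gbEnzyme(e$name, e$recognition, e$spacer_len, e$overhang_len))
  names(out) <- vapply(out, function(e) e@name, character(1L))
  out
}

#' Look up a configured enzyme by name
#'
#' @param name enzyme name (e.g. `"BsaI"`).
#' @param cfg a configuration from [gbConfig()].
#' @return an [EnzymeSpec-class].
#' @export
enzymeByName <- function(name, cfg = gbConfig()) {
  enz <- defaultEnzymes(cfg)
  if (!name %in% names(enz))
    .gbValidationError(paste0("unknown enzyme: ", name))
  enz[[name]]
}

.resolveEnzyme <- function(enzyme, cfg = gbConfig()) {
  if (is(enzyme, "EnzymeSpec")) return(enzyme)
  enzymeByName(as.character(enzyme), cfg)
}
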