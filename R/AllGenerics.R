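#' @include AllClasses.R
NULL

#' Digest a molecule with a restriction enzyme
#'
#' @param x a [DNAMolecule-class].
#' @param enzyme an [EnzymeSpec-class].
#' @param ... further arguments for methods.
#' @return list of [Fragment-class] objects; see [digest,DNAMolecule,EnzymeSpec-method].
#' @export
setGeneric("digest", function(x, enzyme, ...) standardGeneric("digest"))

#' Predict restriction digest band sizes
#'
#' @param x a [DNAMolecule-class] (or object with a hosted molecule).
#' @param enzyme an [EnzymeSpec-class] or the name of a configured enzyme.
#' @param ... further arguments for methods.
#' @return a [DigestPattern-class].
#' @export
setGeneric("predictBands", function(x, enzyme, ...)
  standardGeneric("predictBands"))
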