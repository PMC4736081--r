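#' @include crispr.R
NULL

#' @describeIn predictBands band sizes for a molecule and enzyme. A circular
#'   molecule with k sites yields k bands, a linear one k + 1; band lengths
#'   always sum to the molecule length when cut. A circular molecule with no
#'   site is reported uncut. Named standard enzymes (SpeI, BamHI, EcoRI,
#'   HindIII, ...) resolve via the configured panel, which models within-site
#'   cutters through the negative-spacer geometry extension.
#' @param cfg configuration used to resolve a named enzyme.
#' @export
setMethod("predictBands", signature("DNAMolecule", "ANY"),
          function(x, enzyme, cfg = gbConfig(), ...) {
  enzyme <- .resolveEnzyme(enzyme, cfg)
  cuts <- .cutWindows(x, enzyme)
  L <- nchar(x@seq)
  if (!nrow(cuts)) {
    if (x@topology == "circular")
      return(new("DigestPattern", enzymeName = enzyme@name,
                 bands = integer(0L), uncut = TRUE, moleculeId = x@id,
                 moleculeLength = L))
    return(new("DigestPattern", enzymeName = enzyme@name, bands = L,
               uncut = FALSE, moleculeId = x@id, moleculeLength = L))
  }
  tt <- sort(cuts$cut_top)
  b <- if (x@topology == "circular") {
    if (length(tt) == 1L) L else diff(c(tt, tt[1L] + L))
  } else {
    diff(c(0L, tt, L))
  }
  b <- as.integer(b[b > 0L])
  new("DigestPattern", enzymeName = enzyme@name,
      bands = sort(b, decreasing = TRUE), uncut = FALSE, moleculeId = x@id,
      moleculeLength = L)
})

#' @describeIn predictBands bands of the plasmid hosting a GB part
#' @export
setMethod("predictBands", signature("GBPart", "ANY"),
          function(x, enzyme, cfg = gbConfig(), ...)
            predictBands(x@molecule, enzyme, cfg = cfg))

#' Select a diagnostic restriction assay for mutation re-detection
#'
#' Implements the PCR/RE site-loss assay design: among the panel, pick the
#' enzymes whose only site in the amplicon overlaps the Cas9 cut (recognition
#' span strictly containing the cut position), so that indels at the cut make
#' the amplicon resistant to digestion. Reports the expected wild-type bands
#' and the mutant signature (a single full-length resistant band).
#'
#' @param target a [TargetSpec-class].
#' @param amplicon a linear [DNAMolecule-class] containing the protospacer
#'   exactly once (on either strand).
#' @param panel list of [EnzymeSpec-class] or configured enzyme names.
#' @param cfg configuration.
#' @return list with `enzyme` (chosen name or NA), `wildtype_bands`,
#'   `mutant_bands` (integer vectors), and `excluded` (data.frame with
#'   `enzyme`, `reason`). When no enzyme qualifies, `enzyme` is NA and an
#'   advisory message of class `gb_no_assay` is emitted.
#' @export
designRedetectionAssay <- function(target, amplicon, panel,
                                   cfg = gbConfig()) {
  stopifnot(is(target, "TargetSpec"), is(amplicon, "DNAMolecule"))
  S <- amplicon@seq
  proto <- target@protospacer
  fwd <- .matchStarts(S, proto)
  rev <- .matchStarts(S, revcomp(proto))
  if (length(fwd) + length(rev) != 1L)
    .gbValidationError("amplicon must contain the protospacer exactly once")
  cutPos <- if (length(fwd)) fwd[1L] + target@cutOffset
            else rev[1L] + (20L - target@cutOffset)

  panel <- lapply(panel, .resolveEnzyme, cfg = cfg)
  chosen <- NULL
  excluded <- list()
  for (e in panel) {
    sp <- .recognitionSpans(S, e)
    nsite <- if (is.null(sp)) 0L else nrow(unique(sp))
    if (nsite == 0L) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        enzyme = e@name, reason = "no site in amplicon")
    } else if (nsite > 1L) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        enzyme = e@name, reason = "more than one site in amplicon")
    } else if (!(sp[1L, "start"] < cutPos && cutPos < sp[1L, "end"])) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        enzyme = e@name, reason = "site does not overlap the cut")
    } else if (is.null(chosen)) {
      chosen <- e
    }
  }
  excluded <- if (length(excluded)) do.call(rbind, excluded)
              else data.frame(enzyme = character(0L), reason = character(0L))
  if (is.null(chosen)) {
    message(structure(class = c("gb_no_assay", "message", "condition"),
                      list(message = "no diagnostic assay: no panel enzyme has a unique site overlapping the cut\n",
                           call = NULL)))
    return(list(enzyme = NA_character_, wildtype_bands = integer(0L),
                mutant_bands = nchar(S), excluded = excluded))
  }
  wt <- predictBands(amplicon, chosen, cfg = cfg)
  list(enzyme = chosen@name, wildtype_bands = wt@bands,
       mutant_bands = nchar(S), excluded = excluded)
}

## round half up to one decimal (protects against binary representation of
## values like 12.07 sitting infinitesimally below the .5 boundary)
.roundHalfUp1 <- function(x) floor(x * 10 + 0.5 + 1e-9) / 10

#' Corrected mutation rate from a PCR/RE site-loss assay
#'
#' The raw restriction-resistant amplicon fraction overestimates the editing
#' rate because some resistant clones turn out wild type on sequencing; the
#' corrected rate scales the raw percentage by the non-wild-type fraction:
#' `raw_pct * (1 - wt_clone_frac)`, reported to one decimal (half up).
#'
#' @param rawPct raw resistant-fraction estimate, percent (0--100).
#' @param wtCloneFrac fraction of sequenced resistant clones with wild-type
#'   sequence (0--1).
#' @return corrected mutation rate in percent, one decimal.
#' @examples
#' correctedMutationRate(17, 0.29)    # 12.1
#' correctedMutationRate(14.5, 0.32)  # 9.9
#' @export
correctedMutationRate <- function(rawPct, wtCloneFrac) {
  if (any(rawPct < 0 | rawPct > 100, na.rm = TRUE))
    .gbValidationError("rawPct must lie in [0, 100]")
  if (any(wtCloneFrac < 0 | wtCloneFrac > 1, na.rm = TRUE))
    .gbValidationError("wtCloneFrac must lie in [0, 1]")
  .roundHalfUp1(rawPct * (1 - wtCloneFrac))
}

#' Normalize dual-luciferase reporter ratios
#'
#' Per-sample Fluc/Rluc ratios are averaged per condition and all values are
#' normalized to the reference condition's mean, which is therefore exactly
#' 1. The induction range is the max/min ratio of normalized means over the
#' non-reference conditions. Normalization is scale-invariant in Fluc.
#'
#' @param samples data.frame with columns `condition`, `fluc`, `rluc`
#'   (optionally `replicate`).
#' @param reference name of the reference condition.
#' @return list with `summary` (data.frame: `condition`, `n`,
#'   `mean_normalized`, `sd_normalized`) and `induction_range`.
#' @export
normalizeReporter <- function(samples, reference) {
  stopifnot(is.data.frame(samples),
            all(c("condition", "fluc", "rluc") %in% names(samples)))
  if (any(samples$rluc <= 0))
    .gbValidationError("all Rluc readings must be positive")
  if (!reference %in% samples$condition)
    .gbValidationError(sprintf("reference condition '%s' missing", reference))
  ratio <- samples$fluc / samples$rluc
  refMean <- mean(ratio[samples$condition == reference])
  norm <- ratio / refMean
  conds <- unique(samples$condition)
  summary <- do.call(rbind, lapply(conds, function(cond) {
    v <- norm[samples$condition == cond]
    data.frame(condition = cond, n = length(v), mean_normalized = mean(v),
               sd_normalized = if (length(v) > 1L) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  nonref <- summary$mean_normalized[summary$condition != reference]
  induction <- if (length(nonref)) max(nonref) / min(nonref) else NA_real_
  list(summary = summary, induction_range = induction)
}
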