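#' @include core-ligate.R
NULL

#' Check a sequence for internal BsaI/BsmBI sites (domestication)
#'
#' A sequence is "domesticated" when it carries no internal recognition site
#' of either assembly enzyme on either strand, so it can travel through the
#' whole cloning hierarchy uncut.
#'
#' @param seq nucleotide string.
#' @param enzymes list of [EnzymeSpec-class] to screen (default BsaI + BsmBI).
#' @param cfg configuration.
#' @return data.frame of violations (`enzyme`, `strand`, `offset`; 0-based
#'   plus-strand offset of the recognition occurrence); zero rows means
#'   domesticated.
#' @examples
#' nrow(checkDomestication("ATGCATGC"))           # 0
#' nrow(checkDomestication("AAGGTCTCAA"))         # 1 (BsaI, +)
#' @export
checkDomestication <- function(seq, enzymes = NULL, cfg = gbConfig()) {
  if (is.null(enzymes))
    enzymes <- defaultEnzymes(cfg)[c("BsaI", "BsmBI")]
  seq <- toupper(seq)
  out <- list()
  for (e in enzymes) {
    p <- .matchStarts(seq, e@recognition)
    m <- .matchStarts(seq, revcomp(e@recognition))
    if (length(p))
      out[[length(out) + 1L]] <- data.frame(enzyme = e@name, strand = "+",
                                            offset = p)
    if (length(m))
      out[[length(out) + 1L]] <- data.frame(enzyme = e@name, strand = "-",
                                            offset = m)
  }
  if (!length(out))
    return(data.frame(enzyme = character(0L), strand = character(0L),
                      offset = integer(0L)))
  df <- do.call(rbind, out)
  df[order(df$offset, df$enzyme), , drop = FALSE]
}

## arm an insert for entry cloning: BsmBI-ready fragment whose BsaI release
## regenerates fusionL + insert (+ fusionR socket)
.armLevel0Insert <- function(insert, fusionL, fusionR, cfg) {
  sockets <- cfg$entry_sockets
  armed <- paste0("GGTCTC", "A", fusionL, insert, fusionR, "A", "GAGACC")
  gbFragment(seq = paste0(sockets$left, armed), leftOv = sockets$left,
             rightOv = sockets$right, source = "level0_insert")
}

#' Create a level 0 part in an entry vector
#'
#' Simulates the BsmBI restriction--ligation of a domesticated insert
#' (pre-flanked with its fusion sites and BsaI release arms) into a
#' pUPD-like entry vector. The stored plasmid round-trips: a BsaI digest
#' releases exactly the insert flanked by the left fusion site of the first
#' syntax code and the right fusion site of the last.
#'
#' @param insert nucleotide string (no internal BsaI/BsmBI sites).
#' @param syntaxCodes character vector of syntax position codes spanned
#'   (e.g. `c("B3","B4","B5")`); determines the fusion sites unless
#'   `fusions` is given.
#' @param entryVector a [GBVector-class] of class `entry` (see
#'   [makeVector()]).
#' @param fusions optional explicit `c(left, right)` 4-nt fusion sites,
#'   overriding the syntax lookup.
#' @param partId,name identifier and name for the new part.
#' @param cfg configuration.
#' @return a [GBPart-class] of level `level0`.
#' @export
makeLevel0 <- function(insert, syntaxCodes = NULL, entryVector,
                       fusions = NULL, partId = "GB0000",
                       name = partId, cfg = gbConfig()) {
  insert <- toupper(insert)
  if (!nchar(insert))
    .gbValidationError("empty insert")
  if (!grepl("^[ACGTN]+$", insert))
    .gbValidationError("insert may contain only A, C, G, T, N")
  viol <- checkDomestication(insert, cfg = cfg)
  if (nrow(viol))
    .gbValidationError(paste0(
      "insert is not domesticated; internal site(s): ",
      paste(sprintf("%s(%s)@%d", viol$enzyme, viol$strand, viol$offset),
            collapse = ", ")))
  if (is.null(fusions)) {
    if (is.null(syntaxCodes))
      .gbValidationError("either syntaxCodes or fusions must be given")
    fusions <- .fusionSpan(syntaxCodes, cfg)
  }
  if (is.null(syntaxCodes)) syntaxCodes <- NA_character_
  stopifnot(is(entryVector, "GBVector"), entryVector@klass == "entry")

  frag <- .armLevel0Insert(insert, fusions[1L], fusions[2L], cfg)
  res <- goldenGate(parts = list(), destination = entryVector,
                    enzyme = entryVector@assemblyEnzyme,
                    extraFragments = list(frag), cfg = cfg,
                    idPrefix = partId)
  prod <- backboneProduct(res)
  if (is.null(prod))
    .gbAssemblyError("entry cloning produced no vector-backbone product")
  ## canonicalization may have flipped the circle; store insert-forward
  if (!grepl(paste0(fusions[1L], insert),
             paste0(prod@seq, prod@seq), fixed = TRUE))
    prod@seq <- revcomp(prod@seq)
  prod@id <- partId
  new("GBPart", partId = partId, name = name, level = "level0",
      syntax = syntaxCodes, fusions = fusions, insert = insert,
      molecule = prod, vectorClass = "entry", position = NA_integer_)
}

#' Binary (braid) assembly of two hosted transcriptional units
#'
#' The GoldenBraid loop: two level >= 1 parts hosted in same-class vectors
#' (both alpha or both omega) at complementary braid positions are released
#' with the class's release enzyme (BsmBI for alpha, BsaI for omega) and
#' assembled in tandem into a destination vector of the opposite class. The
#' output class therefore alternates, and any product is itself a valid
#' binary input.
#'
#' @param tuA,tuB [GBPart-class] objects of level `level1plus`, hosted in
#'   same-class vectors at positions 1 and 2 (either argument order).
#' @param destination a [GBVector-class] of the opposite class.
#' @param partId,name identifier and name for the product part.
#' @param cfg configuration.
#' @return a [GBPart-class] of level `level1plus` hosted in the destination
#'   class.
#' @export
binaryAssemble <- function(tuA, tuB, destination, partId = "GB0000",
                           name = partId, cfg = gbConfig()) {
  stopifnot(is(tuA, "GBPart"), is(tuB, "GBPart"),
            is(destination, "GBVector"))
  if (tuA@level != "level1plus" || tuB@level != "level1plus")
    .gbValidationError("binary assembly needs two level >= 1 parts")
  if (tuA@vectorClass != tuB@vectorClass ||
      !tuA@vectorClass %in% c("alpha", "omega"))
    .gbValidationError("both inputs must be hosted in the same destination class (alpha or alpha, omega or omega)")
  if (destination@klass == tuA@vectorClass)
    .gbValidationError(sprintf(
      "braid violation: %s-hosted inputs must enter a %s destination",
      tuA@vectorClass, setdiff(c("alpha", "omega"), tuA@vectorClass)))
  if (!destination@klass %in% c("alpha", "omega"))
    .gbValidationError("destination must be an alpha or omega vector")
  pos <- c(tuA@position, tuB@position)
  if (any(is.na(pos)) || !setequal(pos, c(1L, 2L)))
    .gbValidationError("inputs must occupy complementary braid positions 1 and 2")
  if (tuA@position == 2L) { tmp <- tuA; tuA <- tuB; tuB <- tmp }

  relEnz <- if (tuA@vectorClass == "alpha") enzymeByName("BsmBI", cfg)
            else enzymeByName("BsaI", cfg)
  res <- goldenGate(parts = list(tuA@molecule, tuB@molecule),
                    destination = destination, enzyme = relEnz, cfg = cfg,
                    idPrefix = partId)
  prod <- backboneProduct(res)
  if (is.null(prod))
    .gbAssemblyError("binary assembly produced no destination-backbone product")
  prod@id <- partId
  new("GBPart", partId = partId, name = name, level = "level1plus",
      syntax = c(tuA@syntax, tuB@syntax),
      fusions = destination@sockets,
      insert = NA_character_, molecule = prod,
      vectorClass = destination@klass, position = destination@position)
}
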