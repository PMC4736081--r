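#' @import methods
NULL

## ---------------------------------------------------------------------------
## DNAMolecule
## ---------------------------------------------------------------------------

#' DNAMolecule: a double-stranded DNA sequence with topology
#'
#' Central sequence container of the package. The sequence is the plus strand
#' stored upper-case (alphabet `A C G T N`); `topology` is `"linear"` or
#' `"circular"`. Annotations are a data frame with columns `label`, `start`,
#' `end`, `strand` in 0-based half-open plus-strand coordinates (an annotation
#' may wrap the origin only on circular molecules, expressed as `end > length`).
#'
#' Two circular molecules are considered the same molecule when one sequence
#' is a rotation of the other or of its reverse complement; use
#' [sameMolecule()] for this rotation-invariant comparison.
#'
#' @slot id character molecule identifier.
#' @slot seq character plus-strand sequence.
#' @slot topology `"linear"` or `"circular"`.
#' @slot annotations data.frame of feature annotations.
#' @export
setClass("DNAMolecule",
         representation(id = "character", seq = "character",
                        topology = "character", annotations = "data.frame"))

setValidity("DNAMolecule", function(object) {
  msg <- character(0L)
  if (length(object@seq) != 1L || is.na(object@seq) || nchar(object@seq) == 0L)
    msg <- c(msg, "sequence must be a single nonempty string")
  else if (!grepl("^[ACGTN]+$", object@seq))
    msg <- c(msg, "sequence may contain only A, C, G, T, N")
  if (!object@topology %in% c("linear", "circular"))
    msg <- c(msg, "topology must be 'linear' or 'circular'")
  ann <- object@annotations
  if (nrow(ann)) {
    L <- nchar(object@seq)
    if (!all(c("label", "start", "end", "strand") %in% names(ann)))
      msg <- c(msg, "annotations need columns label, start, end, strand")
    else {
      bad <- ann$start < 0L | ann$end <= ann$start |
        (object@topology == "linear" & ann$end > L) |
        (object@topology == "circular" & ann$start >= L)
      if (any(bad))
        msg <- c(msg, "annotation coordinates out of bounds")
    }
  }
  if (length(msg)) msg else TRUE
})

.emptyAnnotations <- function() {
  data.frame(label = character(0L), start = integer(0L), end = integer(0L),
             strand = character(0L), stringsAsFactors = FALSE)
}

#' Construct a DNAMolecule
#'
#' @param id molecule identifier.
#' @param seq plus-strand nucleotide string (case-insensitive).
#' @param topology `"linear"` (default) or `"circular"`.
#' @param annotations optional data.frame (`label`, `start`, `end`, `strand`;
#'   0-based half-open).
#' @return a [DNAMolecule-class] object.
#' @examples
#' DNAMolecule("m1", "acgt", "circular")
#' @export
DNAMolecule <- function(id, seq, topology = c("linear", "circular"),
                        annotations = .emptyAnnotations()) {
  topology <- match.arg(topology)
  new("DNAMolecule", id = as.character(id), seq = toupper(as.character(seq)),
      topology = topology, annotations = annotations)
}

#' @describeIn DNAMolecule molecule identifier accessor
#' @param x a DNAMolecule.
#' @export
molId <- function(x) x@id

#' @describeIn DNAMolecule plus-strand sequence accessor
#' @export
molSeq <- function(x) x@seq

#' @describeIn DNAMolecule topology accessor
#' @export
topology <- function(x) x@topology

#' @describeIn DNAMolecule sequence length in bp
#' @export
molLength <- function(x) nchar(x@seq)

#' @describeIn DNAMolecule annotation table accessor
#' @export
annotations <- function(x) x@annotations

setMethod("show", "DNAMolecule", function(object) {
  cat(sprintf("DNAMolecule '%s': %d bp, %s, %d annotation(s)\n",
              object@id, nchar(object@seq), object@topology,
              nrow(object@annotations)))
  s <- object@seq
  if (nchar(s) > 60L) s <- paste0(substr(s, 1L, 57L), "...")
  cat("  ", s, "\n", sep = "")
})

#' Rotation-invariant molecule equality
#'
#' Circular molecules compare equal when one is a rotation of the other or of
#' its reverse complement; linear molecules compare equal up to reverse
#' complement.
#'
#' @param a,b [DNAMolecule-class] objects.
#' @return logical.
#' @export
sameMolecule <- function(a, b) {
  if (a@topology != b@topology) return(FALSE)
  if (nchar(a@seq) != nchar(b@seq)) return(FALSE)
  if (a@topology == "circular")
    .canonicalCircular(a@seq) == .canonicalCircular(b@seq)
  else
    .canonicalLinear(a@seq) == .canonicalLinear(b@seq)
}

## ---------------------------------------------------------------------------
## EnzymeSpec
## ---------------------------------------------------------------------------

#' EnzymeSpec: restriction enzyme cut geometry
#'
#' Describes both Type IIS enzymes cutting outside a non-palindromic
#' recognition (e.g. BsaI `GGTCTC(N1)` leaving 4-nt 5' overhangs) and, via a
#' negative `spacerLen`, ordinary palindromic enzymes cutting within their
#' site (e.g. SpeI `A^CTAGT` is `spacerLen = -5`, `overhangLen = 4`). The
#' top-strand cut for a plus-strand site at 0-based `rec_start` falls at
#' `rec_start + nchar(recognition) + spacerLen`; the bottom-strand cut lies
#' `overhangLen` further right (5' overhangs).
#'
#' @slot name enzyme name.
#' @slot recognition recognition sequence (A/C/G/T only).
#' @slot spacerLen integer nt between the recognition 3' end and the
#'   top-strand cut (negative for within-site cutters).
#' @slot overhangLen integer length of the 5' overhang produced (0 = blunt).
#' @export
setClass("EnzymeSpec",
         representation(name = "character", recognition = "character",
                        spacerLen = "integer", overhangLen = "integer"))

setValidity("EnzymeSpec", function(object) {
  msg <- character(0L)
  if (!grepl("^[ACGT]+$", object@recognition))
    msg <- c(msg, "recognition may contain only A, C, G, T")
  if (object@overhangLen < 0L || object@overhangLen > 8L)
    msg <- c(msg, "overhangLen must be between 0 and 8")
  if (nchar(object@recognition) + object@spacerLen < 0L)
    msg <- c(msg, "cut position may not lie left of the recognition start")
  if (length(msg)) msg else TRUE
})

#' Construct an EnzymeSpec
#'
#' @param name enzyme name.
#' @param recognition recognition sequence (A/C/G/T).
#' @param spacerLen nt between recognition 3' end and top-strand cut; negative
#'   places the cut inside the recognition site.
#' @param overhangLen length of the 5' overhang produced.
#' @return an [EnzymeSpec-class].
#' @examples
#' gbEnzyme("BsaI", "GGTCTC", 1, 4)
#' @export
gbEnzyme <- function(name, recognition, spacerLen, overhangLen) {
  new("EnzymeSpec", name = as.character(name),
      recognition = toupper(as.character(recognition)),
      spacerLen = as.integer(spacerLen), overhangLen = as.integer(overhangLen))
}

setMethod("show", "EnzymeSpec", function(object) {
  cat(sprintf("EnzymeSpec %s: %s, spacer %d, %d-nt 5' overhang\n",
              object@name, object@recognition, object@spacerLen,
              object@overhangLen))
})

#' @describeIn gbEnzyme enzyme name accessor
#' @param x an EnzymeSpec.
#' @export
enzymeName <- function(x) x@name

## ---------------------------------------------------------------------------
## Fragment
## ---------------------------------------------------------------------------

#' Fragment: a digestion product with sticky ends
#'
#' Position-free double-stranded fragment. `seq` is the full top strand
#' including the single-stranded left 5' protrusion `leftOv` (a prefix of
#' `seq`; `""` means blunt). The right end is stored as `rightOv`, the
#' plus-strand 4-mer spanning the right-hand cut: the physically protruding
#' bottom strand reads as its reverse complement, and two fragments anneal
#' exactly when one fragment's `rightOv` equals the next fragment's `leftOv`.
#' Ligation is therefore purely overhang-driven string equality.
#'
#' @slot seq top strand (includes the left overhang).
#' @slot leftOv left 5' overhang (prefix of `seq`), `""` if blunt.
#' @slot rightOv plus-strand sequence filling the right-hand cut, `""` if blunt.
#' @slot source id of the molecule the fragment was cut from.
#' @export
setClass("Fragment",
         representation(seq = "character", leftOv = "character",
                        rightOv = "character", source = "character"))

setValidity("Fragment", function(object) {
  msg <- character(0L)
  if (nchar(object@seq) == 0L) msg <- c(msg, "fragment sequence is empty")
  if (nchar(object@leftOv) > 0L && !startsWith(object@seq, object@leftOv))
    msg <- c(msg, "left overhang must be a prefix of the fragment sequence")
  if (length(msg)) msg else TRUE
})

#' Construct a Fragment
#'
#' @param seq top strand including the left overhang.
#' @param leftOv left 5' overhang (prefix of `seq`; `""` for blunt).
#' @param rightOv plus-strand fill of the right cut (`""` for blunt).
#' @param source id of the source molecule.
#' @return a [Fragment-class].
#' @export
gbFragment <- function(seq, leftOv = "", rightOv = "", source = NA_character_) {
  new("Fragment", seq = toupper(seq), leftOv = toupper(leftOv),
      rightOv = toupper(rightOv), source = as.character(source))
}

setMethod("show", "Fragment", function(object) {
  s <- object@seq
  if (nchar(s) > 48L) s <- paste0(substr(s, 1L, 45L), "...")
  cat(sprintf("Fragment [%s|%d nt|%s] from %s\n  %s\n",
              ifelse(nchar(object@leftOv), object@leftOv, "blunt"),
              nchar(object@seq),
              ifelse(nchar(object@rightOv), object@rightOv, "blunt"),
              object@source, s))
})

#' @describeIn gbFragment the two overhangs as a named character vector
#' @export
overhangs <- function(x) c(left = x@leftOv, right = x@rightOv)

## flip a fragment (use it in the opposite orientation)
.flipFragment <- function(f) {
  core <- substring(f@seq, nchar(f@leftOv) + 1L)
  gbFragment(seq = revcomp(paste0(core, f@rightOv)),
             leftOv = revcomp(f@rightOv), rightOv = revcomp(f@leftOv),
             source = f@source)
}

## ---------------------------------------------------------------------------
## AssemblyResult
## ---------------------------------------------------------------------------

#' AssemblyResult: products of a Golden Gate reaction
#'
#' @slot products list of circular [DNAMolecule-class] stable products, in
#'   deterministic (canonical-sequence) order.
#' @slot backboneIndex index of the product carrying the destination backbone
#'   (NA when none does).
#' @slot enzyme name of the assembly enzyme.
#' @export
setClass("AssemblyResult",
         representation(products = "list", backboneIndex = "integer",
                        enzyme = "character"))

#' @describeIn AssemblyResult list of stable products
#' @param x an AssemblyResult.
#' @export
products <- function(x) x@products

#' @describeIn AssemblyResult the product containing the destination backbone
#' @export
backboneProduct <- function(x) {
  if (is.na(x@backboneIndex)) return(NULL)
  x@products[[x@backboneIndex]]
}

setMethod("show", "AssemblyResult", function(object) {
  cat(sprintf("AssemblyResult (%s): %d stable product(s)%s\n", object@enzyme,
              length(object@products),
              if (!is.na(object@backboneIndex))
                sprintf(", backbone product #%d", object@backboneIndex)
              else ""))
  for (i in seq_along(object@products))
    cat(sprintf("  [%d] %s: %d bp\n", i, object@products[[i]]@id,
                nchar(object@products[[i]]@seq)))
})

## ---------------------------------------------------------------------------
## GBPart / GBVector
## ---------------------------------------------------------------------------

#' GBPart: a standardized GoldenBraid part
#'
#' A part at any level of the hierarchy: `minus1` (pre-part tRNA--scaffold
#' plasmids), `level0` (basic parts held in an entry vector, domesticated,
#' i.e. free of internal BsaI/BsmBI sites), or `level1plus` (transcriptional
#' units and multi-TU constructs hosted in alpha/omega destination vectors).
#'
#' @slot partId part identifier (GBxxxx convention).
#' @slot name human-readable name.
#' @slot level `"minus1"`, `"level0"` or `"level1plus"`.
#' @slot syntax character vector of syntax position codes spanned.
#' @slot fusions character(2): left and right fusion sites of the insert.
#' @slot insert the insert sequence (without fusion sites).
#' @slot molecule the hosting plasmid as a circular [DNAMolecule-class].
#' @slot vectorClass class of the hosting vector
#'   (`entry`/`alpha`/`omega`/`minus1_entry`).
#' @slot position braid position (1 or 2) for alpha/omega-hosted parts.
#' @export
setClass("GBPart",
         representation(partId = "character", name = "character",
                        level = "character", syntax = "character",
                        fusions = "character", insert = "character",
                        molecule = "DNAMolecule", vectorClass = "character",
                        position = "integer"))

setValidity("GBPart", function(object) {
  msg <- character(0L)
  if (!object@level %in% c("minus1", "level0", "level1plus"))
    msg <- c(msg, "level must be minus1, level0 or level1plus")
  if (!object@vectorClass %in% c("entry", "alpha", "omega", "minus1_entry"))
    msg <- c(msg, "unknown vector class")
  if (object@molecule@topology != "circular")
    msg <- c(msg, "a GBPart is hosted on a circular plasmid")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GBPart", function(object) {
  cat(sprintf("GBPart %s '%s' (%s in %s%s): %d bp plasmid, fusion %s..%s\n",
              object@partId, object@name, object@level, object@vectorClass,
              if (!is.na(object@position)) object@position else "",
              nchar(object@molecule@seq),
              object@fusions[1L], object@fusions[2L]))
})

#' @describeIn GBPart hosting plasmid accessor
#' @param x a GBPart.
#' @export
partMolecule <- function(x) x@molecule

#' @describeIn GBPart part level accessor
#' @export
partLevel <- function(x) x@level

#' @describeIn GBPart part id accessor
#' @export
partId <- function(x) x@partId

#' GBVector: a GoldenBraid entry or destination vector
#'
#' `entry` vectors (pUPD-like) accept level 0 inserts with BsmBI; `alpha`
#' vectors accept BsaI multipartite assemblies and release their cargo with
#' BsmBI; `omega` vectors the converse (the braid); `minus1_entry` vectors
#' host tRNA--scaffold cassettes opened by BsmBI for the target duplex.
#'
#' @slot vectorId vector identifier.
#' @slot klass `entry`, `alpha`, `omega` or `minus1_entry`.
#' @slot molecule circular [DNAMolecule-class].
#' @slot assemblyEnzyme [EnzymeSpec-class] used to assemble into this vector.
#' @slot releaseEnzyme [EnzymeSpec-class] releasing the hosted cargo.
#' @slot sockets character(2): fusion sites exposed by the opened stuffer.
#' @slot position braid position (1 or 2) for alpha/omega.
#' @export
setClass("GBVector",
         representation(vectorId = "character", klass = "character",
                        molecule = "DNAMolecule",
                        assemblyEnzyme = "EnzymeSpec",
                        releaseEnzyme = "EnzymeSpec",
                        sockets = "character", position = "integer"))

setValidity("GBVector", function(object) {
  msg <- character(0L)
  if (!object@klass %in% c("entry", "alpha", "omega", "minus1_entry"))
    msg <- c(msg, "klass must be entry, alpha, omega or minus1_entry")
  if (object@molecule@topology != "circular")
    msg <- c(msg, "vectors are circular plasmids")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GBVector", function(object) {
  cat(sprintf(
    "GBVector %s (%s%s): %d bp, assembles with %s, releases with %s, sockets %s..%s\n",
    object@vectorId, object@klass,
    if (!is.na(object@position)) object@position else "",
    nchar(object@molecule@seq), object@assemblyEnzyme@name,
    object@releaseEnzyme@name, object@sockets[1L], object@sockets[2L]))
})

#' @describeIn GBVector vector class accessor (also works on a [GBPart-class],
#'   returning its hosting class)
#' @param x a GBVector or GBPart.
#' @export
vectorClass <- function(x) {
  if (is(x, "GBVector")) x@klass else x@vectorClass
}

#' @describeIn GBVector hosting plasmid accessor
#' @export
vectorMolecule <- function(x) x@molecule

## ---------------------------------------------------------------------------
## TargetSpec / OligoDuplex / PolycistronDesign
## ---------------------------------------------------------------------------

#' TargetSpec: a 20-nt SpCas9 protospacer with PAM context
#'
#' The blunt SpCas9 cut is placed between protospacer nt 17 and 18 (3 bp 5' of
#' the PAM); `cutOffset` is that 0-based inter-nucleotide position within the
#' protospacer, `cutPos` the corresponding inter-nucleotide genome coordinate.
#' `diagnosticSites` lists panel enzymes whose recognition span strictly
#' contains the cut, so that indels at the cut disrupt the site.
#'
#' @slot geneId gene label (NA when the target lies outside any annotation).
#' @slot protospacer 20-nt target sequence, 5'->3' on the targeted strand.
#' @slot pam 3-nt NGG motif adjacent to the protospacer.
#' @slot strand `"+"` or `"-"` (genome strand carrying the protospacer).
#' @slot start 0-based genome offset of the protospacer's plus-strand span.
#' @slot gcPct GC content of the protospacer, percent.
#' @slot cutOffset 0-based inter-nucleotide cut position within the
#'   protospacer (default 17).
#' @slot cutPos 0-based inter-nucleotide genome coordinate of the cut.
#' @slot diagnosticSites data.frame (`enzyme`, `rec_start`, `strand`) of
#'   diagnostic restriction sites overlapping the cut.
#' @export
setClass("TargetSpec",
         representation(geneId = "character", protospacer = "character",
                        pam = "character", strand = "character",
                        start = "integer", gcPct = "numeric",
                        cutOffset = "integer", cutPos = "integer",
                        diagnosticSites = "data.frame"))

setValidity("TargetSpec", function(object) {
  msg <- character(0L)
  if (nchar(object@protospacer) != 20L)
    msg <- c(msg, "protospacer must be 20 nt")
  if (!grepl("^.GG$", object@pam))
    msg <- c(msg, "PAM must match NGG")
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TargetSpec", function(object) {
  cat(sprintf("TargetSpec %s%s at %d (%s): %s PAM %s, GC %.0f%%, %d diagnostic site(s)\n",
              ifelse(is.na(object@geneId), "", object@geneId),
              ifelse(is.na(object@geneId), "target", ""), object@start,
              object@strand, object@protospacer, object@pam, object@gcPct,
              nrow(object@diagnosticSites)))
})

#' @describeIn TargetSpec protospacer accessor
#' @param x a TargetSpec.
#' @export
protospacer <- function(x) x@protospacer

#' @describeIn TargetSpec diagnostic-site table accessor
#' @export
diagnosticSites <- function(x) x@diagnosticSites

#' OligoDuplex: annealed oligonucleotide pair encoding a target
#'
#' Two partially complementary oligos which, annealed, yield the 20-nt
#' protospacer flanked by 4-nt 5' protrusions (the fusion sites dictated by
#' the cloning mode). `rightFusion` follows the same plus-strand convention
#' as [gbFragment()] `rightOv`.
#'
#' @slot fwdOligo top-strand oligo, 5'->3' (left fusion + protospacer).
#' @slot revOligo bottom-strand oligo, 5'->3'.
#' @slot leftFusion,rightFusion the 4-nt fusion sites.
#' @slot protospacer the encoded 20-nt target.
#' @slot mode cloning mode the duplex was designed for.
#' @slot substituted5G TRUE when a non-G first base was substituted by G.
#' @export
setClass("OligoDuplex",
         representation(fwdOligo = "character", revOligo = "character",
                        leftFusion = "character", rightFusion = "character",
                        protospacer = "character", mode = "character",
                        substituted5G = "logical"))

setMethod("show", "OligoDuplex", function(object) {
  cat(sprintf("OligoDuplex (%s%s):\n  fwd 5'-%s-3'\n  rev 5'-%s-3'\n",
              object@mode,
              if (object@substituted5G) ", 5' base substituted to G" else "",
              object@fwdOligo, object@revOligo))
})

#' @describeIn domesticateTarget the duplex as a ligatable [Fragment-class]
#' @param duplex an OligoDuplex.
#' @export
duplexFragment <- function(duplex) {
  gbFragment(seq = paste0(duplex@leftFusion, duplex@protospacer),
             leftOv = duplex@leftFusion, rightOv = duplex@rightFusion,
             source = paste0("duplex:", duplex@protospacer))
}

#' PolycistronDesign: an ordered multi-guide tRNA--gRNA design
#'
#' @slot protospacers character vector of 20-nt targets, in slot order.
#' @slot targetNames labels for the targets.
#' @slot promoter the PolIII promoter [GBPart-class].
#' @slot slotParts list of level -1 tRNA--scaffold [GBPart-class], one per slot.
#' @slot label design label.
#' @export
setClass("PolycistronDesign",
         representation(protospacers = "character", targetNames = "character",
                        promoter = "GBPart", slotParts = "list",
                        label = "character"))

setValidity("PolycistronDesign", function(object) {
  msg <- character(0L)
  if (length(object@protospacers) < 2L)
    msg <- c(msg, "a polycistron needs at least 2 targets (use the monocistronic path for 1)")
  if (length(object@slotParts) != length(object@protospacers))
    msg <- c(msg, "one level -1 slot part is required per target")
  if (length(msg)) msg else TRUE
})

#' Construct a PolycistronDesign
#'
#' @param protospacers character vector (length >= 2) of 20-nt targets in
#'   slot order.
#' @param promoter PolIII promoter [GBPart-class].
#' @param slotParts list of level -1 tRNA--scaffold parts, one per slot, in
#'   slot order.
#' @param targetNames optional labels.
#' @param label design label.
#' @return a [PolycistronDesign-class].
#' @export
polycistronDesign <- function(protospacers, promoter, slotParts,
                              targetNames = names(protospacers),
                              label = "polycistron") {
  if (length(protospacers) < 2L)
    .gbValidationError("a polycistron needs at least 2 targets (use the monocistronic path for a single guide)")
  if (is.null(targetNames))
    targetNames <- paste0("target", seq_along(protospacers))
  new("PolycistronDesign", protospacers = toupper(protospacers),
      targetNames = targetNames, promoter = promoter, slotParts = slotParts,
      label = label)
}

setMethod("show", "PolycistronDesign", function(object) {
  cat(sprintf("PolycistronDesign '%s': %d slots (%s)\n", object@label,
              length(object@protospacers),
              paste(object@targetNames, collapse = ", ")))
})

## ---------------------------------------------------------------------------
## DigestPattern
## ---------------------------------------------------------------------------

#' DigestPattern: predicted restriction band sizes
#'
#' @slot enzymeName enzyme used.
#' @slot bands integer band lengths in bp, sorted descending (empty when an
#'   uncut circular molecule is reported).
#' @slot uncut TRUE when a circular molecule has no site for the enzyme.
#' @slot moleculeId id of the digested molecule.
#' @slot moleculeLength its length in bp.
#' @export
setClass("DigestPattern",
         representation(enzymeName = "character", bands = "integer",
                        uncut = "logical", moleculeId = "character",
                        moleculeLength = "integer"))

setMethod("show", "DigestPattern", function(object) {
  cat(sprintf("DigestPattern %s / %s (%d bp): %s\n", object@moleculeId,
              object@enzymeName, object@moleculeLength,
              if (object@uncut) "uncut (circular)"
              else paste(object@bands, collapse = "-")))
})

#' @describeIn predictBands band sizes accessor
#' @param x a DigestPattern.
#' @export
bands <- function(x) x@bands

#' @describeIn predictBands TRUE for an uncut circular molecule
#' @export
isUncut <- function(x) x@uncut
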