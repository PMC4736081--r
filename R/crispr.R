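#' @include grammar.R
NULL

## gene label for a plus-strand span [s, e) from molecule annotations
.geneAt <- function(mol, s, e) {
  ann <- mol@annotations
  if (!nrow(ann)) return(NA_character_)
  hit <- which(ann$start < e & ann$end > s)
  if (!length(hit)) return(NA_character_)
  paste(ann$label[hit], collapse = ",")
}

## recognition spans of an enzyme on both strands, as 0-based [start, end)
.recognitionSpans <- function(seqstr, enzyme) {
  k <- nchar(enzyme@recognition)
  s <- c(.matchStarts(seqstr, enzyme@recognition),
         .matchStarts(seqstr, revcomp(enzyme@recognition)))
  if (!length(s)) return(NULL)
  cbind(start = s, end = s + k)
}

#' Scan a genome for SpCas9 targets
#'
#' Returns every 20-mer followed by an NGG PAM on either strand that passes
#' the filters: an optional requirement for a 5' G (PolIII transcription
#' start), optional inclusive GC bounds, and optionally the presence of a
#' diagnostic restriction site from `enzymePanel` whose recognition span
#' strictly contains the blunt Cas9 cut (between protospacer nt 17 and 18),
#' so that indels at the cut destroy the site. Output order is deterministic
#' (plus-strand coordinate, then strand).
#'
#' @param genome a [DNAMolecule-class] (gene annotations, when present, label
#'   the targets).
#' @param require5primeG require the protospacer to start with G
#'   (default TRUE).
#' @param gcMin,gcMax optional inclusive GC bounds in percent (default off).
#' @param requireDiagnosticSite keep only targets with at least one
#'   diagnostic site from the panel (default FALSE).
#' @param enzymePanel list of [EnzymeSpec-class] (or configured enzyme
#'   names) screened for diagnostic sites.
#' @param cfg configuration.
#' @return list of [TargetSpec-class]; see [targetTable()] for a data.frame
#'   view.
#' @export
scanTargets <- function(genome, require5primeG = TRUE, gcMin = NULL,
                        gcMax = NULL, requireDiagnosticSite = FALSE,
                        enzymePanel = list(), cfg = gbConfig()) {
  stopifnot(is(genome, "DNAMolecule"))
  S <- genome@seq
  L <- nchar(S)
  enzymePanel <- lapply(enzymePanel, .resolveEnzyme, cfg = cfg)
  spans <- lapply(enzymePanel, function(e) .recognitionSpans(S, e))
  names(spans) <- vapply(enzymePanel, function(e) e@name, character(1L))

  diagAt <- function(cutPos) {
    rows <- list()
    for (nm in names(spans)) {
      sp <- spans[[nm]]
      if (is.null(sp)) next
      hit <- which(sp[, "start"] < cutPos & cutPos < sp[, "end"])
      for (h in hit)
        rows[[length(rows) + 1L]] <- data.frame(
          enzyme = nm, rec_start = unname(sp[h, "start"]), strand = "*")
    }
    if (!length(rows))
      return(data.frame(enzyme = character(0L), rec_start = integer(0L),
                        strand = character(0L)))
    do.call(rbind, rows)
  }

  out <- list()
  addTarget <- function(proto, pam, strand, start, cutPos) {
    if (require5primeG && substr(proto, 1L, 1L) != "G") return(invisible())
    gc <- gcContent(proto)
    if (!is.null(gcMin) && gc < gcMin) return(invisible())
    if (!is.null(gcMax) && gc > gcMax) return(invisible())
    diag <- diagAt(cutPos)
    if (requireDiagnosticSite && !nrow(diag)) return(invisible())
    out[[length(out) + 1L]] <<- new(
      "TargetSpec", geneId = .geneAt(genome, start, start + 20L),
      protospacer = proto, pam = pam, strand = strand,
      start = as.integer(start), gcPct = gc, cutOffset = 17L,
      cutPos = as.integer(cutPos), diagnosticSites = diag)
  }

  if (L >= 23L) {
    for (i in 0L:(L - 23L)) {
      ## plus strand: [i, i+20) protospacer, [i+20, i+23) PAM
      if (substr(S, i + 22L, i + 23L) == "GG")
        addTarget(substr(S, i + 1L, i + 20L), substr(S, i + 21L, i + 23L),
                  "+", i, i + 17L)
      ## minus strand: plus-strand CCN at [i, i+3), protospacer [i+3, i+23)
      if (substr(S, i + 1L, i + 2L) == "CC")
        addTarget(revcomp(substr(S, i + 4L, i + 23L)),
                  revcomp(substr(S, i + 1L, i + 3L)),
                  "-", i + 3L, i + 6L)
    }
  }
  ## deterministic order: plus-strand coordinate, then strand
  if (length(out)) {
    ord <- order(vapply(out, function(t) t@start, integer(1L)),
                 vapply(out, function(t) t@strand, character(1L)))
    out <- out[ord]
  }
  out
}

#' Tabulate a list of targets
#'
#' @param targets list of [TargetSpec-class] as returned by [scanTargets()].
#' @return data.frame with one row per target (`gene_id`, `start`, `strand`,
#'   `protospacer`, `pam`, `gc_pct`, `cut_pos`, `diag_enzymes`).
#' @export
targetTable <- function(targets) {
  if (!length(targets))
    return(data.frame(gene_id = character(0L), start = integer(0L),
                      strand = character(0L), protospacer = character(0L),
                      pam = character(0L), gc_pct = numeric(0L),
                      cut_pos = integer(0L), diag_enzymes = character(0L)))
  do.call(rbind, lapply(targets, function(t) data.frame(
    gene_id = t@geneId, start = t@start, strand = t@strand,
    protospacer = t@protospacer, pam = t@pam, gc_pct = t@gcPct,
    cut_pos = t@cutPos,
    diag_enzymes = paste(unique(t@diagnosticSites$enzyme), collapse = ","),
    stringsAsFactors = FALSE)))
}

#' Domesticate a target: design the oligo duplex
#'
#' The CRISPR domesticator: turns a 20-nt protospacer into the two partially
#' complementary oligos whose annealed duplex carries the 4-nt fusion sites
#' dictated by the cloning mode (monocistronic D- or M-Target spanning
#' B3c--B4--B5c / B3c--B4--B5d, or the slot-independent tRNA--scaffold
#' sockets of the polycistronic path). A non-G first base is either rejected
#' or substituted by G and flagged, per `policy5G`. The duplex must pass
#' [checkDomestication()].
#'
#' @param protospacer 20-nt string over A/C/G/T.
#' @param mode one of `"monocistronic_D"`, `"monocistronic_M"`,
#'   `"polycistronic"`.
#' @param slot polycistron slot number (recorded; the duplex chemistry is
#'   slot-independent, slot identity residing in the level -1 backbone).
#' @param policy5G `"substitute"` (default, from config) or `"reject"`.
#' @param cfg configuration.
#' @return an [OligoDuplex-class].
#' @export
domesticateTarget <- function(protospacer,
                              mode = c("monocistronic_D", "monocistronic_M",
                                       "polycistronic"),
                              slot = 1L, policy5G = NULL, cfg = gbConfig()) {
  mode <- match.arg(mode)
  if (is.null(policy5G)) policy5G <- cfg$policies$policy_5G
  protospacer <- toupper(protospacer)
  if (nchar(protospacer) != 20L)
    .gbValidationError("protospacer must be exactly 20 nt")
  if (!grepl("^[ACGT]+$", protospacer))
    .gbValidationError("protospacer may contain only A, C, G, T")
  substituted <- FALSE
  if (substr(protospacer, 1L, 1L) != "G") {
    if (policy5G == "reject")
      .gbValidationError("protospacer must start with G (policy_5G = reject)")
    substr(protospacer, 1L, 1L) <- "G"
    substituted <- TRUE
  }
  fus <- switch(mode,
    monocistronic_D = unlist(cfg$target_modes$monocistronic_D),
    monocistronic_M = unlist(cfg$target_modes$monocistronic_M),
    polycistronic = c(cfg$poly$duplex_sockets$left,
                      cfg$poly$duplex_sockets$right))
  fus <- unname(fus)
  duplexRegion <- paste0(fus[1L], protospacer, fus[2L])
  viol <- checkDomestication(duplexRegion, cfg = cfg)
  if (nrow(viol))
    .gbValidationError(paste0(
      "duplex contains assembly-enzyme site(s): ",
      paste(sprintf("%s(%s)@%d", viol$enzyme, viol$strand, viol$offset),
            collapse = ", ")))
  modeLabel <- if (mode == "polycistronic") sprintf("polycistronic slot %d",
                                                    as.integer(slot)) else mode
  new("OligoDuplex",
      fwdOligo = paste0(fus[1L], protospacer),
      revOligo = revcomp(paste0(protospacer, fus[2L])),
      leftFusion = fus[1L], rightFusion = fus[2L],
      protospacer = protospacer, mode = modeLabel,
      substituted5G = substituted)
}

#' Assemble a monocistronic gRNA expression cassette
#'
#' The CRISPR assembler: combines a PolIII promoter part, the annealed
#' target duplex and the scaffold RNA part in a cyclic BsaI
#' digestion--ligation into an alpha (or omega) destination, yielding a
#' level 1 transcriptional unit whose insert is promoter + protospacer +
#' scaffold, contiguous and in order.
#'
#' @param promoter PolIII promoter [GBPart-class] (right fusion must equal
#'   the duplex's left fusion).
#' @param duplex an [OligoDuplex-class] from [domesticateTarget()].
#' @param scaffold scaffold RNA [GBPart-class].
#' @param destination [GBVector-class] destination (alpha, typically).
#' @param partId,name product identifiers.
#' @param cfg configuration.
#' @return a [GBPart-class] of level `level1plus`.
#' @export
assembleGuideCassette <- function(promoter, duplex, scaffold, destination,
                                  partId = "GB0000", name = partId,
                                  cfg = gbConfig()) {
  stopifnot(is(promoter, "GBPart"), is(duplex, "OligoDuplex"),
            is(scaffold, "GBPart"), is(destination, "GBVector"))
  res <- goldenGate(parts = list(promoter@molecule, scaffold@molecule),
                    destination = destination,
                    enzyme = destination@assemblyEnzyme,
                    extraFragments = list(duplexFragment(duplex)),
                    cfg = cfg, idPrefix = partId)
  prod <- backboneProduct(res)
  if (is.null(prod))
    .gbAssemblyError("cassette assembly produced no destination-backbone product")
  expected <- paste0(promoter@insert, duplex@leftFusion, duplex@protospacer,
                     duplex@rightFusion, scaffold@insert)
  dd <- paste0(prod@seq, prod@seq)
  if (!grepl(expected, dd, fixed = TRUE) &&
      !grepl(expected, revcomp(dd), fixed = TRUE))
    .gbAssemblyError("cassette assembled out of order (promoter-target-scaffold not contiguous)")
  prod@id <- partId
  new("GBPart", partId = partId, name = name, level = "level1plus",
      syntax = c(promoter@syntax, "target", scaffold@syntax),
      fusions = destination@sockets, insert = expected, molecule = prod,
      vectorClass = destination@klass, position = destination@position)
}

#' Build a polycistronic tRNA--gRNA construct (2-D multiplexing)
#'
#' Stage 1: each target duplex enters its level -1 tRNA--scaffold plasmid
#' via BsmBI, yielding a level 0 tRNA--gRNA oligomer. Stage 2: a BsaI
#' multipartite assembly of the PolIII promoter and all n oligomers into the
#' destination vector yields the level 1 polycistron, carrying n tRNA units
#' and n protospacers in slot order.
#'
#' @param design a [PolycistronDesign-class] (slots contiguous from 1,
#'   n >= 2).
#' @param destination [GBVector-class] destination (alpha, typically).
#' @param partId,name product identifiers.
#' @param cfg configuration.
#' @return a [GBPart-class] of level `level1plus`; attribute `"oligomers"`
#'   carries the intermediate level 0 parts.
#' @export
buildPolycistron <- function(design, destination, partId = "GB0000",
                             name = partId, cfg = gbConfig()) {
  stopifnot(is(design, "PolycistronDesign"), is(destination, "GBVector"))
  n <- length(design@protospacers)
  bsmbi <- enzymeByName("BsmBI", cfg)
  oligomers <- vector("list", n)
  for (k in seq_len(n)) {
    dup <- domesticateTarget(design@protospacers[k], "polycistronic",
                             slot = k, cfg = cfg)
    slotPart <- design@slotParts[[k]]
    stopifnot(is(slotPart, "GBPart"))
    res <- goldenGate(parts = list(),
                      destination = slotPart@molecule,
                      enzyme = bsmbi,
                      extraFragments = list(duplexFragment(dup)),
                      cfg = cfg, idPrefix = sprintf("%s_olig%d", partId, k))
    prod <- backboneProduct(res)
    if (is.null(prod))
      .gbAssemblyError(sprintf("slot %d oligomer assembly failed", k))
    oligomers[[k]] <- new("GBPart",
      partId = sprintf("%s_olig%d", partId, k),
      name = sprintf("%s tRNA-gRNA oligomer %d", name, k),
      level = "level0", syntax = sprintf("slot%d", k),
      fusions = slotPart@fusions, insert = NA_character_, molecule = prod,
      vectorClass = "entry", position = NA_integer_)
  }
  res <- goldenGate(
    parts = c(list(design@promoter@molecule),
              lapply(oligomers, function(p) p@molecule)),
    destination = destination, enzyme = destination@assemblyEnzyme,
    cfg = cfg, idPrefix = partId)
  prod <- backboneProduct(res)
  if (is.null(prod))
    .gbAssemblyError("polycistron multipartite assembly produced no destination-backbone product")
  ## slot order check: rotate the product to start at the promoter, then the
  ## protospacers must each occur downstream in ascending slot order
  dd <- paste0(prod@seq, prod@seq)
  ref <- if (grepl(design@promoter@insert, dd, fixed = TRUE)) dd
         else revcomp(dd)
  at <- regexpr(design@promoter@insert, ref, fixed = TRUE)
  if (at < 0L)
    .gbAssemblyError("promoter missing from polycistron product")
  win <- substr(ref, at, at + nchar(prod@seq) - 1L)
  pos <- vapply(design@protospacers, function(p)
    as.integer(regexpr(p, win, fixed = TRUE)), integer(1L),
    USE.NAMES = FALSE)
  if (any(pos < 0L) || is.unsorted(pos, strictly = TRUE))
    .gbAssemblyError("polycistron slots assembled out of order")
  prod@id <- partId
  out <- new("GBPart", partId = partId, name = name, level = "level1plus",
             syntax = c(design@promoter@syntax,
                        sprintf("slot%d", seq_len(n))),
             fusions = destination@sockets, insert = NA_character_,
             molecule = prod, vectorClass = destination@klass,
             position = destination@position)
  attr(out, "oligomers") <- oligomers
  out
}
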