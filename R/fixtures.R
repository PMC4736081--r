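#' @include assay.R
NULL

#' Fixture generator configuration
#'
#' @param seed integer master seed; the same seed yields byte-identical
#'   fixtures.
#' @param backboneLen backbone filler length in bp (a few kb keeps digest
#'   patterns human-checkable).
#' @param gcBackground GC fraction of random filler/genome background.
#' @param nGenes number of gene regions in a mock genome.
#' @param geneLen,spacerLen gene-region and intergenic lengths in bp.
#' @return list of fixture parameters.
#' @export
fixtureConfig <- function(seed = 1L, backboneLen = 2500L,
                          gcBackground = 0.5, nGenes = 2L, geneLen = 600L,
                          spacerLen = 100L) {
  list(seed = as.integer(seed), backboneLen = as.integer(backboneLen),
       gcBackground = gcBackground, nGenes = as.integer(nGenes),
       geneLen = as.integer(geneLen), spacerLen = as.integer(spacerLen))
}

## deterministic sub-seed per fixture kind (kept well below 2^31)
.subseed <- function(fx, salt) {
  (fx$seed %% 1000003L) * 1009L + salt
}

## random DNA free of the given recognition motifs (both strands)
.cleanDNA <- function(n, gc, motifs) {
  .scrubMotifs(.randomDNA(n, gc), motifs)
}

.assemblyMotifs <- function(cfg) c("GGTCTC", "CGTCTC")

## circular occurrence counts of the two assembly enzymes, both strands
.vectorGeometryOK <- function(seqstr, nBsaI, nBsmBI) {
  cnt <- function(m) length(.matchStarts(seqstr, m, circular = TRUE))
  cnt("GGTCTC") + cnt("GAGACC") == nBsaI &&
    cnt("CGTCTC") + cnt("GAGACG") == nBsmBI
}

#' Generate a mock GoldenBraid vector
#'
#' Deterministically builds circular plasmids with the enzyme geometry of
#' each vector class: `entry` (pUPD-like; BsmBI sockets, stuffer carries the
#' recognitions), `alpha` (BsaI sockets GGAG..CGCT plus backbone BsmBI
#' release flanks at the braid position's overhangs), `omega` (the
#' converse), and `minus1_entry` (tRNA--scaffold pre-part plasmid: BsaI
#' release flanks at slot-specific fusion sites, internal BsmBI sockets
#' between tRNA and scaffold awaiting the target duplex). Backbone filler is
#' scrubbed of BsaI/BsmBI recognitions, so every vector passes its own class
#' validation.
#'
#' @param klass one of `"entry"`, `"alpha"`, `"omega"`, `"minus1_entry"`.
#' @param position braid position (1 or 2) for alpha/omega, or slot number
#'   for `minus1_entry`.
#' @param fx fixture configuration from [fixtureConfig()].
#' @param nSlots for `minus1_entry`: total slots of the polycistron design
#'   the part belongs to (the last slot closes on the C1 edge).
#' @param cfg toolbox configuration.
#' @return a [GBVector-class].
#' @export
makeVector <- function(klass = c("entry", "alpha", "omega", "minus1_entry"),
                       position = 1L, fx = fixtureConfig(), nSlots = 2L,
                       cfg = gbConfig()) {
  klass <- match.arg(klass)
  position <- as.integer(position)
  salt <- match(klass, c("entry", "alpha", "omega", "minus1_entry")) * 10L +
    position
  motifs <- .assemblyMotifs(cfg)
  bsai <- enzymeByName("BsaI", cfg)
  bsmbi <- enzymeByName("BsmBI", cfg)

  buildSeq <- function(back, stuf, innerStuf) {
    if (klass == "entry") {
      paste0(back, cfg$entry_sockets$left, "A", "GAGACG", stuf,
             "CGTCTC", "A", cfg$entry_sockets$right)
    } else if (klass == "alpha") {
      br <- cfg$braid$alpha
      xl <- if (position == 1L) br$e1 else br$mid
      xr <- if (position == 1L) br$mid else br$e3
      tu <- cfg$tu_edges
      paste0(back,
             "CGTCTC", "A", xl,           # BsmBI release flank, left
             tu$left, "A", "GAGACC",      # BsaI socket (rec on stuffer)
             stuf,
             "GGTCTC", "A", tu$right,     # BsaI socket (rec on stuffer)
             xr, "A", "GAGACG")           # BsmBI release flank, right
    } else if (klass == "omega") {
      br <- cfg$braid$omega
      yl <- if (position == 1L) br$e1 else br$mid
      yr <- if (position == 1L) br$mid else br$e3
      ba <- cfg$braid$alpha
      paste0(back,
             "GGTCTC", "A", yl,           # BsaI release flank, left
             ba$e1, "A", "GAGACG",        # BsmBI socket (rec on stuffer)
             stuf,
             "CGTCTC", "A", ba$e3,        # BsmBI socket (rec on stuffer)
             yr, "A", "GAGACC")           # BsaI release flank, right
    } else {
      bounds <- unlist(cfg$poly$slot_boundaries)
      if (position > length(bounds))
        .gbValidationError("not enough configured slot boundaries")
      sl <- bounds[position]
      sr <- if (position == nSlots) cfg$tu_edges$right
            else bounds[position + 1L]
      ds <- cfg$poly$duplex_sockets
      paste0(back,
             "GGTCTC", "A", sl,           # BsaI release flank, left
             cfg$sequences$trna,
             ds$left, "A", "GAGACG",      # BsmBI socket (rec on stuffer)
             innerStuf,
             "CGTCTC", "A", ds$right,     # BsmBI socket (rec on stuffer)
             cfg$sequences$scaffold,
             sr, "A", "GAGACC")           # BsaI release flank, right
    }
  }

  .withSeed(.subseed(fx, salt), {
    ## junction bases can recreate a recognition motif by chance; insist on
    ## the designed site counts, regenerating the filler deterministically
    want <- if (klass == "entry") c(0L, 2L) else c(2L, 2L)
    repeat {
      seqstr <- buildSeq(.cleanDNA(fx$backboneLen, fx$gcBackground, motifs),
                         .cleanDNA(400L, fx$gcBackground, motifs),
                         .cleanDNA(60L, fx$gcBackground, motifs))
      if (.vectorGeometryOK(seqstr, want[1L], want[2L])) break
    }

    if (klass == "entry") {
      vid <- sprintf("pUPD_fx%d", fx$seed)
      new("GBVector", vectorId = vid, klass = "entry",
          molecule = DNAMolecule(vid, seqstr, "circular"),
          assemblyEnzyme = bsmbi, releaseEnzyme = bsai,
          sockets = c(cfg$entry_sockets$left, cfg$entry_sockets$right),
          position = NA_integer_)
    } else if (klass == "alpha") {
      vid <- sprintf("pDGB3alpha%d_fx%d", position, fx$seed)
      new("GBVector", vectorId = vid, klass = "alpha",
          molecule = DNAMolecule(vid, seqstr, "circular"),
          assemblyEnzyme = bsai, releaseEnzyme = bsmbi,
          sockets = c(cfg$tu_edges$left, cfg$tu_edges$right),
          position = position)
    } else if (klass == "omega") {
      vid <- sprintf("pDGB3omega%d_fx%d", position, fx$seed)
      new("GBVector", vectorId = vid, klass = "omega",
          molecule = DNAMolecule(vid, seqstr, "circular"),
          assemblyEnzyme = bsmbi, releaseEnzyme = bsai,
          sockets = c(cfg$braid$alpha$e1, cfg$braid$alpha$e3),
          position = position)
    } else {
      ds <- cfg$poly$duplex_sockets
      vid <- sprintf("pVD1_slot%d_fx%d", position, fx$seed)
      new("GBVector", vectorId = vid, klass = "minus1_entry",
          molecule = DNAMolecule(vid, seqstr, "circular"),
          assemblyEnzyme = bsmbi, releaseEnzyme = bsai,
          sockets = c(ds$left, ds$right), position = position)
    }
  })
}

#' Wrap a level -1 vector as a GBPart for polycistron designs
#'
#' @param slot slot number.
#' @param nSlots total slots of the design.
#' @param fx fixture configuration.
#' @param cfg toolbox configuration.
#' @return a [GBPart-class] of level `minus1`.
#' @export
makeSlotPart <- function(slot, nSlots, fx = fixtureConfig(),
                         cfg = gbConfig()) {
  v <- makeVector("minus1_entry", slot, fx, nSlots = nSlots, cfg = cfg)
  new("GBPart", partId = v@vectorId, name = v@vectorId, level = "minus1",
      syntax = sprintf("slot%d", slot), fusions = v@sockets,
      insert = NA_character_, molecule = v@molecule,
      vectorClass = "minus1_entry", position = as.integer(slot))
}

#' Mock level 0 PolIII promoter part
#'
#' The configured synthetic U6-26 stand-in cloned as a level 0 part spanning
#' A1 to the B3c left edge (right fusion ATTG), ready to drive either a
#' monocistronic target duplex or a polycistron's first slot.
#'
#' @param fx fixture configuration.
#' @param cfg toolbox configuration.
#' @return a [GBPart-class].
#' @export
makePromoterPart <- function(fx = fixtureConfig(), cfg = gbConfig()) {
  entry <- makeVector("entry", fx = fx, cfg = cfg)
  makeLevel0(cfg$sequences$promoters[["U6-26"]], syntaxCodes = "A1",
             fusions = c(cfg$tu_edges$left, cfg$syntax$B3c$left),
             entryVector = entry, partId = "GB1001_fx",
             name = "U6-26 promoter (synthetic stand-in)", cfg = cfg)
}

#' Mock level 0 scaffold RNA part
#'
#' @param fx fixture configuration.
#' @param mode `"D"` (B5c path, left fusion GCTT) or `"M"` (B5d path).
#' @param cfg toolbox configuration.
#' @return a [GBPart-class].
#' @export
makeScaffoldPart <- function(fx = fixtureConfig(), mode = c("D", "M"),
                             cfg = gbConfig()) {
  mode <- match.arg(mode)
  entry <- makeVector("entry", fx = fx, cfg = cfg)
  left <- if (mode == "D") cfg$target_modes$monocistronic_D$right
          else cfg$target_modes$monocistronic_M$right
  makeLevel0(cfg$sequences$scaffold, syntaxCodes = "C1",
             fusions = c(left, cfg$tu_edges$right), entryVector = entry,
             partId = paste0("GB0645_fx", mode),
             name = "sgRNA scaffold", cfg = cfg)
}

#' Mock transcriptional units for the braid
#'
#' `makeCas9TU` assembles synthetic promoter/Cas9-CDS/terminator level 0
#' stand-ins multipartitely into an alpha destination; `makeMarkerTU` does
#' the same for a small marker gene (useful as the braid partner when a TU
#' must be moved to an omega host via a binary step).
#'
#' @param destination [GBVector-class] alpha destination for the TU.
#' @param fx fixture configuration.
#' @param cfg toolbox configuration.
#' @return a [GBPart-class] (level `level1plus`).
#' @export
makeCas9TU <- function(destination, fx = fixtureConfig(),
                       cfg = gbConfig()) {
  .makeCdsTU(destination, fx, cfg, salt = 77L, label = "Cas9",
             cdsLen = 1200L)
}

#' @rdname makeCas9TU
#' @export
makeMarkerTU <- function(destination, fx = fixtureConfig(),
                         cfg = gbConfig()) {
  .makeCdsTU(destination, fx, cfg, salt = 78L, label = "marker",
             cdsLen = 450L)
}

.makeCdsTU <- function(destination, fx, cfg, salt, label, cdsLen) {
  stopifnot(is(destination, "GBVector"))
  motifs <- .assemblyMotifs(cfg)
  entry <- makeVector("entry", fx = fx, cfg = cfg)
  .withSeed(.subseed(fx, salt), {
    prom <- .cleanDNA(300L, fx$gcBackground, motifs)
    cds <- .cleanDNA(cdsLen, fx$gcBackground, motifs)
    term <- .cleanDNA(200L, fx$gcBackground, motifs)
    pProm <- makeLevel0(prom, syntaxCodes = c("A1", "A2", "A3", "B1", "B2"),
                        entryVector = entry,
                        partId = sprintf("GB_fx%sProm", label),
                        name = sprintf("%s promoter (synthetic stand-in)",
                                       label), cfg = cfg)
    pCds <- makeLevel0(cds, syntaxCodes = c("B3", "B4", "B5"),
                       entryVector = entry,
                       partId = sprintf("GB_fx%sCDS", label),
                       name = sprintf("%s CDS (synthetic stand-in)", label),
                       cfg = cfg)
    pTerm <- makeLevel0(term, syntaxCodes = c("B6", "C1"),
                        entryVector = entry,
                        partId = sprintf("GB_fx%sTerm", label),
                        name = "terminator (synthetic stand-in)", cfg = cfg)
    res <- goldenGate(list(pProm, pCds, pTerm), destination,
                      destination@assemblyEnzyme, cfg = cfg,
                      idPrefix = sprintf("%sTU_fx", label))
    prod <- backboneProduct(res)
    if (is.null(prod))
      .gbAssemblyError(sprintf("%s TU assembly failed", label))
    prod@id <- sprintf("%sTU_fx", label)
    new("GBPart", partId = sprintf("%sTU_fx", label),
        name = sprintf("%s TU (synthetic)", label),
        level = "level1plus", syntax = c("A1-B2", "B3-B5", "B6-C1"),
        fusions = destination@sockets, insert = NA_character_,
        molecule = prod, vectorClass = destination@klass,
        position = destination@position)
  })
}

## protospacer with exact GC and an optional diagnostic recognition ending
## at its 3' end (span [14, 20) strictly contains the cut at 17); free of
## assembly-enzyme and panel motifs otherwise
.plantableProtospacer <- function(gcPct, diagRecognition = NULL,
                                  cfg = gbConfig()) {
  panelMotifs <- c(.assemblyMotifs(cfg), "ACTAGT", "AAGCTT", "GGATCC",
                   "GAATTC")
  avoid <- setdiff(panelMotifs, diagRecognition)
  tail <- if (is.null(diagRecognition)) "" else diagRecognition
  need <- 20L - 1L - nchar(tail)
  gcTail <- sum(strsplit(tail, "")[[1L]] %in% c("G", "C"))
  gcN <- as.integer(round(gcPct / 100 * 20)) - 1L - gcTail  # leading G counts
  if (gcN < 0L || gcN > need)
    stop("requested GC content incompatible with the diagnostic site")
  for (i in seq_len(500L)) {
    mid <- paste(sample(c(sample(c("G", "C"), gcN, replace = TRUE),
                          sample(c("A", "T"), need - gcN, replace = TRUE))),
                 collapse = "")
    p <- paste0("G", mid, tail)
    clean <- !any(vapply(avoid, function(m)
      grepl(m, p, fixed = TRUE) || grepl(revcomp(m), p, fixed = TRUE),
      logical(1L)))
    if (clean) return(p)
  }
  stop("could not construct a protospacer with the requested properties")
}

#' Generate a mock genome with planted CRISPR targets
#'
#' A linear molecule of gene regions separated by intergenic spacers, with
#' 20-nt + NGG targets planted at recorded coordinates. The same protospacer
#' may be planted into several gene regions (one guide covering a small gene
#' family). Background is scrubbed of all configured recognition motifs, and
#' every planted target passes the [scanTargets()] filters (5' G, NGG PAM)
#' by construction; each planted 23-mer occurs exactly as often as planted
#' (on accidental collision the genome is regenerated deterministically).
#'
#' @param fx fixture configuration from [fixtureConfig()]; when `planted`
#'   names more genes than `fx$nGenes`, one region per planted gene is
#'   created.
#' @param planted data.frame with columns `gene` (gene label), `protospacer`
#'   (20-nt, or NA to draw one), `diag` (diagnostic enzyme name or NA) and
#'   optionally `gc_pct` (target GC when drawing). One row per planting;
#'   repeat a protospacer to share it across genes. NULL plants nothing.
#' @param cfg toolbox configuration.
#' @return list with `genome` (annotated [DNAMolecule-class]) and `truth`
#'   (data.frame: `gene_id`, `start`, `strand`, `protospacer`, `pam`,
#'   `diag_enzyme`).
#' @export
makeGenome <- function(fx = fixtureConfig(), planted = NULL,
                       cfg = gbConfig()) {
  if (fx$nGenes < 1L) .gbValidationError("nGenes must be >= 1")
  enzAll <- defaultEnzymes(cfg)
  motifs <- unique(unlist(lapply(enzAll, function(e) e@recognition)))
  if (!is.null(planted)) {
    planted$protospacer <- as.character(planted$protospacer)
    if (!"diag" %in% names(planted)) planted$diag <- NA_character_
  }
  .withSeed(.subseed(fx, 555L), {
    genes <- if (!is.null(planted)) unique(planted$gene) else character(0L)
    if (length(genes) < fx$nGenes)
      genes <- c(genes, paste0("gene", seq_len(fx$nGenes - length(genes))))

    for (attempt in seq_len(50L)) {
      plan <- planted
      if (!is.null(plan)) {
        for (i in seq_len(nrow(plan))) {
          if (is.na(plan$protospacer[i])) {
            gc <- if ("gc_pct" %in% names(plan) && !is.na(plan$gc_pct[i]))
              plan$gc_pct[i] else 50
            diagRec <- if (!is.na(plan$diag[i]))
              enzAll[[plan$diag[i]]]@recognition else NULL
            plan$protospacer[i] <- .plantableProtospacer(gc, diagRec, cfg)
          }
        }
      }
      pieces <- character(0L)
      truth <- list()
      ann <- list()
      offset <- 0L
      for (g in genes) {
        body <- .scrubMotifs(.randomDNA(fx$geneLen, fx$gcBackground), motifs)
        rows <- if (is.null(plan)) integer(0L) else which(plan$gene == g)
        at <- 50L  # 0-based offset within the gene body
        for (r in rows) {
          site <- paste0(plan$protospacer[r], "TGG")
          stopifnot(at + nchar(site) <= fx$geneLen)
          substr(body, at + 1L, at + nchar(site)) <- site
          truth[[length(truth) + 1L]] <- data.frame(
            gene_id = g, start = offset + at, strand = "+",
            protospacer = plan$protospacer[r], pam = "TGG",
            diag_enzyme = plan$diag[r], stringsAsFactors = FALSE)
          at <- at + 120L
        }
        ann[[length(ann) + 1L]] <- data.frame(
          label = g, start = offset, end = offset + fx$geneLen,
          strand = "+", stringsAsFactors = FALSE)
        pieces <- c(pieces, body,
                    .scrubMotifs(.randomDNA(fx$spacerLen, fx$gcBackground),
                                 motifs))
        offset <- offset + fx$geneLen + fx$spacerLen
      }
      seqstr <- paste(pieces, collapse = "")
      truth <- if (length(truth)) do.call(rbind, truth)
               else data.frame(gene_id = character(0L), start = integer(0L),
                               strand = character(0L),
                               protospacer = character(0L),
                               pam = character(0L),
                               diag_enzyme = character(0L))
      ## collision check: every planted 23-mer occurs exactly as often as
      ## planted, and only on the plus strand
      ok <- TRUE
      if (nrow(truth)) {
        for (p in unique(truth$protospacer)) {
          s23 <- paste0(p, "TGG")
          want <- sum(truth$protospacer == p)
          if (length(.matchStarts(seqstr, s23)) != want ||
              length(.matchStarts(seqstr, revcomp(s23))) != 0L) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok) {
        genome <- DNAMolecule(sprintf("mock_genome_fx%d", fx$seed), seqstr,
                              "linear", annotations = do.call(rbind, ann))
        return(list(genome = genome, truth = truth))
      }
    }
    stop("could not plant targets without collisions")
  })
}

#' Build the full 2-D multiplexing demonstration on fixtures
#'
#' End-to-end fixture pipeline exercising the whole toolbox: a mock genome
#' carries five distinct targets across seven gene labels (two
#' xylosyltransferase-style targets with diagnostic restriction sites, and
#' three fucosyltransferase-style targets of which one is shared by a
#' three-gene subfamily). The two XT guides enter a 2-slot polycistron
#' (alpha-1), the three FucT guides a 3-slot polycistron (alpha-2); a binary
#' braid reaction combines them into a level 2 omega construct carrying all
#' five gRNAs; a Cas9 TU (paired with a marker TU through its own binary
#' step into omega-2) is then added in a final binary reaction.
#'
#' @param seed master fixture seed.
#' @param cfg toolbox configuration.
#' @return list with `truth`, `targets` (scan table), the intermediate and
#'   final [GBPart-class] constructs (`polyA`, `polyB`, `level2`,
#'   `cas9TU`, `final`), and the summary counts `n_guides` (protospacer
#'   slots in the level 2 construct) and `n_genes` (distinct truth-table
#'   gene labels those guides cover).
#' @export
demoMultiplex <- function(seed = 1L, cfg = gbConfig()) {
  fx <- fixtureConfig(seed = seed, nGenes = 7L)
  ## synthetic XT-style targets: GC fixed by construction at 50% and 30%,
  ## diagnostic sites overlapping the cut between nt 17 and 18
  xt1 <- "GCATGCCGTAAACGACTAGT"   # 50% GC, SpeI across the cut
  xt2 <- "GATTACGTAATACAAAGCTT"   # 30% GC, HindIII across the cut
  shared <- .withSeed(.subseed(fx, 901L),
                      .plantableProtospacer(40, NULL, cfg))
  planted <- data.frame(
    gene = c("XT1", "XT2", "FucT1", "FucT2", "FucT3", "FucT4", "FucT5"),
    protospacer = c(xt1, xt2, shared, shared, shared, NA, NA),
    diag = c("SpeI", "HindIII", NA, NA, NA, NA, NA),
    gc_pct = c(50, 30, 40, 40, 40, 45, 55),
    stringsAsFactors = FALSE)
  gen0 <- makeGenome(fx, planted = planted, cfg = cfg)
  genome <- gen0$genome
  truth <- gen0$truth

  targets <- scanTargets(genome, require5primeG = TRUE,
                         enzymePanel = list("SpeI", "HindIII"), cfg = cfg)
  tt <- targetTable(targets)

  prom <- makePromoterPart(fx, cfg)
  alpha1 <- makeVector("alpha", 1L, fx, cfg = cfg)
  alpha2 <- makeVector("alpha", 2L, fx, cfg = cfg)
  omega1 <- makeVector("omega", 1L, fx, cfg = cfg)
  omega2 <- makeVector("omega", 2L, fx, cfg = cfg)

  xtProtos <- c(XT1 = xt1, XT2 = xt2)
  fucProtos <- unique(truth$protospacer[grepl("^FucT", truth$gene_id)])
  names(fucProtos) <- paste0("FucT_guide", seq_along(fucProtos))

  designA <- polycistronDesign(
    xtProtos, promoter = prom,
    slotParts = lapply(1:2, makeSlotPart, nSlots = 2L, fx = fx, cfg = cfg),
    label = "XT polycistron")
  designB <- polycistronDesign(
    fucProtos, promoter = prom,
    slotParts = lapply(1:3, makeSlotPart, nSlots = 3L, fx = fx, cfg = cfg),
    label = "FucT polycistron")

  polyA <- buildPolycistron(designA, alpha1, partId = "polyXT_fx",
                            name = "XT 2-guide polycistron", cfg = cfg)
  polyB <- buildPolycistron(designB, alpha2, partId = "polyFucT_fx",
                            name = "FucT 3-guide polycistron", cfg = cfg)
  level2 <- binaryAssemble(polyA, polyB, omega1, partId = "level2_fx",
                           name = "5-guide level 2", cfg = cfg)
  ## host the Cas9 TU in omega-2 via its own binary step (braid chemistry:
  ## multipartite TU assembly lands in alpha)
  cas9A <- makeCas9TU(alpha1, fx, cfg)
  markerB <- makeMarkerTU(alpha2, fx, cfg)
  cas9TU <- binaryAssemble(cas9A, markerB, omega2, partId = "cas9omega_fx",
                           name = "Cas9 + marker (omega)", cfg = cfg)
  final <- binaryAssemble(level2, cas9TU, alpha1, partId = "final_fx",
                          name = "5-guide + Cas9", cfg = cfg)

  allProtos <- c(xtProtos, fucProtos)
  slotCounts <- vapply(allProtos, function(p)
    length(.matchStarts(level2@molecule@seq, p, circular = TRUE)) +
      length(.matchStarts(level2@molecule@seq, revcomp(p),
                          circular = TRUE)),
    integer(1L))
  nGuides <- sum(slotCounts)
  nGenes <- length(unique(truth$gene_id[
    truth$protospacer %in% allProtos[slotCounts > 0L]]))

  list(truth = truth, targets = tt, genome = genome, polyA = polyA,
       polyB = polyB, level2 = level2, cas9TU = cas9TU, final = final,
       n_guides = nGuides, n_genes = nGenes)
}
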