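#' @include core-digest.R
NULL

## orientation table for a fragment list: one row per usable orientation
.orientations <- function(fragments) {
  rows <- list()
  for (i in seq_along(fragments)) {
    f <- fragments[[i]]
    g <- .flipFragment(f)
    rows[[length(rows) + 1L]] <- list(idx = i, flip = FALSE, seq = f@seq,
                                      L = f@leftOv, R = f@rightOv)
    if (g@seq != f@seq || g@leftOv != f@leftOv || g@rightOv != f@rightOv)
      rows[[length(rows) + 1L]] <- list(idx = i, flip = TRUE, seq = g@seq,
                                        L = g@leftOv, R = g@rightOv)
  }
  rows
}

.warnPalindromicOverhangs <- function(fragments) {
  ovs <- unique(unlist(lapply(fragments, function(f)
    c(f@leftOv, f@rightOv))))
  ovs <- ovs[nchar(ovs) > 0L]
  pal <- ovs[ovs == revcomp(ovs)]
  if (length(pal))
    warning(sprintf("palindromic overhang(s) %s permit self-ligation",
                    paste(unique(pal), collapse = ", ")), call. = FALSE)
}

#' Ligate sticky-ended fragments
#'
#' Builds the directed compatibility graph over fragments in both
#' orientations (an edge runs from one fragment to another when the first
#' fragment's right overhang anneals to the second's left overhang) and
#' enumerates the distinct products. Circular products are simple cycles --
#' each physical fragment used at most once -- reported once under rotation
#' and reverse complement; with `requireCircular = FALSE` maximal linear
#' paths are reported as well. Output order is deterministic (lexicographic
#' on the canonical sequence). Palindromic overhangs are permitted but emit
#' a self-ligation warning.
#'
#' @param fragments nonempty list of [Fragment-class] objects.
#' @param requireCircular when TRUE (default) only circular products are
#'   returned.
#' @param maxFragments cap on fragments per product (default 10).
#' @param maxProducts cap on enumerated products; exceeding it raises an
#'   error advising a cap increase (default 50).
#' @param idPrefix prefix for product molecule ids.
#' @return list of [DNAMolecule-class] products.
#' @examples
#' bsai <- gbEnzyme("BsaI", "GGTCTC", 1, 4)
#' m <- DNAMolecule("plasmid", paste0("GGTCTCAACCT", strrep("AT", 20),
#'                                    "GGTCTCATTGC", strrep("GA", 20)),
#'                  "circular")
#' length(ligate(digest(m, bsai)))
#' @export
ligate <- function(fragments, requireCircular = TRUE, maxFragments = 10L,
                   maxProducts = 50L, idPrefix = "product") {
  if (!length(fragments))
    .gbValidationError("no fragments to ligate")
  .warnPalindromicOverhangs(fragments)
  ori <- .orientations(fragments)
  n <- length(fragments)

  circSeqs <- character(0L)
  linSeqs <- character(0L)

  emitCycle <- function(pathSeqs) {
    circSeqs[[length(circSeqs) + 1L]] <<- .canonicalCircular(
      paste(pathSeqs, collapse = ""))
    if (length(unique(circSeqs)) > maxProducts)
      stop(sprintf(
        "more than %d distinct circular products; increase maxProducts if this is intended",
        maxProducts))
  }

  ## cycles: anchor on the smallest fragment index present in the cycle
  for (a in seq_len(n)) {
    aNodes <- Filter(function(o) o$idx == a, ori)
    for (start in aNodes) {
      ## depth-first over nodes with fragment index > a
      walk <- function(node, used, seqs) {
        if (nchar(node$R) > 0L && node$R == start$L)
          emitCycle(seqs)
        if (length(seqs) >= maxFragments) return(invisible())
        for (o in ori) {
          if (o$idx <= a || used[o$idx]) next
          if (nchar(node$R) > 0L && node$R == o$L) {
            u <- used; u[o$idx] <- TRUE
            walk(o, u, c(seqs, o$seq))
          }
        }
      }
      used <- rep(FALSE, n)
      used[a] <- TRUE
      walk(start, used, start$seq)
    }
  }

  if (!requireCircular) {
    ## maximal simple paths: extendable to the right by no unused fragment,
    ## and not preceded by any unused fragment on the left
    extendable <- function(node, used) {
      any(vapply(ori, function(o)
        !used[o$idx] && nchar(node$R) > 0L && node$R == o$L, logical(1L)))
    }
    precedable <- function(node, used) {
      any(vapply(ori, function(o)
        !used[o$idx] && nchar(o$R) > 0L && o$R == node$L, logical(1L)))
    }
    for (start in ori) {
      walkLin <- function(node, used, seqs, first) {
        if (length(seqs) >= maxFragments ||
            !extendable(node, used)) {
          if (!precedable(first, used))
            linSeqs[[length(linSeqs) + 1L]] <<- .canonicalLinear(
              paste(seqs, collapse = ""))
          return(invisible())
        }
        for (o in ori) {
          if (used[o$idx]) next
          if (nchar(node$R) > 0L && node$R == o$L) {
            u <- used; u[o$idx] <- TRUE
            walkLin(o, u, c(seqs, o$seq), first)
          }
        }
      }
      used <- rep(FALSE, n)
      used[start$idx] <- TRUE
      walkLin(start, used, start$seq, start)
    }
  }

  circSeqs <- sort(unique(circSeqs))
  linSeqs <- sort(unique(linSeqs))
  out <- list()
  for (i in seq_along(circSeqs))
    out[[length(out) + 1L]] <- DNAMolecule(sprintf("%s_c%d", idPrefix, i),
                                           circSeqs[i], "circular")
  if (!requireCircular)
    for (i in seq_along(linSeqs))
      out[[length(out) + 1L]] <- DNAMolecule(sprintf("%s_l%d", idPrefix, i),
                                             linSeqs[i], "linear")
  out
}

## does a molecule carry the enzyme recognition on either strand?
.hasRecognition <- function(seqstr, enzyme, circular = FALSE) {
  length(.matchStarts(seqstr, enzyme@recognition, circular)) > 0L ||
    length(.matchStarts(seqstr, revcomp(enzyme@recognition), circular)) > 0L
}

#' One-pot Golden Gate assembly
#'
#' Simulates the cyclic digestion--ligation endpoint: every input molecule is
#' digested with the assembly enzyme, the resulting sticky fragments are
#' ligated, and only stable products are returned -- circular molecules that
#' contain no recognition site of the assembly enzyme on either strand (an
#' unstable product would be re-cut in the cyclic reaction). The product
#' carrying the destination backbone (the destination fragment free of
#' recognition sites) is flagged.
#'
#' @param parts list of [DNAMolecule-class] (or [GBPart-class]) inputs.
#' @param destination the destination vector as a [DNAMolecule-class] (or
#'   [GBVector-class]); must contain at least two sites of the enzyme.
#' @param enzyme assembly [EnzymeSpec-class] or configured enzyme name.
#' @param extraFragments optional list of pre-formed [Fragment-class] inputs
#'   (e.g. an annealed oligo duplex), pooled with the digestion fragments.
#' @param cfg configuration used to resolve a named enzyme.
#' @param idPrefix prefix for product ids.
#' @return an [AssemblyResult-class]. Raises an assembly-failure error
#'   listing unmatched overhangs when no stable circular product exists.
#' @export
goldenGate <- function(parts, destination, enzyme, extraFragments = list(),
                       cfg = gbConfig(), idPrefix = "assembly") {
  enzyme <- .resolveEnzyme(enzyme, cfg)
  asMol <- function(x) {
    if (is(x, "GBPart")) x@molecule
    else if (is(x, "GBVector")) x@molecule
    else x
  }
  parts <- lapply(parts, asMol)
  destination <- asMol(destination)

  destSites <- .cutWindows(destination, enzyme)
  if (nrow(destSites) < 2L)
    .gbValidationError(sprintf(
      "destination '%s' must carry at least two %s sites releasing a stuffer",
      destination@id, enzyme@name))

  pool <- list()
  backboneSeq <- NULL
  inputs <- c(parts, list(destination))
  for (i in seq_along(inputs)) {
    m <- inputs[[i]]
    frs <- digest(m, enzyme)
    if (!length(frs)) {
      warning(sprintf("input '%s' has no %s site and is ignored", m@id,
                      enzyme@name), call. = FALSE)
      next
    }
    clean <- Filter(function(f) !.hasRecognition(f@seq, enzyme), frs)
    if (i == length(inputs) && length(clean)) {
      ## the backbone is the recognition-free destination fragment
      lens <- vapply(clean, function(f) nchar(f@seq), integer(1L))
      backboneSeq <- clean[[which.max(lens)]]@seq
    }
    pool <- c(pool, clean)
  }
  pool <- c(pool, extraFragments)
  if (!length(pool))
    .gbAssemblyError("assembly failure: no recognition-free fragments to assemble")

  products <- ligate(pool, requireCircular = TRUE,
                     maxFragments = cfg$policies$cycle_cap_fragments,
                     maxProducts = cfg$policies$cycle_cap_products,
                     idPrefix = idPrefix)
  ## junction-spanning recognition sites make a product unstable too
  stable <- Filter(function(p) !.hasRecognition(p@seq, enzyme,
                                                circular = TRUE), products)
  if (!length(stable)) {
    lefts <- unlist(lapply(pool, function(f)
      c(f@leftOv, revcomp(f@rightOv))))
    rights <- unlist(lapply(pool, function(f)
      c(f@rightOv, revcomp(f@leftOv))))
    dangling <- unique(c(setdiff(rights, lefts), setdiff(lefts, rights)))
    dangling <- dangling[nchar(dangling) > 0L]
    .gbAssemblyError(sprintf(
      "assembly failure: no stable circular product; unmatched overhang(s): %s",
      if (length(dangling)) paste(dangling, collapse = ", ") else "none (broken chain)"))
  }
  bb <- NA_integer_
  if (!is.null(backboneSeq)) {
    hit <- vapply(stable, function(p) {
      d <- paste0(p@seq, p@seq)
      grepl(backboneSeq, d, fixed = TRUE) ||
        grepl(backboneSeq, revcomp(d), fixed = TRUE)
    }, logical(1L))
    if (any(hit)) bb <- which(hit)[1L]
  }
  new("AssemblyResult", products = stable, backboneIndex = bb,
      enzyme = enzyme@name)
}
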