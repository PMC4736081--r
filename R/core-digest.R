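#' @include AllClasses.R AllGenerics.R enzymes.R
NULL

#' Find restriction sites on both strands
#'
#' Scans the plus strand for the recognition sequence and for its reverse
#' complement (minus-strand sites). On circular molecules matches spanning
#' the origin are found and cut offsets are reduced modulo the length. Cut
#' offsets are 0-based inter-nucleotide positions on the plus-strand
#' coordinate: for a plus-strand site, `cut_top = rec_start +
#' nchar(recognition) + spacerLen` and `cut_bottom = cut_top + overhangLen`;
#' minus-strand sites mirror the geometry (the top-strand cut always lies
#' left of the bottom-strand cut, as expected for 5' overhangs).
#'
#' @param mol a [DNAMolecule-class].
#' @param enzyme an [EnzymeSpec-class].
#' @return data.frame with columns `enzyme`, `strand`, `rec_start`,
#'   `cut_top`, `cut_bottom`, sorted by `rec_start` then strand. For linear
#'   molecules, sites whose cut window falls off either end carry `NA` cut
#'   offsets (the enzyme binds but cannot produce a duplex cut).
#' @examples
#' bsai <- gbEnzyme("BsaI", "GGTCTC", 1, 4)
#' findSites(DNAMolecule("m", "TTTGGTCTCAACCTCCCGGG"), bsai)
#' @export
findSites <- function(mol, enzyme) {
  stopifnot(is(mol, "DNAMolecule"), is(enzyme, "EnzymeSpec"))
  S <- mol@seq
  L <- nchar(S)
  circ <- mol@topology == "circular"
  rec <- enzyme@recognition
  k <- nchar(rec)
  sp <- enzyme@spacerLen
  ov <- enzyme@overhangLen

  plus <- .matchStarts(S, rec, circular = circ)
  minus <- .matchStarts(S, revcomp(rec), circular = circ)

  rows <- list()
  if (length(plus)) {
    ct <- plus + k + sp
    cb <- ct + ov
    rows[[1L]] <- data.frame(strand = "+", rec_start = plus,
                             cut_top = ct, cut_bottom = cb)
  }
  if (length(minus)) {
    cb <- minus - sp
    ct <- cb - ov
    rows[[2L]] <- data.frame(strand = "-", rec_start = minus,
                             cut_top = ct, cut_bottom = cb)
  }
  if (!length(rows)) {
    return(data.frame(enzyme = character(0L), strand = character(0L),
                      rec_start = integer(0L), cut_top = integer(0L),
                      cut_bottom = integer(0L)))
  }
  df <- do.call(rbind, rows)
  if (circ) {
    shift <- ((df$cut_top %% L) + L) %% L
    df$cut_bottom <- shift + (df$cut_bottom - df$cut_top)
    df$cut_top <- shift
  } else {
    off <- df$cut_top < 0L | df$cut_bottom > L
    df$cut_top[off] <- NA_integer_
    df$cut_bottom[off] <- NA_integer_
  }
  df <- df[order(df$rec_start, df$strand), , drop = FALSE]
  data.frame(enzyme = enzyme@name, df, row.names = NULL,
             stringsAsFactors = FALSE)
}

## distinct usable cut windows (t, b), sorted; errors on overlapping windows
.cutWindows <- function(mol, enzyme) {
  sites <- findSites(mol, enzyme)
  sites <- sites[!is.na(sites$cut_top), , drop = FALSE]
  if (!nrow(sites)) return(sites)
  cuts <- sites[!duplicated(sites[c("cut_top", "cut_bottom")]), , drop = FALSE]
  cuts <- cuts[order(cuts$cut_top), , drop = FALSE]
  n <- nrow(cuts)
  if (n >= 2L) {
    nxt_t <- c(cuts$cut_top[-1L], cuts$cut_top[1L] + nchar(mol@seq))
    prev_b <- c(cuts$cut_bottom, NA_integer_)[seq_len(n)]
    over <- which(nxt_t < prev_b)
    if (mol@topology == "linear" && length(over)) over <- over[over < n]
    if (length(over)) {
      stop(sprintf(
        "ambiguous digest of '%s' with %s: cut windows overlap near recognition offsets %s",
        mol@id, enzyme@name,
        paste(cuts$rec_start[unique(c(over, over + 1L))], collapse = ", ")))
    }
  } else if (n == 1L && mol@topology == "circular" &&
             nchar(mol@seq) < enzyme@overhangLen) {
    stop("molecule shorter than the overhang; ambiguous digest")
  }
  cuts
}

#' @describeIn digest cut a molecule at every enzyme site into sticky-ended
#'   fragments. A circular molecule with `k >= 1` sites yields `k` fragments;
#'   a linear molecule with `k` sites yields `k + 1` fragments with blunt
#'   outer ends. A circular molecule with no site returns an empty list with
#'   attribute `uncut = TRUE`. Fragment top-strand lengths (counting each
#'   overhang once) always sum to the molecule length. Two cuts closer than
#'   the overhang length raise an "ambiguous digest" error naming the sites.
#' @export
setMethod("digest", signature("DNAMolecule", "EnzymeSpec"),
          function(x, enzyme, ...) {
  S <- x@seq
  L <- nchar(S)
  cuts <- .cutWindows(x, enzyme)
  if (!nrow(cuts)) {
    if (x@topology == "circular")
      return(structure(list(), uncut = TRUE))
    return(list(gbFragment(S, "", "", source = x@id)))
  }
  tt <- cuts$cut_top
  bb <- cuts$cut_bottom
  frs <- list()
  if (x@topology == "linear") {
    t0 <- c(0L, tt, L)
    b0 <- c(0L, bb, L)
    for (i in seq_len(length(tt) + 1L)) {
      frs[[i]] <- gbFragment(
        seq = substr(S, t0[i] + 1L, t0[i + 1L]),
        leftOv = if (i == 1L) "" else substr(S, t0[i] + 1L, b0[i]),
        rightOv = if (i == length(tt) + 1L) ""
                  else substr(S, t0[i + 1L] + 1L, b0[i + 1L]),
        source = x@id)
    }
  } else {
    D <- paste0(S, S, substr(S, 1L, 9L))  # right cut window may pass 2L
    k <- length(tt)
    for (i in seq_len(k)) {
      t1 <- tt[i]
      j <- if (i == k) 1L else i + 1L
      t2 <- if (i == k) tt[j] + L else tt[j]
      b1 <- bb[i]
      b2 <- if (i == k) bb[j] + L else bb[j]
      frs[[i]] <- gbFragment(
        seq = substr(D, t1 + 1L, t2),
        leftOv = substr(D, t1 + 1L, b1),
        rightOv = substr(D, t2 + 1L, b2),
        source = x@id)
    }
  }
  frs
})
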