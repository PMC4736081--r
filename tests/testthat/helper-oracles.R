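## shared fixtures and independent oracles for the test suite

.cfg <- gbConfig()
.bsai <- enzymeByName("BsaI", .cfg)
.bsmbi <- enzymeByName("BsmBI", .cfg)

rc <- function(s) gbcrispr::revcomp(s)

## random DNA free of the given motifs (independent of package internals)
randomCleanDNA <- function(n, motifs = character(0L), gc = 0.5) {
  repeat {
    s <- paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
                      prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
               collapse = "")
    all_motifs <- unique(c(motifs, rc(motifs)))
    if (!any(vapply(all_motifs, function(m) grepl(m, s, fixed = TRUE),
                    logical(1L))))
      return(s)
  }
}

## a random circular plasmid with k well-separated BsaI sites, all on the
## plus strand, with distinct non-palindromic overhang fills
randomBsaIPlasmid <- function(k = 2L, segLen = 60L) {
  fills <- c("ACCT", "TTGC", "CAGA", "GTTC", "AGAC", "TCTG", "CATC", "GACT")
  fills <- sample(fills, k)
  repeat {
    pieces <- vapply(seq_len(k), function(i)
      paste0("GGTCTC", "A", fills[i],
             randomCleanDNA(segLen, c("GGTCTC", "CGTCTC"))),
      character(1L))
    m <- DNAMolecule(paste0("rnd", sample.int(1e6, 1)),
                     paste(pieces, collapse = ""), "circular")
    ## junctions can create accidental (minus-strand) sites; insist on the
    ## designed geometry
    s <- findSites(m, .bsai)
    if (nrow(s) == k && all(s$strand == "+")) return(m)
  }
}

## brute-force SpCas9 target scan: every 20-mer + NGG on either strand,
## via an explicit sliding window over the sequence and its reverse
## complement (independent of the package's scanner)
oracleScan <- function(seqstr, require5G = TRUE) {
  L <- nchar(seqstr)
  rows <- list()
  grab <- function(s, i) substr(s, i, i + 22L)
  for (i in seq_len(max(0L, L - 22L))) {
    w <- grab(seqstr, i)
    if (substr(w, 22L, 23L) == "GG" &&
        (!require5G || substr(w, 1L, 1L) == "G"))
      rows[[length(rows) + 1L]] <- data.frame(
        start = i - 1L, strand = "+", protospacer = substr(w, 1L, 20L),
        pam = substr(w, 21L, 23L), stringsAsFactors = FALSE)
  }
  rcS <- rc(seqstr)
  for (i in seq_len(max(0L, L - 22L))) {
    w <- grab(rcS, i)
    if (substr(w, 22L, 23L) == "GG" &&
        (!require5G || substr(w, 1L, 1L) == "G"))
      rows[[length(rows) + 1L]] <- data.frame(
        start = L - (i - 1L) - 20L, strand = "-",
        protospacer = substr(w, 1L, 20L), pam = substr(w, 21L, 23L),
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(start = integer(0L), strand = character(0L),
                      protospacer = character(0L), pam = character(0L)))
  df <- do.call(rbind, rows)
  df[order(df$start, df$strand), , drop = FALSE]
}

## brute-force circular-ligation oracle: enumerate every subset, every
## arrangement (first element fixed, forward orientation) and every
## orientation of the remaining fragments; collect canonical sequences of
## closed chains
oracleCircularProducts <- function(fragments) {
  n <- length(fragments)
  nodes <- lapply(fragments, function(f)
    list(F = list(seq = f@seq, L = f@leftOv, R = f@rightOv),
         R = local({
           g <- gbcrispr:::.flipFragment(f)
           list(seq = g@seq, L = g@leftOv, R = g@rightOv)
         })))
  canon <- gbcrispr:::.canonicalCircular
  found <- character(0L)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  subsets <- function(v) {
    if (!length(v)) return(list(integer(0L)))
    rest <- subsets(v[-1L])
    c(rest, lapply(rest, function(s) c(v[1L], s)))
  }
  for (S in subsets(seq_len(n))) {
    m <- length(S)
    if (m == 0L) next
    anchor <- S[1L]
    others <- S[-1L]
    for (p in perms(others)) {
      ords <- c(anchor, p)
      oriGrid <- if (m == 1L) list(logical(1L)) else
        lapply(seq_len(2L^(m - 1L)) - 1L, function(b)
          c(FALSE, as.logical(bitwAnd(rep(b, m - 1L),
                                      2L^(seq_len(m - 1L) - 1L)) > 0L)))
      for (flips in oriGrid) {
        chain <- lapply(seq_len(m), function(j)
          if (flips[j]) nodes[[ords[j]]]$R else nodes[[ords[j]]]$F)
        ok <- TRUE
        for (j in seq_len(m)) {
          a <- chain[[j]]
          b <- chain[[if (j == m) 1L else j + 1L]]
          if (nchar(a$R) == 0L || a$R != b$L) { ok <- FALSE; break }
        }
        if (ok)
          found <- c(found, canon(paste(vapply(chain, `[[`, "", "seq"),
                                        collapse = "")))
      }
    }
  }
  sort(unique(found))
}
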