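#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors (alphabet
#' `A C G T N`, case preserved per IUPAC complement of the upper-cased base).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @examples
#' revcomp("GGTCTC")
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (is.na(s) || nchar(s) == 0L) return(s)
    paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "",
                       fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' GC content of a DNA string, in percent
#'
#' @param x character vector of DNA sequences.
#' @return numeric vector, `100 * (#G + #C) / length`.
#' @examples
#' gcContent("GATTACGTAATACAAAGCTT")  # 30
#' @export
gcContent <- function(x) {
  vapply(x, function(s) {
    s <- toupper(s)
    n <- nchar(s)
    if (n == 0L) return(NA_real_)
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    100 * sum(ch == "G" | ch == "C") / n
  }, numeric(1L), USE.NAMES = FALSE)
}

## rotate a string left by `i` characters (0 <= i < nchar)
.rotate <- function(s, i) {
  n <- nchar(s)
  if (n == 0L || i %% n == 0L) return(s)
  i <- i %% n
  paste0(substr(s, i + 1L, n), substr(s, 1L, i))
}

## 0-based index of the lexicographically minimal rotation.
## Candidate-refinement: keep all start positions that are minimal at the
## current comparison depth; ties collapse quickly on non-repetitive DNA.
.minRotationIndex <- function(s) {
  n <- nchar(s)
  if (n <= 1L) return(0L)
  ch <- strsplit(paste0(s, s), "", fixed = TRUE)[[1L]]
  head <- ch[seq_len(n)]
  cand <- which(head == min(head))
  depth <- 1L
  while (length(cand) > 1L && depth < n) {
    nxt <- ch[cand + depth]
    cand <- cand[nxt == min(nxt)]
    depth <- depth + 1L
  }
  cand[1L] - 1L
}

## canonical representation of a circular sequence: the lexicographically
## smaller of the minimal rotations of the sequence and its reverse complement
.canonicalCircular <- function(s) {
  s <- toupper(s)
  a <- .rotate(s, .minRotationIndex(s))
  rc <- revcomp(s)
  b <- .rotate(rc, .minRotationIndex(rc))
  if (a <= b) a else b
}

## canonical representation of a linear duplex (strand-insensitive)
.canonicalLinear <- function(s) {
  s <- toupper(s)
  rc <- revcomp(s)
  if (s <= rc) s else rc
}

## all 0-based start offsets of `pattern` on the given string; for circular
## subjects matches may wrap the origin (reported start always in [0, L))
.matchStarts <- function(seqstr, pattern, circular = FALSE) {
  k <- nchar(pattern)
  L <- nchar(seqstr)
  if (k == 0L || L == 0L || (!circular && k > L)) return(integer(0L))
  subject <- if (circular && k > 1L) {
    paste0(seqstr, substr(seqstr, 1L, k - 1L))
  } else {
    seqstr
  }
  n <- nchar(subject) - k + 1L
  if (n < 1L) return(integer(0L))
  starts <- seq_len(n)
  hits <- starts[substring(subject, starts, starts + k - 1L) == pattern]
  hits - 1L
}

## deterministic random DNA of length n with target GC fraction
.randomDNA <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

## remove every occurrence of the given recognition motifs (both strands) by
## toggling the middle base; iterates until clean, deterministically
.scrubMotifs <- function(s, motifs) {
  motifs <- unique(c(toupper(motifs), revcomp(toupper(motifs))))
  cycle <- c(A = "C", C = "G", G = "T", T = "A", N = "A")
  for (iter in seq_len(200L)) {
    hit <- FALSE
    for (m in motifs) {
      p <- .matchStarts(s, m)
      if (length(p)) {
        hit <- TRUE
        mid <- p[1L] + (nchar(m) %/% 2L)  # 0-based offset of middle base
        base <- substr(s, mid + 1L, mid + 1L)
        substr(s, mid + 1L, mid + 1L) <- unname(cycle[base])
      }
    }
    if (!hit) return(s)
  }
  stop("could not scrub recognition motifs from sequence")
}

## run code under a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

## validation / assembly error helpers (CLI maps these to exit codes 2 / 3)
.gbValidationError <- function(msg) {
  stop(structure(class = c("gb_validation_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1L))))
}
.gbAssemblyError <- function(msg) {
  stop(structure(class = c("gb_assembly_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1L))))
}
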