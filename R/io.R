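#' @include fixtures.R
NULL

#' Read molecules from FASTA
#'
#' FASTA carries no topology, so molecules default to linear; set
#' `topology = "circular"` to override (a `[circular]` token in the header
#' is also honoured).
#'
#' @param path FASTA file.
#' @param topology default topology for records without a `[circular]`
#'   header token.
#' @return list of [DNAMolecule-class].
#' @export
readFastaMol <- function(path, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  set <- Biostrings::readDNAStringSet(path)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    header <- names(set)[i]
    circ <- grepl("\\[circular\\]", header)
    id <- sub("\\s.*$", "", header)
    out[[i]] <- DNAMolecule(id, as.character(set[[i]]),
                            if (circ) "circular" else topology)
  }
  out
}

#' Write molecules to FASTA
#'
#' Circular molecules get a `[circular]` token appended to their header so a
#' round trip preserves topology.
#'
#' @param mols a [DNAMolecule-class] or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFastaMol <- function(mols, path) {
  if (is(mols, "DNAMolecule")) mols <- list(mols)
  set <- Biostrings::DNAStringSet(vapply(mols, function(m) m@seq,
                                         character(1L)))
  names(set) <- vapply(mols, function(m)
    paste0(m@id, if (m@topology == "circular") " [circular]" else ""),
    character(1L))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a molecule as an annotated GenBank flat file
#'
#' Minimal writer: LOCUS line (with the circular flag), `misc_feature`
#' entries for every annotation, and the ORIGIN sequence block.
#'
#' @param mol a [DNAMolecule-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenBank <- function(mol, path) {
  stopifnot(is(mol, "DNAMolecule"))
  L <- nchar(mol@seq)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %-17s %d bp    DNA     %-8s SYN %s",
                     substr(mol@id, 1L, 17L), L,
                     ifelse(mol@topology == "circular", "circular",
                            "linear"),
                     toupper(format(Sys.Date(), "%d-%b-%Y"))), con)
  writeLines(sprintf("DEFINITION  %s.", mol@id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  ann <- mol@annotations
  if (nrow(ann)) {
    for (i in seq_len(nrow(ann))) {
      loc <- sprintf("%d..%d", ann$start[i] + 1L, ann$end[i])
      if (identical(ann$strand[i], "-"))
        loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     misc_feature    %s", loc), con)
      writeLines(sprintf("                     /label=\"%s\"", ann$label[i]),
                 con)
    }
  }
  writeLines("ORIGIN", con)
  s <- tolower(mol@seq)
  for (start in seq(1L, L, by = 60L)) {
    chunk <- substr(s, start, min(start + 59L, L))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L),
                             nchar(chunk)))
    writeLines(sprintf("%9d %s", start, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read a GenBank flat file
#'
#' Minimal reader for files written by [writeGenBank()] and similarly plain
#' GenBank records: topology from the LOCUS line, simple
#' `start..end` / `complement(start..end)` feature locations with `/label`
#' qualifiers, sequence from ORIGIN.
#'
#' @param path GenBank file.
#' @return a [DNAMolecule-class].
#' @export
readGenBank <- function(path) {
  lines <- readLines(path)
  locus <- lines[grepl("^LOCUS", lines)][1L]
  if (is.na(locus)) .gbValidationError("not a GenBank file: no LOCUS line")
  toks <- strsplit(trimws(locus), "\\s+")[[1L]]
  id <- toks[2L]
  topo <- if (any(tolower(toks) == "circular")) "circular" else "linear"
  oi <- which(grepl("^ORIGIN", lines))[1L]
  if (is.na(oi)) .gbValidationError("no ORIGIN block")
  seqLines <- lines[(oi + 1L):length(lines)]
  seqLines <- seqLines[!grepl("^//", seqLines)]
  seqstr <- toupper(gsub("[^A-Za-z]", "", paste(seqLines, collapse = "")))

  ann <- .emptyAnnotations()
  fi <- which(grepl("^FEATURES", lines))
  if (length(fi)) {
    i <- fi[1L] + 1L
    while (i < oi) {
      ln <- lines[i]
      m <- regmatches(ln, regexec(
        "^\\s{2,}\\S+\\s+(complement\\()?(\\d+)\\.\\.(\\d+)\\)?", ln))[[1L]]
      if (length(m)) {
        start <- as.integer(m[3L]) - 1L
        end <- as.integer(m[4L])
        strand <- if (nchar(m[2L])) "-" else "+"
        label <- NA_character_
        if (i + 1L < oi) {
          lm <- regmatches(lines[i + 1L],
                           regexec("/label=\"([^\"]*)\"", lines[i + 1L]))[[1L]]
          if (length(lm)) label <- lm[2L]
        }
        ann <- rbind(ann, data.frame(label = label, start = start,
                                     end = end, strand = strand,
                                     stringsAsFactors = FALSE))
      }
      i <- i + 1L
    }
  }
  DNAMolecule(id, seqstr, topo, annotations = ann)
}

#' Emit an oligo order sheet for a duplex
#'
#' @param duplex an [OligoDuplex-class] (or list of them).
#' @param path output TSV path, or NULL to return the data.frame.
#' @param namePrefix oligo name prefix.
#' @return data.frame with columns `name`, `sequence_5to3` (written to
#'   `path` when given).
#' @export
oligoSheet <- function(duplex, path = NULL, namePrefix = "gRNA") {
  if (is(duplex, "OligoDuplex")) duplex <- list(duplex)
  rows <- do.call(rbind, lapply(seq_along(duplex), function(i) {
    d <- duplex[[i]]
    data.frame(name = paste0(namePrefix, "_", i, c("_F", "_R")),
               sequence_5to3 = c(d@fwdOligo, d@revOligo),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(path))
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  rows
}
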