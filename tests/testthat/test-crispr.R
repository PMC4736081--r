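test_that("target scanning applies the 5'-G and PAM rules", {
  g <- DNAMolecule("g", "GAAAAAAAAAAAAAAAAAAATGGT")
  hits <- scanTargets(g, require5primeG = TRUE, cfg = .cfg)
  expect_length(hits, 1L)
  expect_equal(protospacer(hits[[1]]), "GAAAAAAAAAAAAAAAAAAA")
  expect_equal(hits[[1]]@pam, "TGG")
  expect_equal(hits[[1]]@strand, "+")

  ## all-A/T genome: nothing can start with G
  at <- DNAMolecule("at", strrep("AT", 200))
  expect_length(scanTargets(at, require5primeG = TRUE, cfg = .cfg), 0L)

  ## minus-strand target: revcomp of the plus construct
  gm <- DNAMolecule("gm", revcomp("GAAAAAAAAAAAAAAAAAAATGGT"))
  hm <- scanTargets(gm, require5primeG = TRUE, cfg = .cfg)
  expect_length(hm, 1L)
  expect_equal(protospacer(hm[[1]]), "GAAAAAAAAAAAAAAAAAAA")
  expect_equal(hm[[1]]@strand, "-")
})

test_that("diagnostic sites must straddle the Cas9 cut", {
  ## SpeI ends at protospacer nt 20: span [14, 20) contains the cut at 17
  withSite <- paste0("TTTTT", "GCATGCCGTAAACGACTAGT", "TGG", "TTTTT")
  h1 <- scanTargets(DNAMolecule("a", withSite), enzymePanel = list("SpeI"),
                    cfg = .cfg)
  expect_length(h1, 1L)
  expect_equal(unique(diagnosticSites(h1[[1]])$enzyme), "SpeI")

  ## same site fully 5' of the cut: [5, 11) does not contain 17
  early <- paste0("TTTTT", "GCATGACTAGTCCGTAAACG", "TGG", "TTTTT")
  h2 <- scanTargets(DNAMolecule("b", early), enzymePanel = list("SpeI"),
                    cfg = .cfg)
  expect_length(h2, 1L)
  expect_equal(nrow(diagnosticSites(h2[[1]])), 0L)
})

test_that("scanning matches a brute-force 20-mer + NGG sweep", {
  fx <- fixtureConfig(seed = 13L, nGenes = 4L)
  gen <- makeGenome(fx, planted = data.frame(
    gene = c("gene1", "gene3"), protospacer = NA_character_,
    diag = c("SpeI", NA), stringsAsFactors = FALSE), cfg = .cfg)
  got <- targetTable(scanTargets(gen$genome, require5primeG = TRUE,
                                 cfg = .cfg))
  want <- oracleScan(molSeq(gen$genome), require5G = TRUE)
  expect_equal(got$start, want$start)
  expect_equal(got$strand, want$strand)
  expect_equal(got$protospacer, want$protospacer)
  expect_equal(got$pam, want$pam)
  ## 100% planted-target recall
  expect_true(all(gen$truth$protospacer %in% got$protospacer))
})

test_that("the domesticator designs annealing-consistent oligo duplexes", {
  d <- domesticateTarget("GCATGCCGTAAACGACTAGT", "monocistronic_D",
                         cfg = .cfg)
  expect_equal(d@leftFusion, .cfg$target_modes$monocistronic_D$left)
  expect_equal(d@rightFusion, .cfg$target_modes$monocistronic_D$right)
  ## annealing: fwd and rev oligos share the 20-nt duplex core and leave
  ## 4-nt 5' protrusions at both ends
  expect_equal(substring(d@fwdOligo, 5L), d@protospacer)
  expect_equal(substring(d@revOligo, 5L), revcomp(d@protospacer))
  frag <- duplexFragment(d)
  flip <- gbcrispr:::.flipFragment(frag)
  expect_equal(flip@seq, d@revOligo)

  ## M mode differs only in the right fusion site
  m <- domesticateTarget("GCATGCCGTAAACGACTAGT", "monocistronic_M",
                         cfg = .cfg)
  expect_equal(m@leftFusion, d@leftFusion)
  expect_false(m@rightFusion == d@rightFusion)

  ## 5' policy
  expect_error(domesticateTarget("ACATGCCGTAAACGACTAGT", "monocistronic_D",
                                 policy5G = "reject", cfg = .cfg),
               "must start with G")
  sub <- domesticateTarget("ACATGCCGTAAACGACTAGT", "monocistronic_D",
                           policy5G = "substitute", cfg = .cfg)
  expect_true(sub@substituted5G)
  expect_equal(substr(sub@protospacer, 1L, 1L), "G")

  ## internal assembly-enzyme site is rejected with its offset
  expect_error(domesticateTarget(paste0("G", "GGTCTC", "AAAAAAAAAAAAA"),
                                 "monocistronic_D", cfg = .cfg),
               "site")
})

test_that("cassette assembly preserves the designed protospacer losslessly", {
  fx <- fixtureConfig(seed = 17L)
  prom <- makePromoterPart(fx, .cfg)
  scaf <- makeScaffoldPart(fx, cfg = .cfg)
  alpha1 <- makeVector("alpha", 1L, fx, cfg = .cfg)
  proto <- "GTTTACCGGATAACTTTACA"
  dup <- domesticateTarget(proto, "monocistronic_D", cfg = .cfg)
  cass <- assembleGuideCassette(prom, dup, scaf, alpha1, partId = "cass",
                                cfg = .cfg)
  ## re-extract the protospacer between promoter and scaffold
  dd <- paste0(molSeq(partMolecule(cass)), molSeq(partMolecule(cass)))
  ref <- if (grepl(prom@insert, dd, fixed = TRUE)) dd else revcomp(dd)
  m <- regexpr(paste0(prom@insert, dup@leftFusion), ref, fixed = TRUE)
  expect_true(m > 0L)
  got <- substr(ref, m + nchar(prom@insert) + 4L,
                m + nchar(prom@insert) + 23L)
  expect_equal(got, proto)

  ## swapped oligos (reversed overhangs) cannot assemble
  swapped <- gbFragment(paste0(dup@rightFusion, revcomp(proto)),
                        leftOv = dup@rightFusion,
                        rightOv = dup@leftFusion)
  expect_error(goldenGate(list(prom, scaf), alpha1, "BsaI",
                          extraFragments = list(swapped), cfg = .cfg),
               "assembly failure")

  ## two distinct cassettes combine into a 2-gRNA binary construct
  proto2 <- "GACCTTAGACGGATTCTTCA"
  dup2 <- domesticateTarget(proto2, "monocistronic_D", cfg = .cfg)
  alpha2 <- makeVector("alpha", 2L, fx, cfg = .cfg)
  cass2 <- assembleGuideCassette(prom, dup2, scaf, alpha2, partId = "cass2",
                                 cfg = .cfg)
  omega1 <- makeVector("omega", 1L, fx, cfg = .cfg)
  two <- binaryAssemble(cass, cass2, omega1, partId = "two", cfg = .cfg)
  dd2 <- paste0(molSeq(partMolecule(two)), molSeq(partMolecule(two)))
  expect_true(grepl(proto, dd2, fixed = TRUE))
  expect_true(grepl(proto2, dd2, fixed = TRUE))
})

test_that("polycistrons carry every guide in slot order", {
  fx <- fixtureConfig(seed = 19L)
  prom <- makePromoterPart(fx, .cfg)
  alpha1 <- makeVector("alpha", 1L, fx, cfg = .cfg)
  protos <- c("GCATGCCGTAAACGACTAGT", "GATTACGTAATACAAAGCTT",
              "GTTTACCGGATAACTTTACA")
  for (n in 2:3) {
    des <- polycistronDesign(protos[seq_len(n)], promoter = prom,
                             slotParts = lapply(seq_len(n), makeSlotPart,
                                                nSlots = n, fx = fx,
                                                cfg = .cfg))
    poly <- buildPolycistron(des, alpha1, partId = paste0("poly", n),
                             cfg = .cfg)
    seqd <- paste0(molSeq(partMolecule(poly)), molSeq(partMolecule(poly)))
    ref <- if (grepl(prom@insert, seqd, fixed = TRUE)) seqd
           else revcomp(seqd)
    at <- regexpr(prom@insert, ref, fixed = TRUE)
    win <- substr(ref, at, at + molLength(partMolecule(poly)) - 1L)
    pos <- vapply(protos[seq_len(n)], function(p)
      as.integer(regexpr(p, win, fixed = TRUE)), integer(1L),
      USE.NAMES = FALSE)
    expect_true(all(pos > 0L))
    expect_false(is.unsorted(pos, strictly = TRUE))
    ## n tRNA units ride along
    trnaCount <- length(gregexpr(.cfg$sequences$trna, win,
                                 fixed = TRUE)[[1L]])
    expect_equal(trnaCount, n)
  }
  ## n = 1 goes through the monocistronic path instead
  expect_error(polycistronDesign(protos[1L], promoter = prom,
                                 slotParts = list()),
               "at least 2 targets")
})
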