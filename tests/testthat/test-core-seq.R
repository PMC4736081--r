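test_that("site scanning finds Type IIS sites with correct cut geometry", {
  expect_equal(nrow(findSites(DNAMolecule("m", "AAAA"), .bsai)), 0L)

  hit <- findSites(DNAMolecule("m", "TTTGGTCTCAACCTCCCGGG"), .bsai)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$rec_start, 3L)
  expect_equal(hit$cut_top, 10L)
  expect_equal(hit$cut_bottom, 14L)

  ## minus-strand site: revcomp of a plus-strand construct
  m2 <- DNAMolecule("m2", revcomp("TTTGGTCTCAACCTCCCGGG"))
  hit2 <- findSites(m2, .bsai)
  expect_equal(hit2$strand, "-")
  expect_equal(hit2$cut_bottom - hit2$cut_top, 4L)
  ## the cut window mirrors: plus cut [10,14) maps to [20-14, 20-10)
  expect_equal(hit2$cut_top, 6L)

  ## recognition split across the origin of a circular molecule
  circ <- DNAMolecule("c", "TCTCAAAAAAAAGG", "circular")
  hc <- findSites(circ, .bsai)
  expect_equal(nrow(hc), 1L)
  expect_equal(hc$rec_start, 12L)
  expect_equal(hc$cut_top, (12L + 7L) %% 14L)
})

test_that("digestion produces sticky fragments that conserve sequence", {
  frs <- digest(DNAMolecule("m", "TTTGGTCTCAACCTCCCGGG"), .bsai)
  expect_length(frs, 2L)
  expect_equal(frs[[1]]@seq, "TTTGGTCTCA")
  expect_equal(frs[[1]]@leftOv, "")
  expect_equal(frs[[1]]@rightOv, "ACCT")  # bottom strand protrudes as its complement
  expect_equal(frs[[2]]@leftOv, "ACCT")
  expect_equal(frs[[2]]@seq, "ACCTCCCGGG")

  ## circular, no site: error-free uncut marker
  un <- digest(DNAMolecule("c", "ACGTACGTAA", "circular"), .bsai)
  expect_length(un, 0L)
  expect_true(attr(un, "uncut"))

  ## circular with k sites -> k fragments, lengths sum to molecule length
  set.seed(11)
  for (k in c(1L, 2L, 3L)) {
    p <- randomBsaIPlasmid(k)
    frs <- digest(p, .bsai)
    expect_length(frs, k)
    expect_equal(sum(vapply(frs, function(f) nchar(f@seq), integer(1L))),
                 molLength(p))
  }

  ## linear k sites -> k + 1 fragments with blunt outer ends
  lin <- DNAMolecule("l", paste0("AAAA", "GGTCTCATTGC", strrep("AT", 10),
                                 "GGTCTCACCGA", strrep("GA", 10)))
  frsL <- digest(lin, .bsai)
  expect_length(frsL, 3L)
  expect_equal(frsL[[1]]@leftOv, "")
  expect_equal(frsL[[3]]@rightOv, "")
  expect_equal(sum(vapply(frsL, function(f) nchar(f@seq), integer(1L))),
               molLength(lin))
})

test_that("overlapping cut windows raise an ambiguous-digest error", {
  expect_error(digest(DNAMolecule("m", "GGTCTCATTGAGACC"), .bsai),
               "ambiguous digest")
})

test_that("ligation rebuilds circular molecules and rejects mismatches", {
  set.seed(21)
  p <- randomBsaIPlasmid(3L)
  prods <- ligate(digest(p, .bsai))
  expect_true(any(vapply(prods, sameMolecule, logical(1L), b = p)))

  ## non-matching overhangs: no circular product
  f1 <- gbFragment("ACCTGGGGG", leftOv = "ACCT", rightOv = "TTGC")
  f2 <- gbFragment("CAGACCCCC", leftOv = "CAGA", rightOv = "GTTC")
  expect_length(ligate(list(f1, f2)), 0L)

  ## designed 4-fragment cycle plus a decoy: exactly the designed circle,
  ## matching the brute-force ordering oracle
  ovs <- c("ACCT", "TTGC", "CAGA", "GTTC")
  chain <- lapply(1:4, function(i)
    gbFragment(paste0(ovs[i], randomCleanDNA(15)), leftOv = ovs[i],
               rightOv = ovs[if (i == 4L) 1L else i + 1L]))
  decoy <- gbFragment("TCTGAAAAAAAA", leftOv = "TCTG", rightOv = "CATC")
  prods <- ligate(c(chain, list(decoy)))
  expect_length(prods, 1L)
  expect_false(grepl("TCTGAAAAAAAA", paste0(molSeq(prods[[1]]),
                                            molSeq(prods[[1]])),
                     fixed = TRUE))
  expect_equal(vapply(prods, molSeq, character(1L)),
               oracleCircularProducts(c(chain, list(decoy))),
               ignore_attr = TRUE)
})

test_that("palindromic overhangs are permitted with a self-ligation warning", {
  f <- gbFragment("GATCAAAA", leftOv = "GATC", rightOv = "GATC")
  expect_warning(ligate(list(f)), "palindromic")
})

test_that("golden gate returns only stable, recognition-free products", {
  fx <- fixtureConfig(seed = 3L)
  prom <- makePromoterPart(fx, .cfg)
  scaf <- makeScaffoldPart(fx, cfg = .cfg)
  alpha1 <- makeVector("alpha", 1L, fx, cfg = .cfg)
  dup <- domesticateTarget("GCATGCCGTAAACGACTAGT", "monocistronic_D",
                           cfg = .cfg)
  res <- goldenGate(list(prom, scaf), alpha1, "BsaI",
                    extraFragments = list(duplexFragment(dup)), cfg = .cfg)
  expect_length(products(res), 1L)
  prod <- backboneProduct(res)
  expect_false(is.null(prod))
  ## no assembly-enzyme recognition remains on either strand
  dd <- paste0(molSeq(prod), molSeq(prod))
  expect_false(grepl("GGTCTC", dd, fixed = TRUE))
  expect_false(grepl("GGTCTC", revcomp(dd), fixed = TRUE))
  ## product length: backbone + released cargos + duplex (conservation)
  bsaiFree <- function(f) !grepl("GGTCTC", f@seq, fixed = TRUE) &&
    !grepl(revcomp("GGTCTC"), f@seq, fixed = TRUE)
  cargo <- function(m) Filter(bsaiFree, digest(m, .bsai))[[1]]
  expLen <- sum(nchar(c(cargo(partMolecule(prom))@seq,
                        cargo(partMolecule(scaf))@seq,
                        cargo(vectorMolecule(alpha1))@seq))) +
    nchar(duplexFragment(dup)@seq)
  expect_equal(molLength(prod), expLen)

  ## broken chain (scaffold omitted) -> assembly failure
  expect_error(goldenGate(list(prom), alpha1, "BsaI",
                          extraFragments = list(duplexFragment(dup)),
                          cfg = .cfg),
               "assembly failure")

  ## a fragment retaining an internal recognition site never enters a
  ## stable product
  bad <- gbFragment(paste0("ATTG", "GGTCTCA", randomCleanDNA(10)),
                    leftOv = "ATTG", rightOv = "GCTT")
  expect_error(goldenGate(list(prom, scaf), alpha1, "BsaI",
                          extraFragments = list(bad), cfg = .cfg),
               "assembly failure")
})

test_that("golden gate products match the brute-force ordering oracle", {
  set.seed(31)
  for (case in 1:20) {
    k <- sample(3:5, 1L)
    p <- randomBsaIPlasmid(k, segLen = 30L)
    frs <- digest(p, .bsai)
    ## add a decoy fragment in half the cases
    if (case %% 2L == 0L)
      frs <- c(frs, list(gbFragment(paste0("GACT", randomCleanDNA(12)),
                                    leftOv = "GACT", rightOv = "CATC")))
    got <- sort(vapply(ligate(frs), molSeq, character(1L)))
    expect_equal(got, oracleCircularProducts(frs), ignore_attr = TRUE)
  }
})

test_that("rotation-invariant equality recognises rotated and flipped circles", {
  s <- "GATTACAGGCCTTA"
  a <- DNAMolecule("a", s, "circular")
  expect_true(sameMolecule(a, DNAMolecule("b", gbcrispr:::.rotate(s, 5L),
                                          "circular")))
  expect_true(sameMolecule(a, DNAMolecule("c", revcomp(gbcrispr:::.rotate(s, 9L)),
                                          "circular")))
  expect_false(sameMolecule(a, DNAMolecule("d", "GATTACAGGCCTAA", "circular")))
})
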