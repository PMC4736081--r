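test_that("domestication check reports internal sites on both strands", {
  expect_equal(nrow(checkDomestication("ATGCATGC", cfg = .cfg)), 0L)

  v1 <- checkDomestication(paste0("AAA", "GGTCTC", "TTT"), cfg = .cfg)
  expect_equal(nrow(v1), 1L)
  expect_equal(v1$enzyme, "BsaI")
  expect_equal(v1$strand, "+")
  expect_equal(v1$offset, 3L)

  v2 <- checkDomestication(paste0("AA", revcomp("CGTCTC"), "TT"), cfg = .cfg)
  expect_equal(nrow(v2), 1L)
  expect_equal(v2$enzyme, "BsmBI")
  expect_equal(v2$strand, "-")
  expect_equal(v2$offset, 2L)
})

test_that("level 0 cloning round-trips through the entry vector", {
  fx <- fixtureConfig(seed = 5L)
  entry <- makeVector("entry", fx = fx, cfg = .cfg)
  set.seed(52)
  insert <- randomCleanDNA(60L, c("GGTCTC", "CGTCTC"))
  part <- makeLevel0(insert, syntaxCodes = c("B3", "B4", "B5"),
                     entryVector = entry, partId = "GBtest", cfg = .cfg)
  expect_s4_class(part, "GBPart")
  expect_equal(partLevel(part), "level0")
  ## BsaI release regenerates exactly fusionL + insert (+ fusionR socket)
  frs <- digest(partMolecule(part), .bsai)
  cargo <- Filter(function(f)
    !grepl("GGTCTC", f@seq, fixed = TRUE) &&
      !grepl(revcomp("GGTCTC"), f@seq, fixed = TRUE), frs)
  expect_length(cargo, 1L)
  expect_equal(cargo[[1]]@seq, paste0("AATG", insert))
  expect_equal(cargo[[1]]@leftOv, "AATG")
  expect_equal(cargo[[1]]@rightOv, "GCTT")
  ## the stored plasmid is BsmBI-free (stable entry product)
  expect_equal(nrow(findSites(partMolecule(part), .bsmbi)), 0L)

  expect_error(makeLevel0(paste0("AAA", "GGTCTC", "AAA"),
                          syntaxCodes = c("B3", "B4", "B5"),
                          entryVector = entry, cfg = .cfg),
               "not domesticated")
  expect_error(makeLevel0("", syntaxCodes = "B3", entryVector = entry,
                          cfg = .cfg),
               "empty insert")
})

test_that("binary braid assembly alternates vector class and stays composable", {
  fx <- fixtureConfig(seed = 7L)
  alpha1 <- makeVector("alpha", 1L, fx, cfg = .cfg)
  alpha2 <- makeVector("alpha", 2L, fx, cfg = .cfg)
  omega1 <- makeVector("omega", 1L, fx, cfg = .cfg)
  omega2 <- makeVector("omega", 2L, fx, cfg = .cfg)

  tuA <- makeCas9TU(alpha1, fx, .cfg)
  tuB <- makeMarkerTU(alpha2, fx, .cfg)

  lvl2 <- binaryAssemble(tuA, tuB, omega1, partId = "lvl2", cfg = .cfg)
  expect_equal(vectorClass(lvl2), "omega")
  expect_equal(partLevel(lvl2), "level1plus")
  ## length = destination backbone + both released cargos
  bsmbiFree <- function(f) !grepl("CGTCTC", f@seq, fixed = TRUE) &&
    !grepl(revcomp("CGTCTC"), f@seq, fixed = TRUE)
  cargoLen <- function(m, enz) {
    nchar(Filter(function(f)
      !grepl(enz@recognition, f@seq, fixed = TRUE) &&
        !grepl(revcomp(enz@recognition), f@seq, fixed = TRUE),
      digest(m, enz))[[1]]@seq)
  }
  expLen <- cargoLen(partMolecule(tuA), .bsmbi) +
    cargoLen(partMolecule(tuB), .bsmbi) +
    cargoLen(vectorMolecule(omega1), .bsmbi)
  expect_equal(molLength(partMolecule(lvl2)), expLen)

  ## same-class destination is a braid violation
  expect_error(binaryAssemble(tuA, tuB, alpha1, cfg = .cfg),
               "braid violation")
  ## same-position inputs cannot combine
  expect_error(binaryAssemble(tuA, tuA, omega1, cfg = .cfg),
               "complementary braid positions")

  ## depth-4 alternating chain: every product re-enters the loop
  lvl2b <- binaryAssemble(tuA, tuB, omega2, partId = "lvl2b", cfg = .cfg)
  lvl3 <- binaryAssemble(lvl2, lvl2b, alpha1, partId = "lvl3", cfg = .cfg)
  expect_equal(vectorClass(lvl3), "alpha")
  lvl3b <- binaryAssemble(lvl2, lvl2b, alpha2, partId = "lvl3b", cfg = .cfg)
  lvl4 <- binaryAssemble(lvl3, lvl3b, omega1, partId = "lvl4", cfg = .cfg)
  expect_equal(vectorClass(lvl4), "omega")
  ## each step flips the class of its inputs
  expect_false(vectorClass(lvl2) == vectorClass(tuA))
  expect_false(vectorClass(lvl3) == vectorClass(lvl2))
  expect_false(vectorClass(lvl4) == vectorClass(lvl3))
})

test_that("adjacent parts in an assembled unit chain through shared fusion sites", {
  fx <- fixtureConfig(seed = 9L)
  prom <- makePromoterPart(fx, .cfg)
  scaf <- makeScaffoldPart(fx, cfg = .cfg)
  dup <- domesticateTarget("GTTTACCGGATAACTTTACA", "monocistronic_D",
                           cfg = .cfg)
  ## the fusion chain closes: promoter right = duplex left, duplex right =
  ## scaffold left, and the TU edges meet the alpha sockets
  expect_equal(prom@fusions[2L], dup@leftFusion)
  expect_equal(dup@rightFusion, scaf@fusions[1L])
  alpha1 <- makeVector("alpha", 1L, fx, cfg = .cfg)
  expect_equal(c(prom@fusions[1L], scaf@fusions[2L]), alpha1@sockets)
  ## internal fusion sites are pairwise distinct
  sites <- c(prom@fusions, dup@rightFusion, scaf@fusions[2L])
  expect_equal(anyDuplicated(sites), 0L)
})
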