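## circular fixture mirroring a two-site band pattern: total length and
## inter-site distance chosen to give bands 6674 and 1401
makeTwoSitePlasmid <- function(enzRec = "GGATCC", total = 8075L,
                               gap = 1401L) {
  seg1 <- randomCleanDNA(gap - nchar(enzRec), enzRec)
  seg2 <- randomCleanDNA(total - gap - nchar(enzRec), enzRec)
  DNAMolecule("clone", paste0(enzRec, seg1, enzRec, seg2), "circular")
}

test_that("band prediction reproduces expected restriction patterns", {
  set.seed(41)
  pat <- predictBands(makeTwoSitePlasmid(), "BamHI", cfg = .cfg)
  expect_equal(bands(pat), c(6674L, 1401L))
  expect_false(isUncut(pat))

  ## circular without a site: uncut
  un <- predictBands(DNAMolecule("c", randomCleanDNA(300L, "GAATTC"),
                                 "circular"), "EcoRI", cfg = .cfg)
  expect_true(isUncut(un))
  expect_length(bands(un), 0L)

  ## linear 100 bp with one cut at offset 40: bands 60 and 40
  lin <- DNAMolecule("l", paste0(randomCleanDNA(39L, "GGATCC"), "GGATCC",
                                 randomCleanDNA(55L, "GGATCC")))
  expect_equal(bands(predictBands(lin, "BamHI", cfg = .cfg)), c(60L, 40L))
})

test_that("band lengths always sum to the molecule length when cut", {
  set.seed(43)
  enzymes <- c("BamHI", "EcoRI", "HindIII", "SpeI", "BsaI")
  for (i in 1:40) {
    topo <- sample(c("linear", "circular"), 1L)
    m <- DNAMolecule("r", paste(sample(c("A", "C", "G", "T"), 600,
                                       replace = TRUE), collapse = ""),
                     topo)
    for (e in enzymes) {
      pat <- tryCatch(predictBands(m, e, cfg = .cfg),
                      error = function(cond) NULL)  # ambiguous digests skipped
      if (is.null(pat) || isUncut(pat)) next
      expect_equal(sum(bands(pat)), molLength(m))
      nsites <- nrow(unique(findSites(m, enzymeByName(e, .cfg))[
        c("cut_top", "cut_bottom")]))
      expect_length(bands(pat),
                    if (topo == "circular") max(nsites, 0L) else nsites + 1L)
    }
  }
})

test_that("re-detection assay picks a unique cut-overlapping enzyme", {
  set.seed(47)
  proto <- "GCATGCCGTAAACGACTAGT"   # SpeI across the cut
  left <- randomCleanDNA(300L, c("ACTAGT", "GGATCC", proto))
  right <- randomCleanDNA(277L, c("ACTAGT", "GGATCC", proto))
  amp <- DNAMolecule("amp", paste0(left, proto, "TGG", right))
  target <- scanTargets(amp, enzymePanel = list("SpeI"), cfg = .cfg)
  target <- target[[which(vapply(target, protospacer,
                                 character(1L)) == proto)]]

  res <- designRedetectionAssay(target, amp, panel = list("SpeI", "BamHI"),
                                cfg = .cfg)
  expect_equal(res$enzyme, "SpeI")
  expect_length(res$wildtype_bands, 2L)
  expect_equal(sum(res$wildtype_bands), molLength(amp))
  expect_equal(res$mutant_bands, molLength(amp))
  expect_true("BamHI" %in% res$excluded$enzyme)

  ## a second site elsewhere disqualifies the enzyme
  amp2 <- DNAMolecule("amp2", paste0(left, proto, "TGG", "ACTAGT", right))
  expect_message(res2 <- designRedetectionAssay(target, amp2,
                                                panel = list("SpeI"),
                                                cfg = .cfg),
                 "no diagnostic assay")
  expect_true(is.na(res2$enzyme))
  expect_equal(res2$excluded$reason[res2$excluded$enzyme == "SpeI"],
               "more than one site in amplicon")

  ## empty panel: advisory only
  expect_message(res3 <- designRedetectionAssay(target, amp, panel = list(),
                                                cfg = .cfg),
                 "no diagnostic assay")
  expect_true(is.na(res3$enzyme))
})

test_that("mutation-rate correction is exact, monotone and linear", {
  expect_identical(correctedMutationRate(17, 0.29), 12.1)
  expect_identical(correctedMutationRate(14.5, 0.32), 9.9)
  expect_equal(correctedMutationRate(42.5, 0), 42.5)
  expect_equal(correctedMutationRate(42.5, 1), 0)
  ## corrected never exceeds raw; monotone decreasing in the wild-type
  ## fraction, linear in the raw rate
  set.seed(53)
  raw <- runif(50, 0, 100)
  wt <- runif(50)
  expect_true(all(correctedMutationRate(raw, wt) <= raw + 1e-9))
  w <- sort(runif(10))
  expect_false(is.unsorted(rev(correctedMutationRate(80, w))))
  expect_equal(correctedMutationRate(2 * 30, 0.5),
               2 * (30 * 0.5), tolerance = 0.01)
  expect_error(correctedMutationRate(120, 0.2), "rawPct")
  expect_error(correctedMutationRate(20, 1.2), "wtCloneFrac")
})

test_that("reporter normalization sets the reference to 1 and recovers effects", {
  df <- data.frame(condition = rep(c("REF", "a", "b"), each = 3L),
                   fluc = c(100, 101, 99, 50, 50, 50, 325, 325, 325),
                   rluc = 100)
  res <- normalizeReporter(df, "REF")
  expect_equal(res$summary$mean_normalized[res$summary$condition == "REF"],
               1, tolerance = 1e-12)
  ## noiseless 0.5x and 3.25x conditions span a 6.5-fold induction range
  df2 <- data.frame(condition = rep(c("REF", "low", "high"), each = 3L),
                    fluc = c(100, 100, 100, 50, 50, 50, 325, 325, 325),
                    rluc = 100)
  res2 <- normalizeReporter(df2, "REF")
  expect_equal(res2$induction_range, 6.5)

  ## scale invariance in Fluc
  df3 <- df2
  df3$fluc <- df3$fluc * 17.3
  res3 <- normalizeReporter(df3, "REF")
  expect_equal(res3$summary$mean_normalized, res2$summary$mean_normalized)

  ## noisy triplicates: recovered means within 3 SD of the truth
  set.seed(59)
  truth <- c(REF = 1, r1 = 0.4, r2 = 2.5)
  noisy <- do.call(rbind, lapply(names(truth), function(cond)
    data.frame(condition = cond,
               fluc = 1000 * truth[[cond]] * exp(rnorm(3, 0, 0.1)),
               rluc = 1000)))
  resN <- normalizeReporter(noisy, "REF")
  for (cond in c("r1", "r2")) {
    row <- resN$summary[resN$summary$condition == cond, ]
    expect_lt(abs(row$mean_normalized - truth[[cond]]),
              3 * row$sd_normalized + 0.1)
  }

  expect_error(normalizeReporter(df2, "missing"), "reference")
  dfBad <- df2
  dfBad$rluc[1] <- 0
  expect_error(normalizeReporter(dfBad, "REF"), "Rluc")
})
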