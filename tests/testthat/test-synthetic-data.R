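test_that("reference generation honours length, determinism and gene context", {
  ref <- generateReference(1321, seed = 1)
  expect_equal(nchar(ref), 1321L)
  expect_identical(ref, generateReference(1321, seed = 1))
  expect_false(identical(ref, generateReference(1321, seed = 2)))
  expect_error(generateReference(100, seed = 1), "coordinate error")

  # planted context: both ATGs, consensus alleles, splice dinucleotides
  expect_identical(substr(ref, 127, 129), "ATG")
  expect_identical(substr(ref, 52, 54), "ATG")
  expect_identical(substr(ref, 709, 710), "GT")
  expect_identical(substr(ref, 805, 806), "AG")
  pan <- ckx2SnpPanel()
  v <- strsplit(ref, "")[[1]]
  expect_identical(v[snpPositions(pan)], unname(alleleMatrix(pan)[, 1]))

  # the upstream in-frame ATG is unique and the frame runs open into 127
  starts <- seq(1, 124, by = 3)
  codons <- vapply(starts, function(p) substr(ref, p, p + 2), character(1))
  expect_identical(starts[codons == "ATG"], 52)
  open <- vapply(seq(52, 124, by = 3), function(p) substr(ref, p, p + 2),
                 character(1))
  expect_false(any(open %in% c("TAA", "TAG", "TGA")))
})

test_that("zero-noise panels carry exactly the planted haplotype alleles", {
  cfg <- simulationConfig(nAccessions = 80, miscallRate = 0, missingRate = 0)
  sim <- generatePanel(cfg, seed = 11)
  pan <- cfg$panel
  m <- t(vapply(as.character(sim$alignment),
                function(s) strsplit(s, "")[[1]], character(1321),
                USE.NAMES = FALSE))
  for (i in seq_len(nrow(m))) {
    hap <- sim$truth$haplotype[i]
    expect_identical(unname(m[i, snpPositions(pan)]),
                     unname(cfg$hapAlleles[hap, ]))
  }
  # truth table covers every accession exactly once
  expect_identical(sim$truth$accession, names(sim$alignment))
})

test_that("haplotype draws follow the configured frequencies", {
  haps <- hapAlleles(ckx2HaplotypeTable())[1:3, ]
  freqs <- c(0.5, 0.3, 0.2)
  cfg <- simulationConfig(nAccessions = 500, hapAlleles = haps,
                          hapFreqs = freqs, wildFraction = c(0.5, 0.5, 0.5),
                          miscallRate = 0, missingRate = 0)
  sim <- generatePanel(cfg, seed = 21)
  obs <- table(factor(sim$truth$haplotype, levels = rownames(haps))) / 500
  se <- sqrt(freqs * (1 - freqs) / 500)
  expect_true(all(abs(as.numeric(obs) - freqs) < 3 * se))

  # convergence at n = 5000 within 2 percentage points
  cfg2 <- simulationConfig(nAccessions = 5000, hapAlleles = haps,
                           hapFreqs = freqs, wildFraction = c(0.5, 0.5, 0.5),
                           miscallRate = 0, missingRate = 0)
  sim2 <- generatePanel(cfg2, seed = 22)
  obs2 <- table(factor(sim2$truth$haplotype, levels = rownames(haps))) / 5000
  expect_true(all(abs(as.numeric(obs2) - freqs) < 0.02))
})

test_that("noise saturation and config validation behave as specified", {
  cfg <- simulationConfig(nAccessions = 10, miscallRate = 0, missingRate = 1)
  sim <- generatePanel(cfg, seed = 3)
  g <- t(vapply(as.character(sim$alignment),
                function(s) strsplit(s, "")[[1]], character(1321),
                USE.NAMES = FALSE))[, snpPositions(cfg$panel)]
  expect_true(all(g == "N"))

  expect_error(simulationConfig(hapAlleles = matrix(character(), 0, 9)),
               "config error")
  expect_error(simulationConfig(hapFreqs = rep(0.5, 14)), "config error")
  expect_error(simulationConfig(miscallRate = 1.5), "config error")
  expect_error(simulationConfig(climateSd = -1), "config error")
  expect_error(simulationConfig(ampliconLength = 200), "coordinate error")
})

test_that("climate generation recovers planted shifts and degenerates cleanly", {
  haps <- hapAlleles(ckx2HaplotypeTable())[c("1", "3"), ]
  shift <- matrix(0, 2, 12, dimnames = list(c("1", "3"), month.abb))
  shift["3", c("Nov", "Dec", "Jan", "Feb")] <- 30
  cfg <- simulationConfig(nAccessions = 300, hapAlleles = haps,
                          hapFreqs = c(0.5, 0.5), wildFraction = c(1, 1),
                          climateSd = 10, climateShift = shift,
                          miscallRate = 0, missingRate = 0)
  sim <- generatePanel(cfg, seed = 31)
  clim <- generateClimate(cfg, sim$truth, seed = 32)
  s <- monthlySummary(clim)
  for (mo in c("Nov", "Dec", "Jan", "Feb")) {
    m3 <- s$mean[s$haplotype == "3" & s$month == mo]
    m1 <- s$mean[s$haplotype == "1" & s$month == mo]
    expect_gt(m3 - m1, 20)
  }

  # null configuration: no month separates any pair beyond 4 pooled SE
  cfg0 <- simulationConfig(nAccessions = 300, hapAlleles = haps,
                           hapFreqs = c(0.5, 0.5), wildFraction = c(1, 1),
                           climateSd = 10,
                           climateShift = matrix(0, 2, 12,
                             dimnames = list(c("1", "3"), month.abb)),
                           miscallRate = 0, missingRate = 0)
  for (seed in c(41, 42, 43)) {
    sim0 <- generatePanel(cfg0, seed = seed)
    clim0 <- generateClimate(cfg0, sim0$truth, seed = seed + 100)
    s0 <- monthlySummary(clim0)
    for (mo in month.abb) {
      a <- s0[s0$haplotype == "1" & s0$month == mo, ]
      b <- s0[s0$haplotype == "3" & s0$month == mo, ]
      expect_lt(abs(a$mean - b$mean), 4 * sqrt(a$se^2 + b$se^2))
    }
  }

  # sd = 0: all accessions of a haplotype share identical monthly values
  cfgd <- simulationConfig(nAccessions = 40, hapAlleles = haps,
                           hapFreqs = c(0.5, 0.5), wildFraction = c(1, 1),
                           climateSd = 0, climateShift = shift,
                           miscallRate = 0, missingRate = 0)
  simd <- generatePanel(cfgd, seed = 51)
  climd <- generateClimate(cfgd, simd$truth, seed = 52)
  for (h in c("1", "3")) {
    sub <- climd[climd$haplotype == h, month.abb]
    expect_true(all(apply(sub, 2, function(x) length(unique(x)) == 1)))
  }
  expect_error(generateClimate(cfgd, data.frame(accession = "a",
    haplotype = "99", population = "wild")), "config error")
})

test_that("simulation writers round-trip through FASTA and CSV", {
  cfg <- simulationConfig(nAccessions = 12, miscallRate = 0, missingRate = 0)
  sim <- generatePanel(cfg, seed = 61)
  clim <- generateClimate(cfg, sim$truth, seed = 62)
  dir <- tempfile("simout")
  paths <- writeSimulation(sim, dir, climate = clim)
  aln <- readAlignment(paths[["alignment"]])
  expect_identical(as.character(aln), as.character(sim$alignment))
  pops <- read.csv(paths[["populations"]], stringsAsFactors = FALSE)
  expect_identical(pops$accession, sim$populations$accession)
  expect_true(file.exists(paths[["climate"]]))
})
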