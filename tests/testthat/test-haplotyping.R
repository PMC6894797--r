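test_that("genotype extraction coerces non-allele bases to missing", {
  pan <- ckx2SnpPanel()
  cat <- ckx2HaplotypeTable()
  ref <- generateReference(1321, seed = 5)
  v <- strsplit(ref, "")[[1]]
  h1 <- v; h1[snpPositions(pan)] <- hapAlleles(cat)["1", ]
  h2 <- h1; h2[1220] <- "N"
  h3 <- h1; h3[263] <- "G"  # not in the C/T pair at 263
  m <- rbind(a = h1, b = h2, c = h3)
  g <- extractGenotypes(m, pan)
  expect_identical(g$status, c("complete", "partial", "partial"))
  expect_identical(unlist(g[1, paste0("p", snpPositions(pan))],
                          use.names = FALSE),
                   unname(hapAlleles(cat)["1", ]))
  expect_true(is.na(g$p1220[2]))
  expect_true(is.na(g$p263[3]))
})

test_that("haplotype tables partition complete accessions and match truth", {
  cat <- ckx2HaplotypeTable()
  ex <- expandCatalogue(cat)
  tab <- buildHaplotypeTable(ex$genotypes, ex$populations, cat@panel,
                             labels = cat)
  cnt <- hapCounts(tab)
  ref <- hapCounts(cat)
  cnt <- cnt[match(ref$haplotype, cnt$haplotype), ]
  expect_identical(cnt$wild, ref$wild)
  expect_identical(cnt$landrace, ref$landrace)
  expect_identical(cnt$total, ref$total)
  expect_identical(sum(cnt$total), nrow(ex$genotypes))
  expect_identical(hapAlleles(tab)[ref$haplotype, ], hapAlleles(cat))

  # degenerate inputs
  one <- ex$genotypes[1, , drop = FALSE]
  t1 <- buildHaplotypeTable(one, ex$populations, cat@panel)
  expect_identical(hapCounts(t1)$total, 1L)

  two <- ex$genotypes[c(1, 68), , drop = FALSE]  # same vector, both pops
  expect_setequal(ex$populations$population[c(1, 68)],
                  c("wild", "landrace"))
  t2 <- buildHaplotypeTable(two, ex$populations, cat@panel)
  expect_equal(hapCounts(t2)[, c("wild", "landrace", "total")],
               data.frame(wild = 1L, landrace = 1L, total = 2L))

  partial <- ex$genotypes
  partial$p110 <- NA_character_
  partial$status <- "partial"
  expect_warning(t0 <- buildHaplotypeTable(partial, ex$populations,
                                           cat@panel), "no complete")
  expect_identical(nrow(hapAlleles(t0)), 0L)
})

test_that("label assignment is deterministic with lexicographic tie-breaks", {
  pan <- SnpPanel(c(10L, 20L), c("A", "A"), c("C", "C"))
  g <- data.frame(accession = c("x", "y"), status = "complete",
                  p10 = c("C", "A"), p20 = c("A", "C"),
                  stringsAsFactors = FALSE)
  pops <- data.frame(accession = c("x", "y"), population = "wild",
                     stringsAsFactors = FALSE)
  tab <- buildHaplotypeTable(g, pops, pan)
  # equal totals: label 1 goes to the lexicographically smaller vector AC
  expect_identical(unname(hapAlleles(tab)["1", ]), c("A", "C"))
  expect_identical(unname(hapAlleles(tab)["2", ]), c("C", "A"))
})

test_that("partial haplotypes resolve by compatibility extension", {
  cat <- ckx2HaplotypeTable()
  pan <- cat@panel
  pcols <- paste0("p", snpPositions(pan))
  mk <- function(vec, id = "q") {
    d <- data.frame(accession = id, status = "partial",
                    stringsAsFactors = FALSE)
    d[pcols] <- as.list(vec)
    d
  }
  # haplotype 1 with 1220 unread: completions reach haplotypes 1 and 6 only
  v <- hapAlleles(cat)["1", ]; v[9] <- NA
  r <- extendPartial(mk(v), cat)
  expect_identical(r$status, "partial-resolvable")
  expect_setequal(r$compatibleList[[1]], c("1", "6"))

  # all-missing vector is compatible with the whole catalogue
  r2 <- extendPartial(mk(rep(NA_character_, 9)), cat)
  expect_setequal(r2$compatibleList[[1]], hapLabels(cat))

  # a vector incompatible with every completion is partial-novel:
  # G at 277 only occurs with C at 707 (haplotypes 5, 9)
  v3 <- rep(NA_character_, 9)
  v3[4] <- "G"; v3[7] <- "G"
  r3 <- extendPartial(mk(v3), cat)
  expect_identical(r3$status, "partial-novel")

  comp <- mk(hapAlleles(cat)["1", ])
  comp$status <- "complete"
  expect_error(extendPartial(comp, cat), "contract error")
})

test_that("hamming distance reproduces catalogue dissimilarities and is a metric", {
  cat <- ckx2HaplotypeTable()
  al <- hapAlleles(cat)
  expect_identical(hammingDist(al["7", ], al["14", ]), 3L)
  expect_identical(hammingDist(al["1", ], al["10", ]), 3L)
  expect_identical(hammingDist(al["1", ], al["1", ]), 0L)

  d <- hapDistances(cat)
  expect_true(all(d == t(d)))
  expect_true(all(diag(d) == 0L))
  expect_true(all(d[upper.tri(d)] > 0L))  # identity of indiscernibles
  n <- nrow(d)
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(d[i, j], d[i, k] + d[k, j])
  # agreement with the independent oracle on every pair
  for (i in 1:n) for (j in 1:n)
    expect_identical(d[i, j], as.integer(hamOracle(al[i, ], al[j, ])))

  expect_error(hammingDist(c("A", NA), c("A", "C")), "contract error")
  expect_error(hammingDist(c("A"), c("A", "C")), "contract error")
})

test_that("haplotype frequencies stratify by population", {
  cat <- ckx2HaplotypeTable()
  f <- haplotypeFrequency(cat, "3", "wild")
  expect_equal(f, 51 / 172)
  expect_equal(round(100 * f, 2), 29.65)
  expect_identical(haplotypeFrequency(cat, "3", "landrace"), 0)
  expect_equal(haplotypeFrequency(cat, "6", "landrace"), 4 / 200)
  expect_error(haplotypeFrequency(cat, "99", "wild"), "unknown")
})

test_that("the zero-noise pipeline round-trips generated haplotypes exactly", {
  cfg <- simulationConfig(nAccessions = 250, miscallRate = 0,
                          missingRate = 0)
  sim <- generatePanel(cfg, seed = 71)
  pan <- variantsToPanel(callVariants(sim$alignment, laxThresholds()))
  geno <- extractGenotypes(sim$alignment, pan)
  expect_true(all(geno$status == "complete"))
  tab <- buildHaplotypeTable(geno, sim$populations, pan,
                             labels = ckx2HaplotypeTable())
  cnt <- hapCounts(tab)
  truth <- table(sim$truth$haplotype)
  expect_setequal(cnt$haplotype, names(truth))
  expect_identical(cnt$total[match(names(truth), cnt$haplotype)],
                   as.integer(truth))
  truthW <- table(sim$truth$haplotype[sim$truth$population == "wild"])
  expect_identical(cnt$wild[match(names(truthW), cnt$haplotype)],
                   as.integer(truthW))
})
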