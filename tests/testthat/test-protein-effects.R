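test_that("gene-model fitting recovers CDS start and intron length", {
  ann <- ckx2CodonAnnotations()
  m <- fitGeneModel(ann)
  # independent arithmetic oracle: each exon-1 row determines the start as
  # position - 3(codon-1) - (codonpos-1); exon-2 rows then fix the intron
  e1 <- ann[ann$region == "exon1", ]
  starts <- e1$position - 3 * (e1$codon - 1) - (e1$codon_position - 1)
  expect_true(all(starts == starts[1]))
  expect_identical(m@cdsStart, as.integer(starts[1]))
  expect_identical(m@cdsStart, 127L)
  e2 <- ann[ann$region == "exon2", ]
  lens <- e2$position - 3 * (e2$codon - 1) - (e2$codon_position - 1) -
    starts[1]
  expect_true(all(lens == lens[1]))
  expect_identical(m@intronLength, as.integer(lens[1]))
  expect_identical(m@intronLength, 98L)
  expect_identical(m@intronStart, 709L)

  # single exon-1 row: start determined, intron undetermined
  one <- data.frame(position = 263, region = "exon1", codon = 46,
                    codon_position = 2)
  m1 <- fitGeneModel(one)
  expect_identical(m1@cdsStart, 127L)
  expect_true(is.na(m1@intronLength))

  bad <- rbind(one, data.frame(position = 277, region = "exon1",
                               codon = 51, codon_position = 2))
  expect_error(fitGeneModel(bad), "no-solution")
})

test_that("codon annotation reproduces the known substitution effects", {
  m <- fitGeneModel(ckx2CodonAnnotations())
  ref <- generateReference(1321, seed = 9)
  pan <- ckx2SnpPanel()
  eff <- annotateSnps(m, ref, pan)

  e572 <- eff[eff$position == 572, ]
  expect_identical(e572$codon, 149L)
  expect_identical(e572$codonPosition, 2L)
  expect_identical(c(e572$codon1, e572$codon2), c("ATC", "ACC"))
  expect_identical(c(e572$aa1, e572$aa2), c("ile", "thr"))

  e432 <- eff[eff$position == 432, ]
  expect_identical(e432$codon, 102L)
  expect_true(e432$synonymous)

  expect_identical(eff$region[eff$position %in% c(110, 113)],
                   rep("upstream", 2))
  expect_identical(eff$region[eff$position %in% c(1112, 1220)],
                   rep("exon2", 2))

  # synonymy agrees with direct translation of both codons (all nine SNPs)
  cod <- eff[!is.na(eff$codon1), ]
  for (r in seq_len(nrow(cod))) {
    t1 <- as.character(Biostrings::translate(
      Biostrings::DNAString(cod$codon1[r]), no.init.codon = TRUE))
    t2 <- as.character(Biostrings::translate(
      Biostrings::DNAString(cod$codon2[r]), no.init.codon = TRUE))
    expect_identical(cod$synonymous[r], t1 == t2)
  }

  # round-trip closure: annotation reproduces every annotated triple
  ann <- ckx2CodonAnnotations()
  coding <- ann[ann$region != "upstream", ]
  for (r in seq_len(nrow(coding))) {
    got <- eff[eff$position == coding$position[r], ]
    expect_identical(got$region, coding$region[r])
    expect_identical(got$codon, as.integer(coding$codon[r]))
    expect_identical(got$codonPosition,
                     as.integer(coding$codon_position[r]))
  }

  expect_error(annotateSnp(m, ref, 2000, c("A", "C")), "coordinate error")
  refN <- paste0(substr(ref, 1, 570), "N", substr(ref, 572, 1321))
  expect_error(annotateSnp(m, refN, 572, c("T", "C")), "annotation error")
})

test_that("initiation-codon arbitration follows orthologue conservation", {
  ref <- generateReference(1321, seed = 15)
  m <- GeneModel(1321, 127, 709, 98, alternativeStarts = 52L)
  expect_identical(findUpstreamStarts(ref, m), 52L)

  up <- substr(ref, 1, 140)
  noATG <- paste0(substr(up, 1, 51), "CCC", substr(up, 55, 140))
  res <- resolveStart(m, list(target = up, ortholog = noATG))
  expect_identical(res$chosen, 127L)
  expect_identical(res$rejected, 52L)
  expect_identical(res$extraResidues, 25L)
  expect_false(res$orthologHasUpstreamATG)

  res2 <- resolveStart(m, list(target = up, ortholog = up))
  expect_identical(res2$chosen, 52L)
  expect_true(res2$orthologHasUpstreamATG)

  # gapped orthologue alignment still locates the candidate columns
  gapT <- paste0(substr(up, 1, 30), "---", substr(up, 31, 140))
  gapO <- paste0(substr(up, 1, 30), "AAA", substr(up, 31, 140))
  res3 <- resolveStart(m, list(target = gapT, ortholog = gapO))
  expect_identical(res3$chosen, 52L)

  bad <- GeneModel(1321, 127, 709, 98, alternativeStarts = 53L)
  expect_error(resolveStart(bad, list(target = up, ortholog = up)),
               "model error")

  # under the upstream-start model the two promoter-proximal SNPs become
  # coding, at second positions of consecutive codons
  alt <- res$alternativeModel
  a110 <- annotateSnp(alt, ref, 110, c("T", "C"))
  a113 <- annotateSnp(alt, ref, 113, c("A", "G"))
  expect_identical(c(a110$codonPosition, a113$codonPosition), c(2L, 2L))
  expect_identical(a113$codon, a110$codon + 1L)
  expect_identical(c(a110$aa1, a110$aa2), c("leu", "pro"))
  expect_identical(c(a113$aa1, a113$aa2), c("lys", "arg"))
})

test_that("haplotypes collapse into the four known protein variants", {
  cat <- ckx2HaplotypeTable()
  m <- fitGeneModel(ckx2CodonAnnotations())
  ref <- generateReference(1321, seed = 19)
  eff <- annotateSnps(m, ref, ckx2SnpPanel())
  pv <- collapseVariants(cat, eff)

  expect_identical(nrow(pv), 4L)
  expect_identical(pv$total, c(305L, 52L, 11L, 4L))
  expect_identical(sum(pv$total), sum(hapCounts(cat)$total))

  b <- pv[pv$signature == "val-his-thr-gly", ]
  expect_setequal(strsplit(b$haplotypes, ",")[[1]], c("3", "13"))
  expect_identical(c(b$wild, b$landrace), c(52L, 0L))

  cc <- pv[pv$signature == "ala-asp-ile-ala", ]
  expect_setequal(strsplit(cc$haplotypes, ",")[[1]], c("5", "9"))
  expect_identical(cc$total, 11L)

  a <- pv[pv$signature == "ala-his-ile-gly", ]
  expect_setequal(strsplit(a$haplotypes, ",")[[1]],
                  c("1", "2", "4", "6", "8", "10", "11", "12"))

  # degenerate: a table with one haplotype collapses to one variant
  one <- HaplotypeTable(hapAlleles(cat)[1, , drop = FALSE], 5L, 3L,
                        cat@panel)
  expect_identical(nrow(collapseVariants(one, eff)), 1L)
})
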