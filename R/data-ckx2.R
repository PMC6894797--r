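#' The HvCKX2.1 amplicon SNP panel
#'
#' The nine biallelic SNPs segregating on the 1321-nt HvCKX2.1 amplicon in a
#' 444-accession barley diversity panel (228 landraces, 216 wild accessions):
#' positions 110, 113, 263, 277, 432, 572, 707, 1112 and 1220, with the
#' consensus base listed first at each position.
#'
#' @return A \linkS4class{SnpPanel} with 9 positions.
#' @examples
#' snpPositions(ckx2SnpPanel())
#' @export
ckx2SnpPanel <- function() {
  f <- system.file("extdata", "ckx2_snp_panel.csv", package = "hapdiver",
                   mustWork = TRUE)
  d <- read.csv(f, stringsAsFactors = FALSE)
  SnpPanel(d$position, d$allele1, d$allele2)
}

#' The HvCKX2.1 haplotype catalogue
#'
#' The fourteen SNP haplotypes observed among the 372 accessions of the
#' barley diversity panel with complete calls at all nine HvCKX2.1 panel
#' positions, with wild and landrace accession counts (172 wild + 200
#' landraces). Haplotype 3, the third-largest (51 accessions), is confined
#' to the wild population.
#'
#' @return A \linkS4class{HaplotypeTable} with 14 rows.
#' @examples
#' hapCounts(ckx2HaplotypeTable())
#' @export
ckx2HaplotypeTable <- function() {
  f <- system.file("extdata", "ckx2_haplotypes.csv", package = "hapdiver",
                   mustWork = TRUE)
  d <- read.csv(f, colClasses = "character")
  pan <- ckx2SnpPanel()
  al <- as.matrix(d[, paste0("p", pan@positions)])
  rownames(al) <- d$haplotype
  HaplotypeTable(al, as.integer(d$wild), as.integer(d$landrace), pan)
}

#' Codon-level annotations of the HvCKX2.1 panel SNPs
#'
#' For each panel SNP: the gene region it falls in (upstream of the ATG,
#' exon 1 or exon 2 under the Genbank-start gene model) and, for coding
#' SNPs, the 1-based codon index in the protein and the position within the
#' codon (1-3). These annotations are the input from which
#' \code{\link{fitGeneModel}} recovers the CDS start and intron length.
#'
#' @return A data.frame with columns \code{position}, \code{region},
#'   \code{codon}, \code{codon_position}.
#' @export
ckx2CodonAnnotations <- function() {
  f <- system.file("extdata", "ckx2_codon_annotations.csv",
                   package = "hapdiver", mustWork = TRUE)
  read.csv(f, stringsAsFactors = FALSE)
}

#' Curated sequence context for the synthetic HvCKX2.1 amplicon
#'
#' Fixed bases planted into synthetic reference sequences so that codon
#' annotation on simulated panels reproduces the amino-acid effects of the
#' real gene: the initiation ATG at 127, the alternative upstream in-frame
#' ATG at 52, the reference codon context of each coding SNP (GCC at codon
#' 46, CAC at 51, CTG at 102, ATC at 149, GGC at 194, GTC at 296, GCC at
#' 332), the codon context of SNPs 110/113 under the upstream-start reading
#' frame, and canonical GT..AG dinucleotides for the 98-nt intron at
#' 709-806.
#'
#' @return A data.frame with columns \code{position}, \code{base}.
#' @export
ckx2ReferenceConstraints <- function() {
  d <- rbind(
    # upstream alternative ATG (in frame with 127)
    data.frame(position = 52:54, base = c("A", "T", "G")),
    # Genbank initiation codon
    data.frame(position = 127:129, base = c("A", "T", "G")),
    # upstream-start frame context: codon 20 = CTx, codon 21 = AAA/AGA
    data.frame(position = c(109L, 112L, 114L), base = c("C", "A", "A")),
    # coding SNP codon contexts (consensus codons)
    data.frame(position = 262:264, base = c("G", "C", "C")),   # ala 46
    data.frame(position = 277:279, base = c("C", "A", "C")),   # his 51
    data.frame(position = 430:432, base = c("C", "T", "G")),   # leu 102
    data.frame(position = 571:573, base = c("A", "T", "C")),   # ile 149
    data.frame(position = 706:708, base = c("G", "G", "C")),   # gly 194
    data.frame(position = 1110:1112, base = c("G", "T", "C")), # val 296
    data.frame(position = 1218:1220, base = c("G", "C", "C")), # ala 332
    # splice dinucleotides of the 98-nt intron (709-806)
    data.frame(position = c(709L, 710L, 805L, 806L),
               base = c("G", "T", "A", "G")))
  d[!duplicated(d$position), ]
}
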