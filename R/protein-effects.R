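# 1-letter -> 3-letter residue codes (lowercase, as conventionally tabulated)
.AA3 <- c(A = "ala", R = "arg", N = "asn", D = "asp", C = "cys", Q = "gln",
          E = "glu", G = "gly", H = "his", I = "ile", L = "leu", K = "lys",
          M = "met", F = "phe", P = "pro", S = "ser", T = "thr", W = "trp",
          Y = "tyr", V = "val", `*` = "stop")

.translateCodon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stop("annotation error: undefined codon ", codon)
  aa
}

#' Fit a gene model to codon-level SNP annotations
#'
#' Recovers the CDS start and the intron length of a single-intron gene
#' model by exhaustive search against annotated coding SNPs. An exon-1 row
#' (position, codon index c, position-in-codon q) constrains
#' \code{position = cdsStart + 3(c-1) + (q-1)}; an exon-2 row adds the
#' intron length to the right-hand side. The search runs over every
#' \code{cdsStart} in [1, ampliconLength] and, when exon-2 rows are present,
#' every intron length in [0, ampliconLength]; exactly one solution must
#' survive. Without exon-2 rows the intron remains undetermined
#' (\code{NA}). The intron is placed immediately after the last annotated
#' exon-1 codon, the only placement the annotations themselves constrain.
#'
#' @param annotations data.frame with columns \code{position},
#'   \code{region} ("upstream"/"exon1"/"exon2"; upstream rows are ignored),
#'   \code{codon}, \code{codon_position}.
#' @param ampliconLength amplicon length in nt.
#' @param alternativeStarts optional candidate ATG positions to record.
#' @return A \linkS4class{GeneModel}.
#' @examples
#' fitGeneModel(ckx2CodonAnnotations())  # cdsStart 127, intron 98 nt
#' @export
fitGeneModel <- function(annotations, ampliconLength = 1321L,
                         alternativeStarts = integer()) {
  a <- annotations[annotations$region %in% c("exon1", "exon2"), , drop = FALSE]
  if (!nrow(a)) stop("no-solution error: no coding annotations supplied")
  e1 <- a[a$region == "exon1", , drop = FALSE]
  e2 <- a[a$region == "exon2", , drop = FALSE]
  if (!nrow(e1)) stop("no-solution error: at least one exon-1 row required")
  off1 <- 3L * (e1$codon - 1L) + (e1$codon_position - 1L)
  starts <- seq_len(ampliconLength)
  ok <- vapply(starts, function(s) all(e1$position == s + off1), logical(1L))
  s <- starts[ok]
  if (length(s) == 0L)
    stop("no-solution error: inconsistent exon-1 annotations")
  if (length(s) > 1L)
    stop("no-solution error: cdsStart not uniquely determined")
  intronLen <- NA_integer_
  intronStart <- NA_integer_
  if (nrow(e2)) {
    off2 <- 3L * (e2$codon - 1L) + (e2$codon_position - 1L)
    lens <- 0:ampliconLength
    ok2 <- vapply(lens, function(I) all(e2$position == s + off2 + I),
                  logical(1L))
    intronLen <- lens[ok2]
    if (length(intronLen) != 1L)
      stop("no-solution error: intron length not uniquely determined")
    intronStart <- s + 3L * max(e1$codon) - 1L + 1L
    if (intronLen == 0L) intronStart <- NA_integer_
  }
  GeneModel(ampliconLength, s, intronStart, intronLen, alternativeStarts)
}

.cdsToAmplicon <- function(model, cdsPos) {
  amp <- model@cdsStart + cdsPos - 1L
  if (!is.na(model@intronStart)) {
    shift <- amp >= model@intronStart
    amp[shift] <- amp[shift] + model@intronLength
  }
  amp
}

.region <- function(model, pos) {
  if (pos < model@cdsStart) return("upstream")
  if (!is.na(model@intronStart)) {
    iEnd <- model@intronStart + model@intronLength - 1L
    if (pos >= model@intronStart && pos <= iEnd) return("intron")
    if (pos > iEnd) return("exon2")
  }
  "exon1"
}

#' Annotate one SNP against a gene model
#'
#' Classifies the SNP's gene region; for coding positions, computes the
#' codon index and position-in-codon (with the intron removed), builds the
#' two codon variants by substituting each allele into the reference codon,
#' and translates them under the standard genetic code. A SNP whose two
#' codons translate identically is synonymous.
#'
#' @param model a \linkS4class{GeneModel}.
#' @param ref reference amplicon sequence (character string).
#' @param position 1-based SNP position on the amplicon.
#' @param alleles the two bases segregating at the position.
#' @return A one-row data.frame: \code{position}, \code{region},
#'   \code{codon}, \code{codonPosition}, \code{codon1}, \code{codon2},
#'   \code{aa1}, \code{aa2} (3-letter lowercase, or NA outside coding
#'   regions), \code{synonymous}.
#' @export
annotateSnp <- function(model, ref, position, alleles) {
  position <- as.integer(position)
  if (position > model@ampliconLength)
    stop("coordinate error: position beyond the amplicon")
  reg <- .region(model, position)
  out <- data.frame(position = position, region = reg,
                    codon = NA_integer_, codonPosition = NA_integer_,
                    codon1 = NA_character_, codon2 = NA_character_,
                    aa1 = NA_character_, aa2 = NA_character_,
                    synonymous = NA, stringsAsFactors = FALSE)
  if (!reg %in% c("exon1", "exon2")) return(out)
  cdsPos <- position - model@cdsStart + 1L
  if (reg == "exon2") cdsPos <- cdsPos - model@intronLength
  codonIdx <- (cdsPos - 1L) %/% 3L + 1L
  codonPos <- (cdsPos - 1L) %% 3L + 1L
  ampPos <- .cdsToAmplicon(model, (codonIdx - 1L) * 3L + 1:3)
  if (max(ampPos) > nchar(ref))
    stop("annotation error: reference shorter than the codon span")
  bases <- strsplit(ref, "")[[1L]][ampPos]
  if (!all(.isBase(bases)))
    stop("annotation error: reference codon contains undefined bases")
  mk <- function(al) {
    b <- bases; b[codonPos] <- al
    paste0(b, collapse = "")
  }
  c1 <- mk(alleles[1L]); c2 <- mk(alleles[2L])
  a1 <- .translateCodon(c1); a2 <- .translateCodon(c2)
  out$codon <- codonIdx; out$codonPosition <- codonPos
  out$codon1 <- c1; out$codon2 <- c2
  out$aa1 <- .AA3[[a1]]; out$aa2 <- .AA3[[a2]]
  out$synonymous <- a1 == a2
  out
}

#' Annotate every SNP of a panel
#'
#' @param model a \linkS4class{GeneModel}.
#' @param ref reference amplicon sequence (character string).
#' @param snpPanel a \linkS4class{SnpPanel}.
#' @return A data.frame with one \code{\link{annotateSnp}} row per SNP.
#' @examples
#' sim <- generatePanel(simulationConfig(nAccessions = 10), seed = 1)
#' model <- fitGeneModel(ckx2CodonAnnotations())
#' annotateSnps(model, sim$reference, ckx2SnpPanel())
#' @export
annotateSnps <- function(model, ref, snpPanel) {
  do.call(rbind, lapply(seq_along(snpPanel@positions), function(i)
    annotateSnp(model, ref, snpPanel@positions[i], snpPanel@alleles[i, ])))
}

#' Find in-frame upstream candidate initiation codons
#'
#' Scans positions upstream of (and in frame with) the model's CDS start for
#' ATG codons from which the reading frame runs open (no stop codon) into
#' the annotated start.
#'
#' @param ref reference amplicon sequence (character string).
#' @param model a \linkS4class{GeneModel}.
#' @return Integer vector of candidate positions (possibly empty).
#' @export
findUpstreamStarts <- function(ref, model) {
  s <- model@cdsStart
  if (s < 4L) return(integer())
  v <- strsplit(ref, "")[[1L]]
  cands <- integer()
  for (p in seq((s - 1L) %% 3L + 1L, s - 3L, by = 3L)) {
    if (paste0(v[p], v[p + 1L], v[p + 2L]) != "ATG") next
    codons <- vapply(seq(p, s - 3L, by = 3L), function(q)
      paste0(v[q], v[q + 1L], v[q + 2L]), character(1L))
    if (!any(codons %in% c("TAA", "TAG", "TGA")))
      cands <- c(cands, p)
  }
  cands
}

#' Arbitrate between candidate initiation codons
#'
#' Decides between an upstream and a downstream in-frame ATG using an
#' orthologue's upstream alignment: the upstream candidate is retained only
#' when the orthologue carries an aligned ATG at the candidate's columns;
#' otherwise the downstream start is chosen. The rejected candidate is kept
#' as an alternative model so its would-be codon effects can be compared
#' (under an upstream start the protein gains one residue per codon of
#' offset).
#'
#' @param model a \linkS4class{GeneModel} whose \code{alternativeStarts}
#'   holds the candidate ATG positions (the model's own \code{cdsStart}
#'   counts as the downstream candidate).
#' @param orthologAlignment pairwise alignment of the amplicon's upstream
#'   region with the orthologue: a list with gapped equal-length strings
#'   \code{target} and \code{ortholog}, and \code{targetStart}, the amplicon
#'   position of the first target column (default 1).
#' @return A list: \code{chosen} and \code{rejected} (positions),
#'   \code{model} (a \linkS4class{GeneModel} with the chosen start),
#'   \code{alternativeModel}, \code{extraResidues} (protein-length gain of
#'   the upstream model over the downstream one) and
#'   \code{orthologHasUpstreamATG}.
#' @export
resolveStart <- function(model, orthologAlignment) {
  starts <- sort(unique(c(model@cdsStart, model@alternativeStarts)))
  if (length(starts) != 2L)
    stop("model error: exactly two candidate starts required")
  if ((starts[2L] - starts[1L]) %% 3L != 0L)
    stop("model error: candidate starts not in frame with each other")
  up <- starts[1L]; down <- starts[2L]
  tgt <- strsplit(toupper(orthologAlignment$target), "")[[1L]]
  orth <- strsplit(toupper(orthologAlignment$ortholog), "")[[1L]]
  if (length(tgt) != length(orth))
    stop("input error: alignment rows of unequal length")
  tstart <- orthologAlignment$targetStart
  if (is.null(tstart)) tstart <- 1L
  # map amplicon position -> alignment column (gaps consume no position)
  ampPos <- cumsum(tgt != "-") + tstart - 1L
  ampPos[tgt == "-"] <- NA_integer_
  cols <- match(up + 0:2, ampPos)
  conserved <- !anyNA(cols) && identical(orth[cols], c("A", "T", "G"))
  chosen <- if (conserved) up else down
  rejected <- setdiff(starts, chosen)
  mk <- function(s) GeneModel(model@ampliconLength, s, model@intronStart,
                              model@intronLength, setdiff(starts, s))
  list(chosen = chosen, rejected = rejected,
       model = mk(chosen), alternativeModel = mk(rejected),
       extraResidues = (down - up) %/% 3L,
       orthologHasUpstreamATG = conserved)
}

#' Collapse haplotypes into protein variants
#'
#' Maps every haplotype to its residue signature at the non-synonymous SNP
#' positions (ordered by ascending protein position) and groups haplotypes
#' sharing a signature. Variant labels A, B, C, ... are assigned in
#' descending total accession count (ties broken by signature).
#'
#' @param table a \linkS4class{HaplotypeTable}.
#' @param effects data.frame from \code{\link{annotateSnps}} over the same
#'   panel.
#' @return A data.frame: \code{variant}, \code{signature} (residues joined
#'   by "-"), \code{haplotypes} (comma-separated labels), \code{wild},
#'   \code{landrace}, \code{total}.
#' @export
collapseVariants <- function(table, effects) {
  ns <- effects[!is.na(effects$synonymous) & !effects$synonymous, ,
                drop = FALSE]
  ns <- ns[order(ns$codon), , drop = FALSE]
  if (!nrow(ns)) stop("no non-synonymous effect supplied")
  pidx <- match(ns$position, table@panel@positions)
  if (anyNA(pidx))
    stop("consistency error: effect position outside the panel")
  sig <- apply(table@alleles[, pidx, drop = FALSE], 1L, function(row) {
    aa <- vapply(seq_along(pidx), function(k) {
      pair <- table@panel@alleles[pidx[k], ]
      if (row[k] == pair[1L]) ns$aa1[k]
      else if (row[k] == pair[2L]) ns$aa2[k]
      else stop("consistency error: haplotype allele outside the pair")
    }, character(1L))
    paste(aa, collapse = "-")
  })
  usig <- unique(sig)
  wild <- vapply(usig, function(x) sum(table@wild[sig == x]), integer(1L))
  landrace <- vapply(usig, function(x) sum(table@landrace[sig == x]),
                     integer(1L))
  total <- wild + landrace
  haps <- vapply(usig, function(x)
    paste(rownames(table@alleles)[sig == x], collapse = ","), character(1L))
  ord <- order(-total, usig)
  data.frame(variant = LETTERS[seq_along(usig)], signature = usig[ord],
             haplotypes = haps[ord], wild = wild[ord],
             landrace = landrace[ord], total = total[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}
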