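#' SnpPanel: an ordered set of biallelic SNPs on one amplicon
#'
#' Holds the 1-based amplicon positions of a set of biallelic SNPs together
#' with the two segregating bases at each position. The first allele is the
#' consensus (reference) base, the second the alternative.
#'
#' @slot positions integer vector of strictly increasing 1-based positions.
#' @slot alleles character matrix with one row per position and columns
#'   \code{allele1} (consensus) and \code{allele2}.
#' @export
setClass("SnpPanel",
  representation(positions = "integer", alleles = "matrix"))

setValidity("SnpPanel", function(object) {
  p <- object@positions
  a <- object@alleles
  msg <- character()
  if (nrow(a) != length(p))
    msg <- c(msg, "one allele pair required per position")
  if (length(p) && (any(p < 1L) || is.unsorted(p, strictly = TRUE)))
    msg <- c(msg, "positions must be strictly increasing and >= 1")
  if (!identical(colnames(a), c("allele1", "allele2")))
    msg <- c(msg, "allele columns must be 'allele1', 'allele2'")
  if (length(p)) {
    if (!all(.isBase(a)))
      msg <- c(msg, "alleles must be A/C/G/T")
    if (any(a[, 1L] == a[, 2L]))
      msg <- c(msg, "the two alleles at a position must differ")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SnpPanel
#'
#' @param positions integer vector of 1-based amplicon positions.
#' @param allele1 character vector of consensus bases, one per position.
#' @param allele2 character vector of alternative bases.
#' @return A \linkS4class{SnpPanel}.
#' @examples
#' SnpPanel(c(110L, 263L), c("T", "C"), c("C", "T"))
#' @export
SnpPanel <- function(positions, allele1, allele2) {
  al <- cbind(allele1 = toupper(as.character(allele1)),
              allele2 = toupper(as.character(allele2)))
  new("SnpPanel", positions = as.integer(positions), alleles = al)
}

#' HaplotypeTable: allele-vector haplotypes with population counts
#'
#' Each row of the allele matrix is one haplotype over the SNP panel;
#' \code{wild} and \code{landrace} give per-population accession counts.
#'
#' @slot alleles character matrix (haplotypes x positions), rownames are
#'   haplotype labels, colnames are amplicon positions.
#' @slot wild,landrace integer count vectors aligned with the rows.
#' @slot panel the \linkS4class{SnpPanel} the vectors are defined over.
#' @export
setClass("HaplotypeTable",
  representation(alleles = "matrix", wild = "integer",
                 landrace = "integer", panel = "SnpPanel"))

setValidity("HaplotypeTable", function(object) {
  a <- object@alleles
  msg <- character()
  n <- nrow(a)
  if (length(object@wild) != n || length(object@landrace) != n)
    msg <- c(msg, "counts must align with haplotype rows")
  if (any(object@wild < 0L) || any(object@landrace < 0L))
    msg <- c(msg, "counts must be non-negative")
  if (anyDuplicated(.vecKey(a)))
    msg <- c(msg, "haplotype allele vectors must be unique")
  pan <- object@panel
  if (ncol(a) != length(pan@positions))
    msg <- c(msg, "one allele per panel position required")
  else if (n > 0L) {
    ok <- vapply(seq_len(ncol(a)), function(j)
      all(a[, j] %in% pan@alleles[j, ]), logical(1L))
    if (!all(ok))
      msg <- c(msg, "haplotype alleles must belong to the panel allele pairs")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a HaplotypeTable
#'
#' @param alleles character matrix of allele vectors (haplotypes x panel
#'   positions); rownames are used as labels (defaults to 1..n).
#' @param wild,landrace integer accession counts per haplotype.
#' @param panel the \linkS4class{SnpPanel}.
#' @return A \linkS4class{HaplotypeTable}.
#' @export
HaplotypeTable <- function(alleles, wild, landrace, panel) {
  alleles <- as.matrix(alleles)
  if (is.null(rownames(alleles)))
    rownames(alleles) <- as.character(seq_len(nrow(alleles)))
  colnames(alleles) <- as.character(panel@positions)
  new("HaplotypeTable", alleles = alleles, wild = as.integer(wild),
      landrace = as.integer(landrace), panel = panel)
}

#' GeneModel: amplicon coordinate system for a single-intron gene
#'
#' Describes where the coding sequence starts on the amplicon, where the
#' single intron lies, and which alternative initiation codons exist.
#' \code{intronStart}/\code{intronLength} may be \code{NA} when no
#' downstream-exon information constrains them.
#'
#' @slot ampliconLength integer amplicon length (nt).
#' @slot cdsStart integer 1-based position of the A of the chosen ATG.
#' @slot intronStart integer first intron base (1-based), or NA.
#' @slot intronLength integer intron length in nt, or NA.
#' @slot alternativeStarts integer candidate ATG positions (may be empty).
#' @export
setClass("GeneModel",
  representation(ampliconLength = "integer", cdsStart = "integer",
                 intronStart = "integer", intronLength = "integer",
                 alternativeStarts = "integer"))

setValidity("GeneModel", function(object) {
  msg <- character()
  L <- object@ampliconLength
  s <- object@cdsStart
  is <- object@intronStart
  il <- object@intronLength
  if (L < 1L) msg <- c(msg, "ampliconLength must be positive")
  if (is.na(s) || s < 1L || s > L)
    msg <- c(msg, "cdsStart must lie on the amplicon")
  if (!is.na(is)) {
    if (is.na(il) || il < 0L)
      msg <- c(msg, "intronLength required with intronStart")
    else if (s >= is || is + il - 1L > L)
      msg <- c(msg, "intron must lie downstream of cdsStart, on the amplicon")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneModel
#'
#' @param ampliconLength amplicon length in nt.
#' @param cdsStart 1-based amplicon position of the initiation A.
#' @param intronStart 1-based first intron base (NA if unknown).
#' @param intronLength intron length in nt (NA if unknown).
#' @param alternativeStarts integer vector of candidate ATG positions.
#' @return A \linkS4class{GeneModel}.
#' @export
GeneModel <- function(ampliconLength, cdsStart, intronStart = NA,
                      intronLength = NA, alternativeStarts = integer()) {
  new("GeneModel", ampliconLength = as.integer(ampliconLength),
      cdsStart = as.integer(cdsStart), intronStart = as.integer(intronStart),
      intronLength = as.integer(intronLength),
      alternativeStarts = as.integer(alternativeStarts))
}

#' HaplotypeNetwork: observed and inferred haplotypes with weighted links
#'
#' A haplotype network over complete allele vectors: observed haplotypes carry
#' population counts; inferred median vectors carry count 0 and
#' \code{median = TRUE}. Every edge weight equals the Hamming distance of its
#' endpoint vectors, and the network is connected.
#'
#' @slot nodes data.frame with columns \code{id}, \code{haplotype} (the
#'   collapsed allele string), \code{wild}, \code{landrace}, \code{total},
#'   \code{median}.
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{weight}.
#' @slot alleles character matrix of node allele vectors (rownames = id).
#' @slot epsilon numeric relaxation parameter used in construction.
#' @export
setClass("HaplotypeNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 alleles = "matrix", epsilon = "numeric"))

setValidity("HaplotypeNetwork", function(object) {
  nd <- object@nodes
  ed <- object@edges
  al <- object@alleles
  msg <- character()
  need <- c("id", "haplotype", "wild", "landrace", "total", "median")
  if (!all(need %in% names(nd)))
    msg <- c(msg, "nodes must have id/haplotype/wild/landrace/total/median")
  if (!all(c("from", "to", "weight") %in% names(ed)))
    msg <- c(msg, "edges must have from/to/weight")
  if (length(msg)) return(msg)
  if (!identical(rownames(al), nd$id))
    msg <- c(msg, "allele matrix rows must align with node ids")
  if (nrow(ed)) {
    if (!all(ed$from %in% nd$id) || !all(ed$to %in% nd$id))
      msg <- c(msg, "edge endpoints must be node ids")
    else {
      w <- mapply(function(u, v) sum(al[u, ] != al[v, ]), ed$from, ed$to)
      if (!all(w == ed$weight))
        msg <- c(msg, "edge weights must equal Hamming distances")
    }
  }
  # connectivity via breadth-first expansion over the edge list
  if (nrow(nd) > 1L) {
    reach <- nd$id[1L]
    repeat {
      nxt <- unique(c(ed$to[ed$from %in% reach], ed$from[ed$to %in% reach]))
      nxt <- setdiff(nxt, reach)
      if (!length(nxt)) break
      reach <- c(reach, nxt)
    }
    if (length(reach) < nrow(nd))
      msg <- c(msg, "network must be connected")
  }
  if (length(msg)) msg else TRUE
})
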