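#' Extract per-accession genotypes over a SNP panel
#'
#' Reads the base carried by each accession at each panel position. Any base
#' outside the position's allele pair — including N, IUPAC ambiguity codes
#' and gaps — is coerced to missing (\code{NA}). Accessions with no missing
#' entry are \code{complete}; the others are \code{partial} until resolved
#' by \code{\link{extendPartial}}.
#'
#' @param panel alignment as a \code{Biostrings::DNAStringSet} or character
#'   matrix (accessions x positions).
#' @param snpPanel a \linkS4class{SnpPanel}.
#' @return A data.frame with \code{accession}, \code{status} and one allele
#'   column \code{p<position>} per panel SNP.
#' @export
extractGenotypes <- function(panel, snpPanel) {
  pos <- snpPanel@positions
  if (is.matrix(panel)) {
    if (ncol(panel) < max(pos))
      stop("coordinate error: alignment shorter than the last SNP position")
    g <- toupper(panel[, pos, drop = FALSE])
    ids <- rownames(panel)
  } else {
    if (min(Biostrings::width(panel)) < max(pos))
      stop("coordinate error: alignment shorter than the last SNP position")
    g <- vapply(seq_along(pos), function(j)
      as.character(Biostrings::subseq(panel, pos[j], pos[j])),
      character(length(panel)))
    if (is.null(dim(g))) g <- matrix(g, nrow = length(panel))
    ids <- names(panel)
  }
  if (is.null(ids)) ids <- sprintf("acc%04d", seq_len(nrow(g)))
  for (j in seq_along(pos))
    g[!(g[, j] %in% snpPanel@alleles[j, ]), j] <- NA_character_
  status <- ifelse(rowSums(is.na(g)) == 0L, "complete", "partial")
  out <- data.frame(accession = ids, status = status,
                    stringsAsFactors = FALSE)
  g <- as.data.frame(g, stringsAsFactors = FALSE)
  names(g) <- paste0("p", pos)
  cbind(out, g)
}

.genoMatrix <- function(genotypes) {
  cols <- grep("^p[0-9]+$", names(genotypes), value = TRUE)
  m <- as.matrix(genotypes[, cols, drop = FALSE])
  rownames(m) <- genotypes$accession
  m
}

#' Build a population-stratified haplotype table
#'
#' Enumerates haplotypes from complete-data accessions only (partial
#' accessions contribute to no count) and stratifies counts by population.
#' Haplotype labels are assigned in descending total count, ties broken by
#' lexicographic order of the allele vector; alternatively the labels of a
#' supplied reference \linkS4class{HaplotypeTable} are adopted for vectors
#' that match it (remaining vectors get fresh numeric labels).
#'
#' @param genotypes data.frame from \code{\link{extractGenotypes}}.
#' @param populations data.frame with columns \code{accession} and
#'   \code{population} ("wild"/"landrace").
#' @param snpPanel the \linkS4class{SnpPanel}.
#' @param labels optional \linkS4class{HaplotypeTable} whose labels to adopt.
#' @return A \linkS4class{HaplotypeTable}.
#' @export
buildHaplotypeTable <- function(genotypes, populations, snpPanel,
                                labels = NULL) {
  g <- .genoMatrix(genotypes)
  complete <- genotypes$status == "complete" & rowSums(is.na(g)) == 0L
  if (!any(complete)) {
    warning("no complete-data accessions; returning an empty table")
    return(HaplotypeTable(
      matrix(character(), 0L, length(snpPanel@positions)),
      integer(), integer(), snpPanel))
  }
  g <- g[complete, , drop = FALSE]
  pop <- populations$population[match(rownames(g), populations$accession)]
  if (anyNA(pop))
    stop("input error: population label missing for some accessions")
  key <- apply(g, 1L, paste0, collapse = "")
  uniq <- !duplicated(key)
  vec <- g[uniq, , drop = FALSE]
  ukey <- key[uniq]
  wild <- vapply(ukey, function(k)
    sum(key == k & pop == "wild"), integer(1L))
  landrace <- vapply(ukey, function(k)
    sum(key == k & pop == "landrace"), integer(1L))
  total <- wild + landrace
  ord <- order(-total, ukey)
  vec <- vec[ord, , drop = FALSE]
  wild <- wild[ord]; landrace <- landrace[ord]; ukey <- ukey[ord]
  labs <- as.character(seq_along(ukey))
  if (inherits(labels, "HaplotypeTable")) {
    refKey <- .vecKey(labels@alleles)
    hit <- match(ukey, refKey)
    labs[!is.na(hit)] <- rownames(labels@alleles)[hit[!is.na(hit)]]
    fresh <- which(is.na(hit))
    if (length(fresh))
      labs[fresh] <- paste0("n", seq_along(fresh))
  }
  rownames(vec) <- labs
  HaplotypeTable(vec, wild, landrace, snpPanel)
}

#' Resolve partial haplotypes against a haplotype table
#'
#' For each accession with missing entries, finds every catalogued haplotype
#' agreeing with it at all observed positions. Accessions with a non-empty
#' compatible set are \code{partial-resolvable}; the rest are
#' \code{partial-novel} (their observed alleles cannot be completed into any
#' known haplotype).
#'
#' @param genotypes data.frame from \code{\link{extractGenotypes}} (partial
#'   rows are processed; passing only complete rows is an error).
#' @param table a \linkS4class{HaplotypeTable}.
#' @return A data.frame with \code{accession}, \code{nMissing},
#'   \code{status}, \code{compatible} (comma-separated labels) and a
#'   list-column \code{compatibleList}.
#' @export
extendPartial <- function(genotypes, table) {
  g <- .genoMatrix(genotypes)
  part <- rowSums(is.na(g)) > 0L
  if (!any(part))
    stop("contract error: no partial accession supplied")
  g <- g[part, , drop = FALSE]
  ref <- table@alleles
  res <- lapply(seq_len(nrow(g)), function(i) {
    obs <- !is.na(g[i, ])
    comp <- if (any(obs)) {
      hits <- apply(ref[, obs, drop = FALSE], 1L, function(r)
        all(r == g[i, obs]))
      rownames(ref)[hits]
    } else rownames(ref)
    list(n = sum(!obs), comp = comp)
  })
  comp <- lapply(res, `[[`, "comp")
  data.frame(accession = rownames(g),
             nMissing = vapply(res, `[[`, integer(1L), "n"),
             status = ifelse(lengths(comp) > 0L,
                             "partial-resolvable", "partial-novel"),
             compatible = vapply(comp, paste, character(1L),
                                 collapse = ","),
             compatibleList = I(comp),
             stringsAsFactors = FALSE)
}

#' Hamming distance between complete allele vectors
#'
#' @param a,b character vectors of equal length with no missing entries.
#' @return Integer count of positions at which they differ.
#' @examples
#' hammingDist(c("A", "C", "G"), c("A", "T", "G"))
#' @export
hammingDist <- function(a, b) {
  if (length(a) != length(b))
    stop("contract error: vectors of unequal length")
  if (anyNA(a) || anyNA(b))
    stop("contract error: missing entries not allowed")
  sum(a != b)
}

#' Pairwise Hamming distances between catalogued haplotypes
#'
#' @param table a \linkS4class{HaplotypeTable}.
#' @return A symmetric integer matrix of SNP differences.
#' @export
hapDistances <- function(table) {
  a <- table@alleles
  n <- nrow(a)
  d <- matrix(0L, n, n, dimnames = list(rownames(a), rownames(a)))
  if (n > 1L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- hammingDist(a[i, ], a[j, ])
  d
}

#' Within-population frequency of a haplotype
#'
#' The count of the haplotype in the requested population divided by the
#' total number of complete-data accessions of that population.
#'
#' @param table a \linkS4class{HaplotypeTable}.
#' @param label haplotype label.
#' @param population "wild" or "landrace".
#' @return A fraction in [0, 1].
#' @examples
#' haplotypeFrequency(ckx2HaplotypeTable(), "3", "wild")  # 51/172
#' @export
haplotypeFrequency <- function(table, label, population = c("wild",
                                                            "landrace")) {
  population <- match.arg(population)
  i <- match(as.character(label), rownames(table@alleles))
  if (is.na(i)) stop("unknown haplotype label")
  cnt <- slot(table, population)
  denom <- sum(cnt)
  if (denom == 0L)
    stop("undefined frequency: no complete accessions in that population")
  cnt[i] / denom
}
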