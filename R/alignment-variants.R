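#' Read a multi-accession amplicon alignment
#'
#' Reads an aligned FASTA (one record per accession), uppercases the
#' sequences, and validates that there are at least two records, that all
#' records have the same length, and that accession ids (the first word of
#' each header) are unique.
#'
#' @param path path to a FASTA file.
#' @return A \code{Biostrings::DNAStringSet} with one record per accession.
#' @export
readAlignment <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) < 2L)
    stop("alignment error: at least two records required")
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("input error: duplicate accession ids in alignment")
  if (length(unique(Biostrings::width(raw))) != 1L)
    stop("alignment error: records have unequal lengths")
  out <- Biostrings::DNAStringSet(toupper(as.character(raw)))
  names(out) <- ids
  out
}

#' Variant-calling thresholds
#'
#' Confidence settings for \code{\link{callVariants}}. A column is a
#' high-confidence SNP when its minor-allele binomial tail probability is at
#' most \code{highMaxP} and its coverage (accessions with an unambiguous
#' base) reaches \code{highMinCov}; otherwise it may qualify as medium
#' confidence at the laxer settings. Coverage thresholds below 1 are read as
#' fractions of the panel size.
#'
#' @param errorRate assumed per-base miscall probability.
#' @param highMaxP,highMinCov high-confidence tier settings (defaults: the
#'   study's p <= 1e-9 with coverage 393/444 of the panel).
#' @param mediumMaxP,mediumMinCov medium-confidence tier settings.
#' @return A validated list of class \code{CallThresholds}.
#' @export
callThresholds <- function(errorRate = 0.01,
                           highMaxP = 1e-9, highMinCov = 393 / 444,
                           mediumMaxP = 1e-4, mediumMinCov = 0.75) {
  if (errorRate < 0 || errorRate > 1)
    stop("errorRate must lie in [0, 1]")
  if (highMaxP > mediumMaxP)
    stop("high tier must be at least as stringent as medium (p)")
  structure(list(errorRate = errorRate, highMaxP = highMaxP,
                 highMinCov = highMinCov, mediumMaxP = mediumMaxP,
                 mediumMinCov = mediumMinCov), class = "CallThresholds")
}

.resolveCov <- function(x, n) if (x < 1) ceiling(x * n) else x

#' Call biallelic SNPs from an aligned panel
#'
#' Scans every alignment column with at least two segregating unambiguous
#' bases. Coverage is the number of accessions with an A/C/G/T call at the
#' column; any IUPAC ambiguity code, N or gap counts as missing. The variant
#' p-value is the upper tail of Binomial(coverage, errorRate) at the
#' minor-allele count: the probability that sequencing error alone produces
#' at least that many minor-allele calls. Columns are tiered by the most
#' stringent thresholds they pass (\code{high}, \code{medium}, else
#' \code{rejected}); columns with more than two segregating bases are
#' reported as rejected with \code{multiallelic = TRUE} and never tiered.
#'
#' @param panel alignment as a \code{Biostrings::DNAStringSet} (equal-width)
#'   or a character matrix (accessions x positions).
#' @param thresholds a \code{\link{callThresholds}} object.
#' @return A data.frame with one row per variable column: \code{position},
#'   \code{major}, \code{minor}, \code{majorCount}, \code{minorCount},
#'   \code{coverage}, \code{pValue}, \code{tier}, \code{multiallelic}.
#' @examples
#' sim <- generatePanel(simulationConfig(nAccessions = 60,
#'   miscallRate = 0, missingRate = 0), seed = 1)
#' head(callVariants(sim$alignment))
#' @export
callVariants <- function(panel, thresholds = callThresholds()) {
  m <- if (is.matrix(panel)) toupper(panel)
       else {
         if (length(unique(Biostrings::width(panel))) != 1L)
           stop("alignment error: records have unequal lengths")
         t(vapply(as.character(panel),
                  function(s) strsplit(s, "")[[1L]],
                  character(Biostrings::width(panel)[1L]),
                  USE.NAMES = FALSE))
       }
  if (nrow(m) == 0L) stop("alignment error: empty panel")
  n <- nrow(m)
  hiCov <- .resolveCov(thresholds$highMinCov, n)
  medCov <- .resolveCov(thresholds$mediumMinCov, n)
  rows <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    col <- col[.isBase(col)]
    if (!length(col)) return(NULL)
    tab <- sort(table(col), decreasing = TRUE)
    if (length(tab) < 2L) return(NULL)
    cov <- sum(tab)
    # deterministic tie-break: among equal counts, alphabetical base first
    ord <- order(-as.integer(tab), names(tab))
    tab <- tab[ord]
    if (length(tab) > 2L)
      return(data.frame(position = j, major = names(tab)[1L],
                        minor = names(tab)[2L],
                        majorCount = as.integer(tab[1L]),
                        minorCount = as.integer(tab[2L]),
                        coverage = cov, pValue = NA_real_,
                        tier = "rejected", multiallelic = TRUE,
                        stringsAsFactors = FALSE))
    minorCount <- as.integer(tab[2L])
    p <- pbinom(minorCount - 1L, cov, thresholds$errorRate,
                lower.tail = FALSE)
    tier <- if (p <= thresholds$highMaxP && cov >= hiCov) "high"
            else if (p <= thresholds$mediumMaxP && cov >= medCov) "medium"
            else "rejected"
    data.frame(position = j, major = names(tab)[1L], minor = names(tab)[2L],
               majorCount = as.integer(tab[1L]), minorCount = minorCount,
               coverage = cov, pValue = p, tier = tier, multiallelic = FALSE,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows))
    return(data.frame(position = integer(), major = character(),
                      minor = character(), majorCount = integer(),
                      minorCount = integer(), coverage = integer(),
                      pValue = numeric(), tier = character(),
                      multiallelic = logical(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Promote called variants to a SnpPanel
#'
#' Keeps calls at or above the requested tiers (never multi-allelic columns)
#' and assembles them into a \linkS4class{SnpPanel}, major allele first.
#'
#' @param calls data.frame from \code{\link{callVariants}}.
#' @param tiers tiers to retain.
#' @return A \linkS4class{SnpPanel}.
#' @export
variantsToPanel <- function(calls, tiers = c("high", "medium")) {
  keep <- calls[!calls$multiallelic & calls$tier %in% tiers, , drop = FALSE]
  keep <- keep[order(keep$position), , drop = FALSE]
  SnpPanel(keep$position, keep$major, keep$minor)
}
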