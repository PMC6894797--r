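#' Simulation configuration for a synthetic amplicon panel
#'
#' Bundles and validates every parameter of the synthetic-data generator.
#' Defaults emulate the HvCKX2.1 study panel: 444 accessions drawn from the
#' fourteen catalogued haplotypes at their observed frequencies, wild/landrace
#' assignment at each haplotype's observed population split, a light per-base
#' miscall rate, a per-SNP-site missing-call rate calibrated so that roughly
#' one accession in six carries at least one no-call over the nine panel
#' sites, a Fertile-Crescent winter-rainfall monthly precipitation profile,
#' and a +30 mm November-February precipitation shift linked to haplotype 3.
#'
#' @param nAccessions number of accessions to simulate.
#' @param panel the \linkS4class{SnpPanel} carrying SNP positions/alleles.
#' @param hapAlleles character matrix of haplotype allele vectors
#'   (haplotypes x panel positions); rownames are haplotype labels.
#' @param hapFreqs haplotype sampling probabilities (must sum to 1).
#' @param wildFraction per-haplotype probability that an accession is wild
#'   (the complement is landrace).
#' @param miscallRate per-base probability of a miscalled (substituted) base,
#'   applied to every column, panel or not.
#' @param missingRate per-SNP-site probability of a no-call ("N").
#' @param ampliconLength amplicon length in nt.
#' @param climateBase numeric vector of 12 monthly precipitation means (mm),
#'   January to December.
#' @param climateSd common monthly standard deviation (mm).
#' @param climateShift numeric matrix (haplotypes x 12) of additive monthly
#'   offsets (mm); rownames must cover every haplotype label.
#' @return A validated list of class \code{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nAccessions = 50)
#' cfg$nAccessions
#' @export
simulationConfig <- function(nAccessions = 444L,
                             panel = ckx2SnpPanel(),
                             hapAlleles = NULL,
                             hapFreqs = NULL,
                             wildFraction = NULL,
                             miscallRate = 0.001,
                             missingRate = 0.02,
                             ampliconLength = 1321L,
                             climateBase = c(62, 55, 48, 30, 12, 3,
                                             1, 1, 4, 22, 44, 60),
                             climateSd = 10,
                             climateShift = NULL) {
  if (is.null(hapAlleles) || is.null(hapFreqs) || is.null(wildFraction)) {
    ref <- ckx2HaplotypeTable()
    cnt <- hapCounts(ref)
    if (is.null(hapAlleles)) hapAlleles <- hapAlleles(ref)
    if (is.null(hapFreqs)) hapFreqs <- cnt$total / sum(cnt$total)
    if (is.null(wildFraction)) wildFraction <- cnt$wild / cnt$total
  }
  hapAlleles <- as.matrix(hapAlleles)
  if (nrow(hapAlleles) == 0L)
    stop("config error: at least one haplotype definition required")
  if (is.null(rownames(hapAlleles)))
    rownames(hapAlleles) <- as.character(seq_len(nrow(hapAlleles)))
  labs <- rownames(hapAlleles)
  if (is.null(climateShift)) {
    climateShift <- matrix(0, nrow(hapAlleles), 12L,
                           dimnames = list(labs, .months()))
    if ("3" %in% labs)  # haplotype-3-linked winter-rainfall surplus
      climateShift["3", c("Nov", "Dec", "Jan", "Feb")] <- 30
  }
  climateShift <- as.matrix(climateShift)
  if (ncol(hapAlleles) != length(panel@positions))
    stop("config error: each haplotype needs one allele per panel position")
  for (j in seq_len(ncol(hapAlleles)))
    if (!all(hapAlleles[, j] %in% panel@alleles[j, ]))
      stop("config error: haplotype alleles must match the panel pairs")
  if (abs(sum(hapFreqs) - 1) > 1e-12)
    stop("config error: haplotype frequencies must sum to 1")
  rates <- c(miscallRate, missingRate, wildFraction)
  if (any(rates < 0) || any(rates > 1))
    stop("config error: rates must lie in [0, 1]")
  if (length(wildFraction) != nrow(hapAlleles))
    stop("config error: one wild fraction per haplotype required")
  if (length(climateBase) != 12L)
    stop("config error: climateBase must have 12 monthly values")
  if (climateSd < 0) stop("config error: negative climate sd")
  if (!all(labs %in% rownames(climateShift)) || ncol(climateShift) != 12L)
    stop("config error: climateShift must cover every haplotype x 12 months")
  if (ampliconLength < max(panel@positions))
    stop("coordinate error: amplicon shorter than the last panel position")
  structure(list(nAccessions = as.integer(nAccessions), panel = panel,
                 hapAlleles = hapAlleles, hapFreqs = as.numeric(hapFreqs),
                 wildFraction = as.numeric(wildFraction),
                 miscallRate = miscallRate, missingRate = missingRate,
                 ampliconLength = as.integer(ampliconLength),
                 climateBase = as.numeric(climateBase),
                 climateSd = climateSd, climateShift = climateShift),
            class = "SimulationConfig")
}

#' Generate a synthetic amplicon reference sequence
#'
#' Draws a uniform-random nucleotide sequence, then plants a deterministic
#' gene context: the consensus allele at every panel position and the fixed
#' bases of \code{constraints} (by default \code{\link{ckx2ReferenceConstraints}}:
#' both candidate ATGs, the coding-SNP codon contexts and the intron splice
#' dinucleotides). When \code{upstreamStart}/\code{cdsStart} are supplied the
#' open reading between them is enforced: any other in-frame ATG upstream of
#' \code{cdsStart} is disrupted and in-frame stop codons between the two
#' starts are recoded, so the sequence carries exactly two candidate
#' initiation codons.
#'
#' @param length amplicon length in nt; must reach the last panel position.
#' @param seed integer seed (same seed, same sequence).
#' @param panel \linkS4class{SnpPanel} whose consensus alleles are planted.
#' @param constraints data.frame(position, base) of fixed bases, or NULL.
#' @param upstreamStart,cdsStart candidate initiation ATG positions used for
#'   reading-frame clean-up; either may be NA to skip that step.
#' @return A single character string of A/C/G/T of the requested length.
#' @examples
#' ref <- generateReference(1321, seed = 1)
#' substr(ref, 127, 129)  # "ATG"
#' @export
generateReference <- function(length = 1321L, seed = NULL,
                              panel = ckx2SnpPanel(),
                              constraints = ckx2ReferenceConstraints(),
                              upstreamStart = 52L, cdsStart = 127L) {
  length <- as.integer(length)
  if (length(panel@positions) && length < max(panel@positions))
    stop("coordinate error: length below the last panel position")
  withSeed(seed, {
    s <- sample(.BASES, length, replace = TRUE)
    if (length(panel@positions))
      s[panel@positions] <- panel@alleles[, "allele1"]
    fixed <- panel@positions
    if (!is.null(constraints) && nrow(constraints)) {
      keep <- constraints$position <= length
      s[constraints$position[keep]] <- constraints$base[keep]
      fixed <- c(fixed, constraints$position[keep])
    }
    if (!is.na(upstreamStart) && !is.na(cdsStart) && cdsStart <= length) {
      starts <- seq((cdsStart - 1L) %% 3L + 1L, cdsStart - 3L, by = 3L)
      for (p in starts) {
        codon <- paste0(s[p], s[p + 1L], s[p + 2L])
        if (p != upstreamStart && codon == "ATG") {
          free <- setdiff(p + 0:2, fixed)
          if (length(free)) s[free[length(free)]] <- "C"
        }
        if (p >= upstreamStart && codon %in% c("TAA", "TAG", "TGA")) {
          free <- setdiff(p + 0:2, fixed)
          if (length(free)) s[free[1L]] <- "C"
        }
      }
    }
    paste0(s, collapse = "")
  })
}

#' Generate a synthetic accession panel
#'
#' Draws a haplotype for each accession at the configured frequencies,
#' substitutes its alleles into the reference at the panel positions, then
#' applies per-base miscalls (a uniformly chosen different base, at every
#' column) and per-SNP-site no-calls ("N"). Population labels, a growth-habit
#' phenotype (independent of haplotype) and collection-site coordinates are
#' drawn per accession. The truth table records every accession's pre-noise
#' haplotype and its true monthly climate means.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param seed integer seed governing every draw.
#' @return A list with elements \code{alignment}
#'   (\code{Biostrings::DNAStringSet}), \code{reference} (character),
#'   \code{populations} (data.frame: accession, population, growth_habit,
#'   longitude, latitude) and \code{truth} (data.frame: accession, haplotype,
#'   population and 12 true monthly means).
#' @examples
#' sim <- generatePanel(simulationConfig(nAccessions = 20), seed = 7)
#' length(sim$alignment)
#' @export
generatePanel <- function(config, seed = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  withSeed(seed, {
    n <- config$nAccessions
    L <- config$ampliconLength
    pan <- config$panel
    labs <- rownames(config$hapAlleles)
    ref <- generateReference(L, seed = NULL, panel = pan)
    refv <- strsplit(ref, "")[[1L]]
    hapIdx <- sample.int(length(labs), n, replace = TRUE,
                         prob = config$hapFreqs)
    pop <- ifelse(rbinom(n, 1L, config$wildFraction[hapIdx]) == 1L,
                  "wild", "landrace")
    seqs <- matrix(rep(refv, each = n), nrow = n)
    seqs[, pan@positions] <- config$hapAlleles[hapIdx, , drop = FALSE]
    if (config$miscallRate > 0) {
      hit <- which(matrix(runif(n * L) < config$miscallRate, n, L))
      if (length(hit)) {
        cur <- seqs[hit]
        seqs[hit] <- vapply(cur, function(b)
          sample(setdiff(.BASES, b), 1L), character(1L))
      }
    }
    if (config$missingRate > 0 && length(pan@positions)) {
      sub <- seqs[, pan@positions, drop = FALSE]
      sub[matrix(runif(n * length(pan@positions)) < config$missingRate,
                 n, length(pan@positions))] <- "N"
      seqs[, pan@positions] <- sub
    }
    ids <- sprintf("acc%04d", seq_len(n))
    aln <- Biostrings::DNAStringSet(apply(seqs, 1L, paste0, collapse = ""))
    names(aln) <- ids
    truthClim <- sweep(config$climateShift[labs[hapIdx], , drop = FALSE],
                       2L, config$climateBase, "+")
    colnames(truthClim) <- paste0("mean_", .months())
    populations <- data.frame(
      accession = ids, population = pop,
      growth_habit = sample(c("winter", "spring"), n, replace = TRUE),
      longitude = runif(n, 34, 48), latitude = runif(n, 31, 38),
      stringsAsFactors = FALSE)
    truth <- cbind(
      data.frame(accession = ids, haplotype = labs[hapIdx],
                 population = pop, stringsAsFactors = FALSE),
      as.data.frame(truthClim, row.names = FALSE))
    list(alignment = aln, reference = ref,
         populations = populations, truth = truth)
  })
}

#' Generate per-accession monthly precipitation
#'
#' Draws 12 monthly precipitation values per accession around the configured
#' monthly base means plus that accession's haplotype-linked shift, with a
#' common standard deviation; negative draws are truncated at zero.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param truth truth table from \code{\link{generatePanel}} (columns
#'   \code{accession}, \code{haplotype}, \code{population}).
#' @param seed integer seed.
#' @return A climate data.frame: accession, haplotype, population and the 12
#'   monthly columns Jan..Dec (mm).
#' @export
generateClimate <- function(config, truth, seed = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (config$climateSd < 0) stop("config error: negative climate sd")
  if (!all(truth$haplotype %in% rownames(config$climateShift)))
    stop("config error: climateShift missing for some haplotype labels")
  withSeed(seed, {
    n <- nrow(truth)
    mu <- sweep(config$climateShift[truth$haplotype, , drop = FALSE],
                2L, config$climateBase, "+")
    vals <- mu + matrix(rnorm(n * 12L, sd = config$climateSd), n, 12L)
    vals <- pmax(vals, 0)
    colnames(vals) <- .months()
    cbind(data.frame(accession = truth$accession,
                     haplotype = truth$haplotype,
                     population = truth$population,
                     stringsAsFactors = FALSE),
          as.data.frame(vals, row.names = FALSE))
  })
}

#' Write a simulated panel to disk
#'
#' Writes the alignment as FASTA and the population, truth and (optionally)
#' climate tables as headed CSV.
#'
#' @param sim result of \code{\link{generatePanel}}.
#' @param dir output directory (created if needed).
#' @param climate optional climate data.frame from
#'   \code{\link{generateClimate}}.
#' @return Invisibly, the paths written.
#' @export
writeSimulation <- function(sim, dir, climate = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(alignment = file.path(dir, "alignment.fasta"),
             populations = file.path(dir, "populations.csv"),
             truth = file.path(dir, "truth.csv"))
  Biostrings::writeXStringSet(sim$alignment, paths[["alignment"]])
  write.csv(sim$populations, paths[["populations"]], row.names = FALSE)
  write.csv(sim$truth, paths[["truth"]], row.names = FALSE)
  if (!is.null(climate)) {
    paths <- c(paths, climate = file.path(dir, "climate.csv"))
    write.csv(climate, paths[["climate"]], row.names = FALSE)
  }
  invisible(paths)
}
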