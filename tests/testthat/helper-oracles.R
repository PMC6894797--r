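# Independent oracles and small fixture builders shared across the suite.

# upper-tail binomial probability by direct summation of the mass function
binomTailOracle <- function(k, n, p) {
  if (k > n) return(0)
  sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
}

# Hamming distance written independently of the package
hamOracle <- function(a, b) sum(a != b)

# Prim's algorithm MST total weight over rows of a character matrix,
# independent of the package's Kruskal construction
primCostOracle <- function(v) {
  n <- nrow(v)
  if (n < 2L) return(0L)
  d <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- hamOracle(v[i, ], v[j, ])
  inTree <- c(TRUE, rep(FALSE, n - 1L))
  best <- d[1L, ]
  cost <- 0L
  for (step in seq_len(n - 1L)) {
    cand <- which(!inTree)
    nxt <- cand[which.min(best[cand])]
    cost <- cost + best[nxt]
    inTree[nxt] <- TRUE
    best <- pmin(best, d[nxt, ])
  }
  cost
}

# exhaustive Steiner-augmentation oracle: minimum MST cost over the observed
# vectors plus any subset (size <= maxExtra) of candidate vectors drawn from
# the per-site observed alleles
steinerOracle <- function(v, maxExtra = 2L) {
  alleles <- lapply(seq_len(ncol(v)), function(j) unique(v[, j]))
  cand <- as.matrix(expand.grid(alleles, stringsAsFactors = FALSE))
  keys <- apply(v, 1L, paste0, collapse = "")
  ckeys <- apply(cand, 1L, paste0, collapse = "")
  cand <- cand[!(ckeys %in% keys), , drop = FALSE]
  best <- primCostOracle(v)
  for (k in seq_len(min(maxExtra, nrow(cand)))) {
    for (sub in combn(nrow(cand), k, simplify = FALSE)) {
      aug <- rbind(v, cand[sub, , drop = FALSE])
      best <- min(best, primCostOracle(aug))
    }
  }
  best
}

# random panel of distinct binary-allele haplotype vectors
randomBinaryPanel <- function(nHap, nSites) {
  repeat {
    v <- matrix(sample(c("A", "C"), nHap * nSites, replace = TRUE),
                nHap, nSites)
    if (!anyDuplicated(apply(v, 1L, paste0, collapse = ""))) break
  }
  rownames(v) <- paste0("h", seq_len(nHap))
  v
}

# expand the haplotype catalogue into one synthetic accession record per
# counted accession (ids carry the population), as genotype + population
# tables ready for buildHaplotypeTable
expandCatalogue <- function(tab) {
  al <- hapAlleles(tab)
  cnt <- hapCounts(tab)
  rows <- list(); pops <- list()
  id <- 0L
  for (i in seq_len(nrow(cnt))) {
    for (p in c("wild", "landrace")) {
      k <- cnt[[p]][i]
      if (k == 0L) next
      for (r in seq_len(k)) {
        id <- id + 1L
        rows[[id]] <- al[i, ]
        pops[[id]] <- p
      }
    }
  }
  g <- do.call(rbind, rows)
  ids <- sprintf("acc%04d", seq_len(id))
  geno <- data.frame(accession = ids, status = "complete",
                     stringsAsFactors = FALSE)
  gdf <- as.data.frame(g, stringsAsFactors = FALSE)
  names(gdf) <- paste0("p", snpPositions(tab))
  list(genotypes = cbind(geno, gdf),
       populations = data.frame(accession = ids,
                                population = unlist(pops),
                                stringsAsFactors = FALSE))
}

# thresholds lax enough to admit every segregating biallelic column
laxThresholds <- function() callThresholds(mediumMaxP = 1, mediumMinCov = 0)
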