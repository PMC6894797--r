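#' Accessors for hapdiver classes
#'
#' \code{snpPositions} and \code{alleleMatrix} expose a
#' \linkS4class{SnpPanel}; \code{hapLabels}, \code{hapAlleles} and
#' \code{hapCounts} expose a \linkS4class{HaplotypeTable};
#' \code{networkNodes} and \code{networkEdges} expose a
#' \linkS4class{HaplotypeNetwork}.
#'
#' @param x the object.
#' @return The requested component (vector, matrix or data.frame).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("snpPositions", function(x) standardGeneric("snpPositions"))
#' @rdname accessors
#' @export
setGeneric("alleleMatrix", function(x) standardGeneric("alleleMatrix"))
#' @rdname accessors
#' @export
setGeneric("hapLabels", function(x) standardGeneric("hapLabels"))
#' @rdname accessors
#' @export
setGeneric("hapAlleles", function(x) standardGeneric("hapAlleles"))
#' @rdname accessors
#' @export
setGeneric("hapCounts", function(x) standardGeneric("hapCounts"))
#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname minimumSpanningNetwork
#' @export
setGeneric("minimumSpanningNetwork",
  function(x, epsilon = 0, ...) standardGeneric("minimumSpanningNetwork"))

#' @rdname medianJoining
#' @export
setGeneric("medianJoining",
  function(x, epsilon = 0, ...) standardGeneric("medianJoining"))

#' @rdname accessors
#' @export
setMethod("snpPositions", "SnpPanel", function(x) x@positions)
#' @rdname accessors
#' @export
setMethod("alleleMatrix", "SnpPanel", function(x) {
  m <- x@alleles
  rownames(m) <- as.character(x@positions)
  m
})
#' @rdname accessors
#' @export
setMethod("snpPositions", "HaplotypeTable", function(x) x@panel@positions)
#' @rdname accessors
#' @export
setMethod("hapLabels", "HaplotypeTable", function(x) rownames(x@alleles))
#' @rdname accessors
#' @export
setMethod("hapAlleles", "HaplotypeTable", function(x) x@alleles)
#' @rdname accessors
#' @export
setMethod("hapCounts", "HaplotypeTable", function(x)
  data.frame(haplotype = rownames(x@alleles), wild = x@wild,
             landrace = x@landrace, total = x@wild + x@landrace,
             row.names = NULL, stringsAsFactors = FALSE))
#' @rdname accessors
#' @export
setMethod("networkNodes", "HaplotypeNetwork", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("networkEdges", "HaplotypeNetwork", function(x) x@edges)

setMethod("show", "SnpPanel", function(object) {
  cat("SnpPanel with", length(object@positions), "biallelic positions\n")
  if (length(object@positions)) {
    pair <- paste0(object@alleles[, 1L], "/", object@alleles[, 2L])
    cat(" ", paste(object@positions, pair, sep = ":", collapse = "  "), "\n")
  }
})

setMethod("show", "HaplotypeTable", function(object) {
  cat("HaplotypeTable:", nrow(object@alleles), "haplotypes over",
      length(object@panel@positions), "SNPs;",
      sum(object@wild), "wild +", sum(object@landrace), "landrace =",
      sum(object@wild) + sum(object@landrace), "accessions\n")
  df <- cbind(as.data.frame(object@alleles, stringsAsFactors = FALSE),
              wild = object@wild, landrace = object@landrace,
              total = object@wild + object@landrace)
  print(utils::head(df, 8L))
  if (nrow(df) > 8L) cat("  ...", nrow(df) - 8L, "more haplotypes\n")
})

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel on a", object@ampliconLength, "nt amplicon\n")
  cat("  CDS start:", object@cdsStart, "\n")
  if (!is.na(object@intronStart))
    cat("  intron:", object@intronStart, "-",
        object@intronStart + object@intronLength - 1L,
        paste0("(", object@intronLength, " nt)"), "\n")
  else if (!is.na(object@intronLength))
    cat("  intron length:", object@intronLength, "nt (placement unset)\n")
  else cat("  intron: undetermined\n")
  if (length(object@alternativeStarts))
    cat("  alternative starts:",
        paste(object@alternativeStarts, collapse = ", "), "\n")
})

setMethod("show", "HaplotypeNetwork", function(object) {
  nm <- sum(object@nodes$median)
  cat("HaplotypeNetwork:", nrow(object@nodes) - nm, "observed +",
      nm, "median nodes,", nrow(object@edges), "edges (epsilon =",
      object@epsilon, ")\n")
})
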