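# pairwise Hamming distance matrix over rows of a character matrix
.hamMat <- function(v) {
  n <- nrow(v)
  d <- matrix(0L, n, n)
  if (n > 1L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- sum(v[i, ] != v[j, ])
  d
}

# deterministic Kruskal MST; returns edge index pairs and the total weight.
# Ties are broken by (weight, lexicographic endpoint vector keys).
.mstEdges <- function(v, d = .hamMat(v)) {
  n <- nrow(v)
  if (n < 2L) return(list(edges = cbind(integer(), integer()), cost = 0L))
  key <- .vecKey(v)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  lo <- pmin(key[idx[, 1L]], key[idx[, 2L]])
  hi <- pmax(key[idx[, 1L]], key[idx[, 2L]])
  ord <- order(d[idx], lo, hi)
  idx <- idx[ord, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  picked <- matrix(integer(), 0L, 2L)
  cost <- 0L
  for (r in seq_len(nrow(idx))) {
    a <- find(idx[r, 1L]); b <- find(idx[r, 2L])
    if (a != b) {
      parent[a] <- b
      picked <- rbind(picked, idx[r, , drop = FALSE])
      cost <- cost + d[idx[r, 1L], idx[r, 2L]]
      if (nrow(picked) == n - 1L) break
    }
  }
  list(edges = picked, cost = cost)
}

.mstCost <- function(v) .mstEdges(v)$cost

# minimax connection levels: lambda[i,j] = max edge weight on the MST path,
# the single-linkage merge level of i and j
.minimaxLevels <- function(v, d = .hamMat(v)) {
  n <- nrow(v)
  lam <- matrix(0L, n, n)
  if (n < 2L) return(lam)
  mst <- .mstEdges(v, d)$edges
  adj <- vector("list", n)
  for (r in seq_len(nrow(mst))) {
    i <- mst[r, 1L]; j <- mst[r, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  for (s in seq_len(n)) {
    seen <- rep(FALSE, n); seen[s] <- TRUE
    queue <- s
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[u]]) if (!seen[w]) {
        seen[w] <- TRUE
        lam[s, w] <- max(lam[s, u], d[u, w])
        queue <- c(queue, w)
      }
    }
  }
  lam
}

# MSN edge list over a vector set: all pairs within epsilon of their
# single-linkage merge level
.msnEdges <- function(v, epsilon = 0) {
  d <- .hamMat(v)
  lam <- .minimaxLevels(v, d)
  idx <- which(upper.tri(d) & d <= lam + epsilon, arr.ind = TRUE)
  cbind(idx, weight = d[idx])
}

.makeNetwork <- function(v, observed, counts, epsilon) {
  ids <- rownames(v)
  ed <- .msnEdges(v, epsilon)
  edges <- data.frame(from = ids[ed[, 1L]], to = ids[ed[, 2L]],
                      weight = as.integer(ed[, 3L]),
                      stringsAsFactors = FALSE)
  nodes <- data.frame(id = ids, haplotype = .vecKey(v),
                      wild = counts$wild, landrace = counts$landrace,
                      total = counts$wild + counts$landrace,
                      median = !observed, stringsAsFactors = FALSE)
  new("HaplotypeNetwork", nodes = nodes, edges = edges, alleles = v,
      epsilon = as.numeric(epsilon))
}

.prepVectors <- function(x) {
  v <- as.matrix(x)
  if (anyNA(v)) stop("input error: vectors must be complete")
  if (is.null(rownames(v))) rownames(v) <- as.character(seq_len(nrow(v)))
  if (anyDuplicated(.vecKey(v)))
    stop("input error: duplicate haplotype vectors")
  v
}

.zeroCounts <- function(v, counts) {
  if (is.null(counts))
    counts <- data.frame(wild = rep(0L, nrow(v)),
                         landrace = rep(0L, nrow(v)))
  counts
}

#' Minimum spanning network of haplotype vectors
#'
#' Builds the epsilon-relaxed minimum spanning network: the union of every
#' minimum spanning tree of the Hamming-distance graph, plus any edge whose
#' weight is within \code{epsilon} of the level at which its endpoints'
#' clusters merge under single linkage. With \code{epsilon = 0} this is the
#' classical MSN; larger epsilon retains progressively more alternative
#' links. Construction is deterministic: edges are processed by weight with
#' lexicographic endpoint-vector tie-breaks.
#'
#' @param x a character matrix of complete allele vectors (rows named by
#'   haplotype label) or a \linkS4class{HaplotypeTable}.
#' @param epsilon non-negative relaxation parameter (default 0).
#' @param counts optional data.frame with \code{wild}/\code{landrace}
#'   counts aligned with the rows (matrix method only).
#' @param ... passed between methods.
#' @return A \linkS4class{HaplotypeNetwork}.
#' @examples
#' minimumSpanningNetwork(ckx2HaplotypeTable())
#' @name minimumSpanningNetwork
NULL

#' @rdname minimumSpanningNetwork
#' @export
setMethod("minimumSpanningNetwork", "matrix",
  function(x, epsilon = 0, counts = NULL, ...) {
    v <- .prepVectors(x)
    .makeNetwork(v, observed = rep(TRUE, nrow(v)),
                 .zeroCounts(v, counts), epsilon)
  })

#' @rdname minimumSpanningNetwork
#' @export
setMethod("minimumSpanningNetwork", "HaplotypeTable",
  function(x, epsilon = 0, ...) {
    minimumSpanningNetwork(x@alleles, epsilon,
      counts = data.frame(wild = x@wild, landrace = x@landrace))
  })

# positionwise majority of three vectors; ties (all distinct) fall back to
# the first vector's base, keeping the operation deterministic
.medianVector <- function(a, b, c) {
  vapply(seq_along(a), function(k) {
    tri <- c(a[k], b[k], c[k])
    tab <- table(tri)
    if (max(tab) >= 2L) names(tab)[which.max(tab)] else a[k]
  }, character(1L))
}

#' Median-joining haplotype network
#'
#' Augments the observed haplotypes with inferred median vectors: repeatedly
#' builds the minimum spanning network, forms the positionwise majority
#' (median) vector of every connected triplet, and adds the candidate median
#' that most reduces the total spanning cost of the node set, stopping at a
#' fixpoint. Median nodes of degree below three that lie on no shortest
#' path between observed haplotypes are pruned. Median nodes carry count 0
#' and \code{median = TRUE}.
#'
#' @param x a character matrix of complete allele vectors or a
#'   \linkS4class{HaplotypeTable}.
#' @param epsilon non-negative relaxation parameter (default 0).
#' @param counts optional wild/landrace counts (matrix method only).
#' @param maxIter cap on median-addition rounds (diagnostic error beyond).
#' @param ... passed between methods.
#' @return A \linkS4class{HaplotypeNetwork} over observed plus median nodes.
#' @examples
#' net <- medianJoining(ckx2HaplotypeTable())
#' networkNodes(net)
#' @name medianJoining
NULL

#' @rdname medianJoining
#' @export
setMethod("medianJoining", "matrix",
  function(x, epsilon = 0, counts = NULL, maxIter = 50L, ...) {
    v <- .prepVectors(x)
    counts <- .zeroCounts(v, counts)
    nObs <- nrow(v)
    cur <- v
    nMed <- 0L
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > maxIter)
        stop("diagnostic error: median joining did not converge in ",
             maxIter, " rounds")
      ed <- .msnEdges(cur, epsilon)
      if (!nrow(ed)) break
      adj <- vector("list", nrow(cur))
      for (r in seq_len(nrow(ed))) {
        i <- ed[r, 1L]; j <- ed[r, 2L]
        adj[[i]] <- c(adj[[i]], j)
        adj[[j]] <- c(adj[[j]], i)
      }
      seen <- character()
      cands <- list()
      for (u in seq_len(nrow(cur))) {
        nb <- adj[[u]]
        if (length(nb) < 2L) next
        for (pair in utils::combn(sort(nb), 2L, simplify = FALSE)) {
          med <- .medianVector(cur[u, ], cur[pair[1L], ], cur[pair[2L], ])
          k <- paste0(med, collapse = "")
          if (k %in% seen) next
          seen <- c(seen, k)
          cands[[length(cands) + 1L]] <- med
        }
      }
      curKeys <- .vecKey(cur)
      cands <- cands[!vapply(cands, function(m)
        paste0(m, collapse = "") %in% curKeys, logical(1L))]
      if (!length(cands)) break
      base <- .mstCost(cur)
      deltas <- vapply(cands, function(m)
        .mstCost(rbind(cur, m)) - base, numeric(1L))
      best <- min(deltas)
      if (best >= 0) break
      pick <- which(deltas == best)
      keys <- vapply(cands[pick], paste0, character(1L), collapse = "")
      chosen <- cands[[pick[order(keys)[1L]]]]
      nMed <- nMed + 1L
      cur <- rbind(cur, chosen)
      rownames(cur)[nrow(cur)] <- paste0("mv", nMed)
    }
    cur <- .pruneMedians(cur, nObs, epsilon)
    obs <- c(rep(TRUE, nObs), rep(FALSE, nrow(cur) - nObs))
    allCounts <- data.frame(
      wild = c(counts$wild, rep(0L, nrow(cur) - nObs)),
      landrace = c(counts$landrace, rep(0L, nrow(cur) - nObs)))
    .makeNetwork(cur, obs, allCounts, epsilon)
  })

#' @rdname medianJoining
#' @export
setMethod("medianJoining", "HaplotypeTable",
  function(x, epsilon = 0, maxIter = 50L, ...) {
    medianJoining(x@alleles, epsilon,
      counts = data.frame(wild = x@wild, landrace = x@landrace),
      maxIter = maxIter)
  })

# drop median nodes of degree < 3 lying on no shortest path between
# observed nodes; repeat until stable
.pruneMedians <- function(cur, nObs, epsilon) {
  repeat {
    n <- nrow(cur)
    if (n == nObs) return(cur)
    ed <- .msnEdges(cur, epsilon)
    deg <- tabulate(c(ed[, 1L], ed[, 2L]), nbins = n)
    g <- igraph::graph_from_data_frame(
      data.frame(from = ed[, 1L], to = ed[, 2L]),
      directed = FALSE, vertices = data.frame(name = seq_len(n)))
    dist <- igraph::distances(g, weights = ed[, 3L])
    drop <- integer()
    for (m in (nObs + 1L):n) {
      if (deg[m] >= 3L) next
      onPath <- FALSE
      for (i in seq_len(nObs - 1L)) {
        for (j in (i + 1L):nObs) {
          if (dist[i, m] + dist[m, j] == dist[i, j]) { onPath <- TRUE; break }
        }
        if (onPath) break
      }
      if (!onPath) drop <- c(drop, m)
    }
    if (!length(drop)) return(cur)
    cur <- cur[-drop, , drop = FALSE]
  }
}

#' Export a haplotype network
#'
#' Writes the network as GML (node attributes: haplotype string, wild,
#' landrace, total, median flag; edge attribute: weight) or as a CSV edge
#' list with an accompanying \code{*_nodes.csv} table. Both formats
#' round-trip losslessly through \code{\link{importNetwork}}.
#'
#' @param network a \linkS4class{HaplotypeNetwork}.
#' @param path output file path.
#' @param format "gml" or "edgelist".
#' @return Invisibly, the path(s) written.
#' @export
exportNetwork <- function(network, path, format = c("gml", "edgelist")) {
  format <- match.arg(format)
  nd <- network@nodes
  ed <- network@edges
  if (format == "gml") {
    g <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = nd)
    igraph::V(g)$median <- as.integer(nd$median)
    igraph::write_graph(g, path, format = "gml")
    return(invisible(path))
  }
  npath <- sub("(\\.[^.]+)?$", "_nodes.csv", path)
  write.csv(ed, path, row.names = FALSE)
  write.csv(transform(nd, median = as.integer(median)), npath,
            row.names = FALSE)
  invisible(c(path, npath))
}

#' Import a haplotype network written by exportNetwork
#'
#' @param path file path (for "edgelist", the edge CSV; the nodes CSV is
#'   located alongside).
#' @param format "gml" or "edgelist".
#' @return A \linkS4class{HaplotypeNetwork}.
#' @export
importNetwork <- function(path, format = c("gml", "edgelist")) {
  format <- match.arg(format)
  if (format == "gml") {
    g <- igraph::read_graph(path, format = "gml")
    nd <- data.frame(id = igraph::V(g)$name,
                     haplotype = igraph::V(g)$haplotype,
                     wild = as.integer(igraph::V(g)$wild),
                     landrace = as.integer(igraph::V(g)$landrace),
                     total = as.integer(igraph::V(g)$total),
                     median = igraph::V(g)$median > 0,
                     stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(g)
    ed <- data.frame(from = el[, 1L], to = el[, 2L],
                     weight = as.integer(igraph::E(g)$weight),
                     stringsAsFactors = FALSE)
  } else {
    npath <- sub("(\\.[^.]+)?$", "_nodes.csv", path)
    ed <- read.csv(path, stringsAsFactors = FALSE)
    nd <- read.csv(npath, colClasses = c(id = "character",
                                         haplotype = "character"))
    nd$median <- nd$median > 0
    ed$from <- as.character(ed$from)
    ed$to <- as.character(ed$to)
  }
  v <- do.call(rbind, strsplit(nd$haplotype, ""))
  rownames(v) <- nd$id
  new("HaplotypeNetwork", nodes = nd, edges = ed, alleles = v,
      epsilon = NA_real_)
}
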