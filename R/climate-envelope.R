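.monthCols <- function(clim) {
  miss <- setdiff(.months(), names(clim))
  if (length(miss))
    stop("climate table must carry the 12 monthly columns Jan..Dec ",
         "(missing: ", paste(miss, collapse = ", "), ")")
  .months()
}

#' Per-haplotype monthly precipitation summaries
#'
#' Means and standard errors of monthly precipitation per haplotype group,
#' in calendar order. Groups with a single accession get a standard error
#' of 0 and are flagged rather than dropped; requested haplotypes absent
#' from the data are excluded with a warning.
#'
#' @param clim climate data.frame: \code{accession}, \code{haplotype} and
#'   monthly columns \code{Jan}..\code{Dec} (mm).
#' @param haplotypes labels to summarise (default: all present).
#' @param minN groups below this size are flagged \code{lowN}.
#' @return A data.frame: \code{haplotype}, \code{month} (ordered factor),
#'   \code{n}, \code{mean}, \code{se}, \code{lowN}.
#' @export
monthlySummary <- function(clim, haplotypes = NULL, minN = 3L) {
  mc <- .monthCols(clim)
  if (is.null(haplotypes)) haplotypes <- sort(unique(clim$haplotype))
  absent <- setdiff(haplotypes, clim$haplotype)
  if (length(absent)) {
    warning("empty haplotype group(s) excluded: ",
            paste(absent, collapse = ", "))
    haplotypes <- setdiff(haplotypes, absent)
  }
  out <- do.call(rbind, lapply(haplotypes, function(h) {
    sub <- clim[clim$haplotype == h, mc, drop = FALSE]
    n <- nrow(sub)
    mu <- colMeans(sub)
    se <- if (n > 1L) apply(sub, 2L, sd) / sqrt(n) else rep(0, 12L)
    data.frame(haplotype = h, month = mc, n = n, mean = unname(mu),
               se = unname(se), lowN = n < minN,
               stringsAsFactors = FALSE)
  }))
  out$month <- factor(out$month, levels = .months(), ordered = TRUE)
  rownames(out) <- NULL
  out
}

#' Default bimonthly pairing (Oct/Nov .. Aug/Sep)
#'
#' The six two-month windows starting at October, matching the seasonal
#' windows used for the bimonthly precipitation analysis.
#'
#' @return A list of six month-name pairs.
#' @export
bimonthlyPairing <- function() {
  list(c("Oct", "Nov"), c("Dec", "Jan"), c("Feb", "Mar"),
       c("Apr", "May"), c("Jun", "Jul"), c("Aug", "Sep"))
}

#' Aggregate monthly precipitation into bimonthly windows
#'
#' Sums each accession's precipitation over the paired months. The pairing
#' must cover each of the 12 months exactly once.
#'
#' @param clim climate data.frame with monthly columns \code{Jan}..\code{Dec}.
#' @param pairing list of month-name pairs (default
#'   \code{\link{bimonthlyPairing}}).
#' @return The input data.frame with the 12 monthly columns replaced by 6
#'   aggregate columns named like \code{"Oct/Nov"}.
#' @export
bimonthlyAggregate <- function(clim, pairing = bimonthlyPairing()) {
  mc <- .monthCols(clim)
  flat <- unlist(pairing)
  if (length(flat) != 12L || anyDuplicated(flat) ||
      !setequal(flat, .months()))
    stop("config error: pairing must cover each month exactly once")
  agg <- vapply(pairing, function(p) clim[[p[1L]]] + clim[[p[2L]]],
                numeric(nrow(clim)))
  if (is.null(dim(agg))) agg <- matrix(agg, nrow = nrow(clim))
  colnames(agg) <- vapply(pairing, paste, character(1L), collapse = "/")
  cbind(clim[, setdiff(names(clim), mc), drop = FALSE],
        as.data.frame(agg, row.names = NULL))
}

#' Principal components analysis of a climate matrix
#'
#' Eigendecomposition of the covariance matrix of column-centred data (the
#' variables share units, mm, so the covariance rather than correlation
#' matrix is the default; set \code{scale. = TRUE} for correlation-based
#' PCA). Scores are the projections onto the eigenvectors; the variance
#' fraction of each component is its eigenvalue over the trace. Signs are
#' fixed so the largest-magnitude loading of each component is positive.
#'
#' @param x numeric matrix (rows = accessions, columns = variables), at
#'   least 3 rows and 2 columns, no missing values.
#' @param scale. divide each column by its standard deviation first.
#' @return A list of class \code{OrdinationResult}: \code{scores},
#'   \code{loadings}, \code{varFrac}, \code{center}, \code{sdev}.
#' @export
climatePca <- function(x, scale. = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 3L || ncol(x) < 2L)
    stop("at least 3 rows and 2 columns required")
  if (anyNA(x)) stop("missing values not allowed")
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  if (scale.) {
    s <- apply(x, 2L, sd)
    if (any(s == 0)) stop("zero-variance error: constant column")
    xc <- sweep(xc, 2L, s, "/")
  }
  S <- cov(xc)
  if (all(abs(S) < .Machine$double.eps * 100))
    stop("zero-variance error: constant matrix")
  eig <- eigen(S, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  for (k in seq_len(ncol(vecs))) {   # sign convention
    m <- which.max(abs(vecs[, k]))
    if (vecs[m, k] < 0) vecs[, k] <- -vecs[, k]
  }
  scores <- xc %*% vecs
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  colnames(vecs) <- colnames(scores)
  rownames(vecs) <- colnames(x)
  structure(list(scores = scores, loadings = vecs,
                 varFrac = vals / sum(vals), center = ctr,
                 sdev = sqrt(vals)),
            class = "OrdinationResult")
}

#' Gaussian confidence ellipse of 2-D scores
#'
#' The ellipse containing the requested probability mass of a bivariate
#' normal with the group's sample mean and covariance: Mahalanobis radius
#' squared equal to the chi-squared quantile at \code{level} with 2 degrees
#' of freedom. Semi-axes are the square roots of the covariance eigenvalues
#' scaled by that quantile.
#'
#' @param scores numeric matrix with 2 columns and at least 3 rows.
#' @param level coverage level in [0, 1); \code{level = 0} degenerates to
#'   the mean point.
#' @return A list: \code{center}, \code{cov}, \code{radiusSq},
#'   \code{semiAxes} (major, minor), \code{angle} (radians, major axis vs
#'   first coordinate), \code{level}.
#' @export
confidenceEllipse <- function(scores, level = 0.95) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2L || nrow(scores) < 3L)
    stop("scores must have 2 columns and at least 3 rows")
  if (level < 0 || level >= 1) stop("level must lie in [0, 1)")
  ctr <- colMeans(scores)
  S <- cov(scores)
  if (abs(det(S)) < 1e-12 * max(1, abs(S[1, 1] * S[2, 2])))
    stop("degenerate-ellipse error: singular covariance")
  r2 <- qchisq(level, df = 2L)
  eig <- eigen(S, symmetric = TRUE)
  list(center = ctr, cov = S, radiusSq = r2,
       semiAxes = sqrt(eig$values * r2),
       angle = atan2(eig$vectors[2L, 1L], eig$vectors[1L, 1L]),
       level = level)
}

#' Test points for ellipse membership
#'
#' @param ellipse result of \code{\link{confidenceEllipse}}.
#' @param points numeric matrix with 2 columns.
#' @return Logical vector: point inside (or on) the ellipse.
#' @export
inEllipse <- function(ellipse, points) {
  points <- as.matrix(points)
  mahalanobis(points, ellipse$center, ellipse$cov) <= ellipse$radiusSq
}
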