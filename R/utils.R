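#' @import methods
#' @importFrom stats pbinom qchisq rnorm rbinom runif sd cov mahalanobis
#' @importFrom utils read.csv write.csv combn head
NULL

# canonical nucleotide alphabet; anything else (N, IUPAC ambiguity, gaps)
# collapses to "no call"
.BASES <- c("A", "C", "G", "T")

.isBase <- function(x) x %in% .BASES

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs \code{expr} with the random number generator seeded at \code{seed},
#' then restores the caller's RNG state, so seeded operations leave no trace
#' in the global stream. A \code{NULL} seed evaluates \code{expr} against the
#' current stream unchanged.
#'
#' @param seed integer seed or \code{NULL}.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer or NULL")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# collapse an allele vector to a compact key (used for dedup / ordering)
.vecKey <- function(m) apply(m, 1L, paste0, collapse = "")

.months <- function() month.abb
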