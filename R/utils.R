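#' Evaluate an expression with a local RNG seed
#'
#' All stochastic operations in the package draw their randomness from an
#' explicit per-call seed; the caller's RNG state is saved and restored so no
#' global state leaks between calls.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Triangular-lattice spacing for a target density
#'
#' A triangular (hexagonal-packing) lattice with point spacing \eqn{s} has
#' density \eqn{2/(\sqrt{3} s^2)}; this inverts that relation.
#'
#' @param densityDeg2 density in cells/degree^2 (or any unit; the spacing is
#'   returned in the corresponding length unit).
#' @return lattice spacing \eqn{s = \sqrt{2/(\sqrt{3}\,d)}}.
#' @export
#' @examples
#' latticeSpacing(461.88)  # ~0.05 degrees
latticeSpacing <- function(densityDeg2) {
  stopifnot(is.numeric(densityDeg2), densityDeg2 > 0)
  sqrt(2 / (sqrt(3) * densityDeg2))
}

#' Density of a triangular lattice with a given spacing
#' @param spacing lattice spacing.
#' @return density \eqn{2/(\sqrt{3} s^2)}.
#' @export
hexLatticeDensity <- function(spacing) {
  stopifnot(is.numeric(spacing), spacing > 0)
  2 / (sqrt(3) * spacing^2)
}

## Shoelace (surveyor's) polygon area; vertices in order, not closed.
shoelaceArea <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

## Pairwise Euclidean distances between two n x 2 coordinate matrices.
crossDist <- function(a, b) {
  da <- outer(a[, 1], b[, 1], "-")
  db <- outer(a[, 2], b[, 2], "-")
  sqrt(da * da + db * db)
}

## Sidak family-wise adjustment for m comparisons.
#' Sidak multiple-comparison adjustment
#'
#' @param p vector of raw p-values.
#' @param m number of comparisons in the family (default \code{length(p)}).
#' @return adjusted p-values \eqn{1 - (1 - p)^m}.
#' @export
sidakAdjust <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), m >= 1)
  pmin(1, 1 - (1 - p)^m)
}

## Coerce a CellSet or 2-column matrix/data.frame to an n x 2 matrix.
asCoords <- function(x) {
  if (is(x, "CellSet")) return(cellCoords(x))
  if (is(x, "ConeMosaic")) stop("supply ConeMosaic points in a pixel frame explicitly")
  m <- as.matrix(x)
  stopifnot(ncol(m) == 2)
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y")
  m
}
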