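# Spearman rank correlation machinery. All triplet scores are built from
# rank correlations so that they are invariant under strictly monotone
# transforms of the inputs. Ties receive average ranks.

# rank each row, average ties
rank_rows <- function(m) {
  m <- as.matrix(m)
  t(apply(m, 1L, rank, ties.method = "average"))
}

# center and L2-normalize rows; constant rows become all-zero so that any
# correlation involving them is 0 (flagged degenerate by callers)
standardize_rows <- function(r) {
  r <- r - rowMeans(r)
  s <- sqrt(rowSums(r * r))
  s[s == 0] <- Inf
  r / s
}

# Spearman correlation matrix between rows of a and rows of b (both
# entities x metacells, shared metacell order). Constant rows give 0.
spearman_cor_rows <- function(a, b) {
  ra <- standardize_rows(rank_rows(a))
  rb <- standardize_rows(rank_rows(b))
  out <- tcrossprod(ra, rb)
  pmin(pmax(out, -1), 1)
}

#' Spearman rank correlation of two vectors
#'
#' Pearson correlation of average-ranked values. If either vector is
#' constant the correlation is undefined; 0 is returned with attribute
#' `degenerate = TRUE` rather than NA, so degeneracies propagate as
#' flagged zero scores.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  rho <- stats::cor(rank(x, ties.method = "average"),
                    rank(y, ties.method = "average"))
  min(max(rho, -1), 1)
}

#' First-order Spearman partial correlation
#'
#' Association between `x` and `y` with the (rank-linear) effect of `z`
#' removed, computed by the first-order recursion on rank correlations:
#' \deqn{\rho_{xy;z} = \frac{\rho_{xy} - \rho_{xz}\rho_{yz}}
#'   {\sqrt{(1-\rho_{xz}^2)(1-\rho_{yz}^2)}}}
#' This equals correlating the residuals of least-squares fits of the
#' ranks of `x` and `y` on the ranks of `z`. If `z` is constant the plain
#' Spearman correlation is returned; if `x` or `y` is rank-collinear with
#' `z` (\eqn{|\rho| = 1}) the partial correlation is undefined and 0 is
#' returned with attribute `degenerate = TRUE`.
#'
#' @param x,y,z numeric vectors of equal length >= 4.
#' @return Partial correlation in `[-1, 1]`.
#' @export
spearman_pcor <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("x, y, z lengths differ")
  if (n < 4) stop("need at least 4 observations")
  if (stats::sd(z) == 0) return(spearman_cor(x, y))
  rxy <- spearman_cor(x, y)
  rxz <- spearman_cor(x, z)
  ryz <- spearman_cor(y, z)
  pcor_from_cor(rxy, rxz, ryz)
}

# vectorized recursion formula; degenerate conditioning gives flagged 0
pcor_from_cor <- function(rxy, rxz, ryz) {
  denom2 <- (1 - rxz^2) * (1 - ryz^2)
  out <- ifelse(denom2 <= 0, 0, (rxy - rxz * ryz) / sqrt(pmax(denom2, 0)))
  out <- pmin(pmax(out, -1), 1)
  if (length(out) == 1 && denom2 <= 0) attr(out, "degenerate") <- TRUE
  out
}
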