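# 2-Wasserstein distance between empirical point sets (uniform weights).

sq_dist_matrix <- function(A, B) {
  # pairwise squared Euclidean distances, n x m
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  D <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  D[D < 0] <- 0
  D
}

lcm2 <- function(a, b) {
  gcd <- function(x, y) if (y == 0) x else gcd(y, x %% y)
  a / gcd(a, b) * b
}

#' 2-Wasserstein distance between point sets
#'
#' Optimal-transport distance with squared-Euclidean ground cost between two
#' uniformly weighted empirical distributions, with the square root taken so
#' the value is on the scale of the data. Equal-size inputs (and unequal sizes
#' whose least common multiple is small) are solved exactly as a linear
#' assignment problem; larger unequal problems fall back to a log-domain
#' Sinkhorn approximation with a small entropic regulariser. The method used
#' is recorded in the `"method"` attribute.
#'
#' @param A,B numeric matrices (points in rows) with the same column dimension;
#'   vectors are treated as 1-d point sets.
#' @param exact_max exact assignment is used whenever the (replicated) problem
#'   size does not exceed this.
#' @param sinkhorn_reg entropic regulariser for the approximate branch, as a
#'   fraction of the mean ground cost.
#' @return scalar distance with attributes `method` and, for the exact branch,
#'   `assignment` (when sizes are equal).
#' @examples
#' w2_distance(matrix(c(0, 0), 1), matrix(c(3, 4), 1))  # 5
#' @export
w2_distance <- function(A, B, exact_max = 512L, sinkhorn_reg = 0.01) {
  if (is.null(dim(A))) A <- matrix(A, ncol = 1L)
  if (is.null(dim(B))) B <- matrix(B, ncol = 1L)
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) == 0L || nrow(B) == 0L) stopf("w2_distance: empty point set")
  if (ncol(A) != ncol(B)) stopf("w2_distance: dimension mismatch (%d vs %d)", ncol(A), ncol(B))
  n <- nrow(A); m <- nrow(B)

  if (n == m && n <= exact_max) {
    D <- sq_dist_matrix(A, B)
    idx <- .solve_assignment(D)
    val <- sqrt(mean(D[cbind(seq_len(n), idx)]))
    return(structure(val, method = "assignment", assignment = idx))
  }
  if (n != m && lcm2(n, m) <= 4L * exact_max) {
    l <- lcm2(n, m)
    Ar <- A[rep(seq_len(n), each = l / n), , drop = FALSE]
    Br <- B[rep(seq_len(m), each = l / m), , drop = FALSE]
    D <- sq_dist_matrix(Ar, Br)
    idx <- .solve_assignment(D)
    val <- sqrt(mean(D[cbind(seq_len(l), idx)]))
    return(structure(val, method = "assignment_replicated"))
  }
  # entropic branch (log-domain Sinkhorn, uniform marginals)
  D <- sq_dist_matrix(A, B)
  reg <- max(sinkhorn_reg * mean(D), 1e-9)
  la <- -log(n); lb <- -log(m)
  f <- numeric(n); g <- numeric(m)
  for (it in seq_len(300L)) {
    M <- (outer(f, g, "+") - D) / reg
    g_new <- g + reg * (lb - apply(M, 2L, logsumexp) - log(1) )
    M <- (outer(f, g_new, "+") - D) / reg
    f_new <- f + reg * (la - apply(M, 1L, logsumexp))
    if (max(abs(f_new - f)) < 1e-7 * (1 + max(abs(f_new)))) { f <- f_new; g <- g_new; break }
    f <- f_new; g <- g_new
  }
  P <- exp((outer(f, g, "+") - D) / reg + la + lb)
  P <- P / sum(P)
  structure(sqrt(sum(P * D)), method = "sinkhorn")
}
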