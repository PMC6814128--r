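## Comparison of genetic-correlation matrices between model variants (Mantel
## test) and detection of trait modules (weighted Newman modularity).

#' Mantel test between two trait-correlation matrices
#'
#' Statistic: Pearson correlation of the off-diagonal (upper-triangle)
#' entries; significance by permuting the row/column order of the second
#' matrix (delegated to \code{vegan::mantel}).
#'
#' @param M1,M2 Symmetric trait-correlation matrices with identical trait
#'   sets and order (unit diagonal).
#' @param n_perm Number of permutations (>= 99).
#' @param seed RNG seed for the permutations.
#' @return List with \code{statistic} and \code{p_value}.
#' @export
mantel_test <- function(M1, M2, n_perm = 999, seed = 1L) {
  M1 <- as.matrix(M1); M2 <- as.matrix(M2)
  if (!all(dim(M1) == dim(M2)))
    stop("correlation matrices differ in dimension")
  if (!is.null(dimnames(M1)) && !is.null(dimnames(M2)) &&
      !identical(rownames(M1), rownames(M2)))
    stop("correlation matrices must share trait order")
  if (n_perm < 99) stop("use at least 99 permutations")
  set.seed(seed)
  mt <- vegan::mantel(stats::as.dist(M1), stats::as.dist(M2),
                      method = "pearson", permutations = n_perm)
  list(statistic = unname(mt$statistic), p_value = unname(mt$signif),
       n_perm = n_perm)
}

#' Detect trait modules in a genetic-correlation matrix
#'
#' Builds a weighted undirected graph with edge weights \eqn{|r_G|} (diagonal
#' removed) and maximises Newman weighted modularity by agglomerative
#' (fast-greedy) community detection via igraph.
#'
#' @param M Symmetric trait-correlation matrix (at least 3 traits).
#' @return List with \code{membership} (named integer vector: trait ->
#'   module) and \code{q_mod} (modularity score).
#' @export
detect_modules <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) < 3L) stop("need at least 3 traits")
  if (is.null(rownames(M))) rownames(M) <- colnames(M) <-
      paste0("trait", seq_len(nrow(M)))
  W <- abs(M)
  diag(W) <- 0
  if (all(W == 0)) {
    return(list(membership = stats::setNames(rep(1L, nrow(M)), rownames(M)),
                q_mod = 0))
  }
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  cm <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  memb <- igraph::membership(cm)
  list(membership = stats::setNames(as.integer(memb), rownames(M)),
       q_mod = igraph::modularity(g, memb, weights = igraph::E(g)$weight))
}

#' Weighted Newman modularity of a given trait partition
#'
#' Q for an explicit membership vector on the |r_G|-weighted graph; used to
#' compare detected partitions against alternatives.
#'
#' @param M Symmetric trait-correlation matrix.
#' @param membership Integer vector assigning each trait to a module.
#' @export
modularity_score <- function(M, membership) {
  W <- abs(as.matrix(M))
  diag(W) <- 0
  tot <- sum(W)
  if (tot == 0) return(0)
  k <- rowSums(W)
  same <- outer(membership, membership, "==")
  sum((W - outer(k, k) / tot) * same) / tot
}
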