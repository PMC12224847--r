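# Resolution-parameterized modularity and the native Louvain optimizer.
#
# Modularity convention: Q = (1/2m) sum_ij [A_ij - gamma k_i k_j / 2m]
# delta(c_i, c_j), adjacency binary after thresholding (A_ij in {0,1})
# unless weighted = TRUE, in which case edge similarities are used. The
# aggregation phase carries self-loop weights (A_ii = 2 * w_self) so Q is
# preserved under aggregation.

.edge_weights <- function(g, weighted) {
  if (weighted) g$edges$weight else rep(1, nrow(g$edges))
}

#' Modularity of a partition
#'
#' Exact, from-scratch evaluation of resolution-parameterized modularity on
#' a `cmm_graph`. At gamma = 1 this is the classical Newman-Girvan Q.
#'
#' @param g a `cmm_graph`.
#' @param membership integer community labels, one per node.
#' @param gamma resolution; multiplies the degree-null term.
#' @param weighted use similarity weights instead of binary adjacency.
#' @return scalar Q.
#' @export
modularity_q <- function(g, membership, gamma = 1, weighted = FALSE) {
  if (nrow(g$edges) == 0)
    stop("modularity is undefined on an edgeless graph", call. = FALSE)
  if (length(membership) != g$n_nodes)
    stop("membership must assign every node", call. = FALSE)
  w <- .edge_weights(g, weighted)
  m <- sum(w)
  k <- numeric(g$n_nodes)
  agg <- rowsum(c(w, w), group = c(g$edges$i, g$edges$j))
  k[as.integer(rownames(agg))] <- agg[, 1]
  memb <- as.integer(factor(membership))
  within <- memb[g$edges$i] == memb[g$edges$j]
  tot <- tapply(k, memb, sum)
  q_in <- sum(w[within]) / m
  q_null <- gamma * sum((tot / (2 * m))^2)
  q_in - q_null
}

.canonical <- function(labels) {
  as.integer(factor(labels, levels = unique(labels)))
}

.partition <- function(g, membership, gamma, seed, q, levels = NA_integer_) {
  memb <- .canonical(membership)
  names(memb) <- g$node_ids
  structure(list(membership = memb,
                 n_communities = max(memb),
                 modularity = q,
                 resolution = gamma,
                 rng_seed = seed,
                 levels = levels),
            class = "cmm_partition")
}

#' @export
print.cmm_partition <- function(x, ...) {
  cat("cmm_partition:", x$n_communities, "communities, Q =",
      format(x$modularity, digits = 4), "at gamma =", x$resolution, "\n")
  invisible(x)
}

#' Louvain community detection
#'
#' Native two-phase multilevel optimizer: repeated single-node moves to the
#' neighboring community with maximal positive modularity gain (sweep order
#' shuffled by `seed`; a move that only ties the current community is
#' rejected, ties among candidates go to the lowest label), followed by
#' aggregation of communities into super-nodes with self-loops, until no
#' move improves. The returned Q is recomputed from scratch on the original
#' graph at `gamma`.
#'
#' @param g a `cmm_graph` with at least one edge.
#' @param gamma resolution parameter.
#' @param seed integer RNG seed for the sweep order.
#' @param weighted use similarity weights instead of binary adjacency.
#' @return a `cmm_partition` with canonicalized (contiguous, first-
#'   appearance-ordered) labels.
#' @export
louvain <- function(g, gamma = 1, seed = 0L, weighted = FALSE) {
  if (nrow(g$edges) == 0)
    stop("modularity is undefined on an edgeless graph", call. = FALSE)
  w <- .edge_weights(g, weighted)
  res <- .louvain_cpp(g$n_nodes, g$edges$i - 1L, g$edges$j - 1L, w,
                      gamma, as.integer(seed))
  memb <- res$membership + 1L
  q <- modularity_q(g, memb, gamma = gamma, weighted = weighted)
  stopifnot(abs(q - res$modularity) < 1e-9)
  p <- .partition(g, memb, gamma, as.integer(seed), q, res$levels)
  p$level_modularity <- res$level_modularity
  p
}

# restricted-growth-string enumeration of all set partitions of n elements,
# in lexicographic order
.rgs_enumerate <- function(n) {
  out <- list()
  rec <- function(prefix, maxl) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxl + 1L))
      rec(c(prefix, v), max(maxl, v))
  }
  rec(integer(0), 0L)
  out
}

#' Exhaustive modularity maximizer (test oracle)
#'
#' Enumerates every set partition of the nodes (Bell-number many) and
#' returns the global Q maximizer. Ties are broken by the lexicographically
#' smallest restricted-growth labeling, which is also the canonical form.
#' Refuses graphs with more than 10 nodes.
#'
#' @param g a `cmm_graph` with `<= 10` nodes and at least one edge.
#' @param gamma resolution parameter.
#' @param weighted use similarity weights.
#' @return a `cmm_partition`.
#' @export
brute_force_best_partition <- function(g, gamma = 1, weighted = FALSE) {
  if (g$n_nodes > 10)
    stop("brute-force partition search is limited to 10 nodes",
         call. = FALSE)
  if (nrow(g$edges) == 0)
    stop("modularity is undefined on an edgeless graph", call. = FALSE)
  parts <- .rgs_enumerate(g$n_nodes)
  # modularity matrix M = (A - gamma k k^T / 2m) / 2m, so that
  # Q(partition) = sum_ij M_ij delta(c_i, c_j); agreement with
  # modularity_q() is asserted in the test suite
  n <- g$n_nodes
  w <- .edge_weights(g, weighted)
  A <- matrix(0, n, n)
  for (e in seq_along(w)) {
    i <- g$edges$i[e]; j <- g$edges$j[e]
    if (i == j) A[i, i] <- A[i, i] + 2 * w[e]
    else {
      A[i, j] <- A[i, j] + w[e]
      A[j, i] <- A[j, i] + w[e]
    }
  }
  m <- sum(w)
  k <- rowSums(A)
  M <- (A - gamma * tcrossprod(k) / (2 * m)) / (2 * m)
  best_q <- -Inf
  best <- NULL
  for (p in parts) {
    q <- sum(M[outer(p, p, "==")])
    if (q > best_q + 1e-15) {
      best_q <- q
      best <- p
    }
  }
  .partition(g, best, gamma, NA_integer_,
             modularity_q(g, best, gamma = gamma, weighted = weighted))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same elements.
#'
#' @param a,b label vectors of equal length.
#' @return scalar ARI (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Planted-partition random graph
#'
#' Blocks of nodes with independent within-block edge probability `p_in`
#' and between-block probability `p_out`; the planted block labels are
#' attached as attribute `planted`.
#'
#' @param block_sizes integer vector of block sizes.
#' @param p_in,p_out edge probabilities.
#' @param seed RNG seed.
#' @return a `cmm_graph`.
#' @export
planted_partition_graph <- function(block_sizes, p_in, p_out, seed = 0L) {
  n <- sum(block_sizes)
  blocks <- rep(seq_along(block_sizes), block_sizes)
  .with_seed(seed, {
    pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    p <- ifelse(blocks[pr[, 1]] == blocks[pr[, 2]], p_in, p_out)
    keep <- runif(nrow(pr)) < p
    edges <- data.frame(i = pr[keep, 1], j = pr[keep, 2], weight = 1)
    g <- .graph(as.character(seq_len(n)), edges, NA_real_)
    attr(g, "planted") <- blocks
    g
  })
}

#' Write a partition as TSV with a JSON run report
#'
#' @param p a `cmm_partition`.
#' @param path TSV path (`node_id`, `community`); the report goes to
#'   `<path>.json` with Q, gamma, seed and the per-level modularity trace.
#' @return `path`, invisibly.
#' @export
write_partition <- function(p, path) {
  utils::write.table(
    data.frame(node_id = names(p$membership), community = p$membership),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(modularity = p$modularity,
                            resolution = p$resolution,
                            n_communities = p$n_communities,
                            rng_seed = p$rng_seed,
                            levels = p$levels,
                            level_modularity = p$level_modularity),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
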