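#' Cosine similarity between two feature vectors
#'
#' `a . b / (||a|| ||b||)`, in `[-1, 1]`.
#'
#' @param a,b numeric vectors of equal length >= 1.
#' @return scalar similarity.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b) || length(a) < 1)
    stop("vectors must have equal positive length", call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("cosine similarity is undefined for a zero-norm vector",
         call. = FALSE)
  sum(a * b) / (na * nb)
}

.graph <- function(node_ids, edges, threshold) {
  structure(list(node_ids = node_ids,
                 n_nodes = length(node_ids),
                 edges = edges,
                 threshold = threshold),
            class = "cmm_graph")
}

#' @export
print.cmm_graph <- function(x, ...) {
  cat("cmm_graph:", x$n_nodes, "nodes,", nrow(x$edges), "edges",
      if (!is.null(x$threshold) && is.finite(x$threshold))
        paste0("(threshold ", x$threshold, ")") else "", "\n")
  invisible(x)
}

#' Number of non-isolated nodes of a graph
#' @param g a `cmm_graph`.
#' @return count of nodes with degree >= 1.
#' @export
retained_nodes <- function(g) {
  length(unique(c(g$edges$i, g$edges$j)))
}

#' Build a patient-similarity graph by thresholded cosine similarity
#'
#' Evaluates cosine similarity over all unordered row pairs of the feature
#' matrix and keeps an (unweighted) edge wherever similarity is at least
#' `threshold`. Isolated nodes stay in the node list. Zero-norm rows (which
#' have undefined similarity) receive no edges.
#'
#' @param fm a `cmm_feature_matrix`, or a plain numeric matrix.
#' @param threshold edge-inclusion cutoff in `[-1, 1]`; the edge rule is
#'   `similarity >= threshold`.
#' @return a `cmm_graph` with edge list columns `i`, `j` (node indices,
#'   `i < j`) and `weight` (the cosine similarity).
#' @export
build_graph <- function(fm, threshold) {
  X <- if (inherits(fm, "cmm_feature_matrix")) fm$values else as.matrix(fm)
  ids <- if (inherits(fm, "cmm_feature_matrix")) fm$row_ids
         else as.character(seq_len(nrow(X)))
  if (nrow(X) < 2) stop("need at least 2 rows", call. = FALSE)
  if (!is.numeric(threshold) || threshold < -1 || threshold > 1)
    stop("threshold must lie in [-1, 1]", call. = FALSE)
  S <- similarity_matrix(X)
  keep <- which(S >= threshold & upper.tri(S), arr.ind = TRUE)
  edges <- data.frame(i = keep[, 1], j = keep[, 2],
                      weight = S[keep])
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  .graph(ids, edges, threshold)
}

#' Full pairwise cosine-similarity matrix
#'
#' Row-normalizes the matrix and takes the cross product; zero-norm rows get
#' `-Inf` similarity so no threshold can admit them.
#'
#' @param X numeric matrix (rows = patients).
#' @return symmetric matrix of cosine similarities with `-Inf` diagonal
#'   placeholder removed (diagonal set to 1 for nonzero rows).
#' @export
similarity_matrix <- function(X) {
  X <- as.matrix(X)
  nrm <- sqrt(rowSums(X^2))
  zero <- nrm == 0
  nrm[zero] <- 1
  S <- tcrossprod(X / nrm)
  S <- pmin(pmax(S, -1), 1)
  if (any(zero)) {
    S[zero, ] <- -Inf
    S[, zero] <- -Inf
  }
  S
}

#' Grid search over similarity threshold and Louvain resolution
#'
#' For every (threshold, resolution) cell the graph is rebuilt, the native
#' Louvain optimizer is run at that resolution, and the modularity of the
#' detected partition is recorded. Model selection compares cells by
#' modularity evaluated at gamma = 1 (so cells with different resolutions
#' are comparable; the resolution only shapes the Louvain objective), with
#' ties broken by more retained (non-isolated) nodes, then by lower
#' threshold. Default grids cover thresholds 0.3-0.7 and resolutions
#' 0.5-1.5 in steps of 0.05.
#'
#' @param fm a `cmm_feature_matrix` (or numeric matrix).
#' @param thresholds,resolutions numeric grids.
#' @param seed detector seed passed to [louvain()].
#' @param weighted if `TRUE`, modularity uses the similarity weights instead
#'   of a binary adjacency.
#' @return a `cmm_grid_result`: the selected `threshold`, `resolution`,
#'   `modularity` (at gamma = 1), `modularity_at_gamma`, `n_retained_nodes`,
#'   the selected `partition`, `graph`, `included` (logical: nodes with at
#'   least one edge at the selected threshold — isolated nodes sit in
#'   singleton communities and are excluded from downstream pattern
#'   analysis), and the full `grid` table.
#' @export
grid_search <- function(fm, thresholds = seq(0.3, 0.7, by = 0.05),
                        resolutions = seq(0.5, 1.5, by = 0.05),
                        seed = 0L, weighted = FALSE) {
  if (!length(thresholds) || !length(resolutions))
    stop("threshold and resolution grids must be non-empty", call. = FALSE)
  X <- if (inherits(fm, "cmm_feature_matrix")) fm$values else as.matrix(fm)
  ids <- if (inherits(fm, "cmm_feature_matrix")) fm$row_ids
         else as.character(seq_len(nrow(X)))
  S <- similarity_matrix(X)

  grid <- expand.grid(threshold = thresholds, resolution = resolutions,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$threshold, grid$resolution), , drop = FALSE]
  rownames(grid) <- NULL
  grid$modularity <- NA_real_
  grid$modularity_at_gamma <- NA_real_
  grid$n_retained_nodes <- NA_integer_
  grid$n_communities <- NA_integer_

  best <- NULL
  for (th in thresholds) {
    keep <- which(S >= th & upper.tri(S), arr.ind = TRUE)
    if (nrow(keep) == 0) next
    edges <- data.frame(i = keep[, 1], j = keep[, 2], weight = S[keep])
    g <- .graph(ids, edges, th)
    ret <- retained_nodes(g)
    for (gm in resolutions) {
      p <- louvain(g, gamma = gm, seed = seed, weighted = weighted)
      q1 <- if (gm == 1) p$modularity
            else modularity_q(g, p$membership, gamma = 1, weighted = weighted)
      row <- which(grid$threshold == th & grid$resolution == gm)
      grid$modularity[row] <- q1
      grid$modularity_at_gamma[row] <- p$modularity
      grid$n_retained_nodes[row] <- ret
      grid$n_communities[row] <- p$n_communities
      cand <- list(threshold = th, resolution = gm, modularity = q1,
                   modularity_at_gamma = p$modularity,
                   n_retained_nodes = ret, partition = p, graph = g,
                   included = tabulate(c(edges$i, edges$j),
                                       nbins = nrow(X)) > 0)
      if (is.null(best) ||
          q1 > best$modularity + 1e-15 ||
          (abs(q1 - best$modularity) <= 1e-15 &&
           (ret > best$n_retained_nodes ||
            (ret == best$n_retained_nodes && th < best$threshold)))) {
        best <- cand
      }
    }
  }
  if (is.null(best))
    stop("no structure: every grid cell yields an edgeless graph",
         call. = FALSE)
  best$grid <- grid
  class(best) <- "cmm_grid_result"
  best
}

#' @export
print.cmm_grid_result <- function(x, ...) {
  cat("grid search optimum: threshold =", x$threshold,
      "resolution =", x$resolution, "\n",
      "modularity (gamma=1) =", format(x$modularity, digits = 4),
      "| communities =", x$partition$n_communities,
      "| retained nodes =", x$n_retained_nodes, "\n")
  invisible(x)
}

#' Export a graph as an edge-list TSV or GraphML
#'
#' @param g a `cmm_graph`.
#' @param path output path.
#' @param format `"edgelist"` (TSV: node_i, node_j, similarity) or
#'   `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(g, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    out <- data.frame(node_i = g$node_ids[g$edges$i],
                      node_j = g$node_ids[g$edges$j],
                      similarity = g$edges$weight)
    utils::write.table(out, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    ig <- igraph::graph_from_data_frame(
      data.frame(from = g$node_ids[g$edges$i], to = g$node_ids[g$edges$j],
                 weight = g$edges$weight),
      directed = FALSE,
      vertices = data.frame(name = g$node_ids))
    igraph::write_graph(ig, path, format = "graphml")
  }
  invisible(path)
}
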