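#' Build a class-similarity graph from a confusion matrix
#'
#' Inter-class confusion mass becomes edge weight: the (undirected) weight
#' between classes i and j is the arithmetic mean of the two directed
#' confusion fractions, `(cm[i,j] + cm[j,i]) / 2`. Self-confusion (the
#' diagonal) is discarded — similarity reflects confusability between
#' distinct classes only. Rectangular matrices (cross-day designs) are
#' first embedded on the union of row and column label sets with absent
#' cells set to 0.
#'
#' @param cm a `confusion_matrix` (or any labeled numeric matrix of
#'   non-negative fractions).
#' @return an object of class `similarity_graph`: `nodes` and the
#'   symmetric `weights` matrix (zero diagonal).
#' @export
build_similarity_graph <- function(cm) {
  rn <- rownames(cm); cn <- colnames(cm)
  if (is.null(rn) || is.null(cn)) {
    stop_invalid("invalid-argument: confusion matrix must have row and column labels")
  }
  nodes <- sort(union(rn, cn))
  full <- matrix(0, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
  full[rn, cn] <- as.matrix(cm)
  w <- (full + t(full)) / 2
  diag(w) <- 0
  structure(list(nodes = nodes, weights = w), class = "similarity_graph")
}

#' Construct a similarity graph directly from an edge weight matrix
#' @param w symmetric non-negative matrix with zero diagonal; row names
#'   are node labels (defaults to V1..Vn).
#' @return a `similarity_graph`.
#' @export
similarity_graph <- function(w) {
  w <- as.matrix(w)
  if (is.null(rownames(w))) {
    rownames(w) <- colnames(w) <- paste0("V", seq_len(nrow(w)))
  }
  if (any(w < 0)) stop_invalid("invalid-argument: edge weights must be >= 0")
  if (max(abs(w - t(w))) > 1e-12) stop_invalid("invalid-argument: weights must be symmetric")
  diag(w) <- 0
  structure(list(nodes = rownames(w), weights = w), class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("similarity_graph: %d nodes, %d positive edges\n",
              length(x$nodes), sum(x$weights[upper.tri(x$weights)] > 0)))
  invisible(x)
}

#' Newman-Girvan modularity of a partition
#'
#' `Q = sum_c [ W_c / W - gamma * (S_c / (2 W))^2 ]` where `W` is the total
#' edge weight (each edge once), `W_c` the intra-community edge weight and
#' `S_c` the summed node strength of community `c`.
#'
#' @param graph a `similarity_graph`.
#' @param membership named integer vector mapping every node to a
#'   community id (or a `graph_partition`).
#' @param gamma resolution parameter (default 1).
#' @return modularity Q (0 for an edgeless graph by convention).
#' @export
modularity <- function(graph, membership, gamma = 1) {
  if (inherits(membership, "graph_partition")) membership <- membership$membership
  if (!all(graph$nodes %in% names(membership))) {
    stop_invalid("invalid-partition: membership does not cover all nodes")
  }
  m <- membership[graph$nodes]
  w <- graph$weights
  W <- sum(w) / 2
  if (W == 0) return(0)
  k <- rowSums(w)
  Q <- 0
  for (c in unique(m)) {
    sel <- m == c
    Wc <- sum(w[sel, sel]) / 2
    Sc <- sum(k[sel])
    Q <- Q + Wc / W - gamma * (Sc / (2 * W))^2
  }
  Q
}

# One full Louvain run (local moving + aggregation, repeated until stable)
# on weight matrix w. Diagonal entries of w at aggregated levels carry
# 2 * intra-weight (self-loop convention). Ties in modularity gain are
# broken by the smallest community id. Returns an integer membership.
louvain_once <- function(w, gamma) {
  n_orig <- nrow(w)
  node_map <- seq_len(n_orig)   # original node -> current supernode
  repeat {
    n <- nrow(w)
    comm <- seq_len(n)
    strength <- rowSums(w)      # counts self-loop once == 2*intra ✔
    two_m <- sum(strength)
    if (two_m == 0) break
    sigma_tot <- strength
    improved_any <- FALSE
    repeat {
      improved <- FALSE
      for (i in sample.int(n)) {
        ci <- comm[i]
        ki <- strength[i]
        # weight from i to each community (self-loop excluded)
        wi <- w[i, ]
        wi[i] <- 0
        links <- tapply(wi, comm, sum)
        cand <- as.integer(names(links))
        sigma_tot[ci] <- sigma_tot[ci] - ki
        gain <- as.numeric(links) - gamma * ki * sigma_tot[cand] / two_m
        if (!(ci %in% cand)) {
          cand <- c(cand, ci)
          gain <- c(gain, -gamma * ki * sigma_tot[ci] / two_m)
        }
        cur_gain <- gain[match(ci, cand)]
        gmax <- max(gain)
        # strict improvement required to move; ties among the best
        # candidates resolved to the smallest community id
        best <- min(cand[gain >= gmax - 1e-12])
        if (best != ci && gmax > cur_gain + 1e-12) {
          comm[i] <- best
          sigma_tot[best] <- sigma_tot[best] + ki
          improved <- TRUE; improved_any <- TRUE
        } else {
          sigma_tot[ci] <- sigma_tot[ci] + ki
        }
      }
      if (!improved) break
    }
    if (!improved_any) break
    # aggregate
    ids <- sort(unique(comm))
    M <- matrix(0, n, length(ids))
    M[cbind(seq_len(n), match(comm, ids))] <- 1
    w <- t(M) %*% w %*% M
    node_map <- match(comm, ids)[node_map]
    if (length(ids) == n) break
  }
  node_map
}

#' Louvain community detection on a similarity graph
#'
#' Standard two-phase Louvain (greedy local moving plus graph aggregation)
#' on the weighted undirected graph, with seeded node-visiting order,
#' modularity-gain ties broken deterministically by smallest community id,
#' and best-of-`restarts` selection by recomputed modularity on the
#' original graph. An all-zero-weight graph yields the singleton partition
#' with Q = 0, flagged.
#'
#' @param graph a `similarity_graph`.
#' @param resolution resolution parameter gamma (default 1).
#' @param seed integer seed (node visiting order).
#' @param restarts independent restarts; the partition with the best
#'   recomputed Q is kept (default 10).
#' @return an object of class `graph_partition`: `membership` (named,
#'   communities renumbered 1..k by first appearance), `modularity`,
#'   `n_communities`, `degenerate` flag.
#' @export
louvain <- function(graph, resolution = 1, seed = 1L, restarts = 10) {
  stopifnot(inherits(graph, "similarity_graph"))
  n <- length(graph$nodes)
  if (n == 0) stop_invalid("invalid-argument: empty graph")
  if (sum(graph$weights) == 0) {
    memb <- stats::setNames(seq_len(n), graph$nodes)
    return(structure(list(membership = memb, modularity = 0,
                          n_communities = n, degenerate = TRUE),
                     class = "graph_partition"))
  }
  best <- NULL; best_q <- -Inf
  for (r in seq_len(restarts)) {
    memb <- with_seed(derive_seed(seed, r), {
      louvain_once(graph$weights, resolution)
    })
    names(memb) <- graph$nodes
    q <- modularity(graph, memb, gamma = resolution)
    if (q > best_q + 1e-12) {
      best_q <- q; best <- memb
    }
  }
  # canonical renumbering by first appearance
  ids <- unique(best)
  memb <- stats::setNames(match(best, ids), graph$nodes)
  structure(list(membership = memb, modularity = best_q,
                 n_communities = length(ids), degenerate = FALSE),
            class = "graph_partition")
}

#' @export
print.graph_partition <- function(x, ...) {
  cat(sprintf("graph_partition: %d communities, Q = %.4f%s\n",
              x$n_communities, x$modularity,
              if (isTRUE(x$degenerate)) " (degenerate: no edges)" else ""))
  for (c in sort(unique(x$membership))) {
    cat(sprintf("  [%d] %s\n", c,
                paste(names(x$membership)[x$membership == c], collapse = ", ")))
  }
  invisible(x)
}

#' Export a similarity graph as a weighted edge list
#' @param graph a `similarity_graph`.
#' @param path CSV path (`from,to,weight`); positive-weight edges only.
#' @export
write_edge_list <- function(graph, path) {
  w <- graph$weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  df <- data.frame(from = graph$nodes[idx[, 1]], to = graph$nodes[idx[, 2]],
                   weight = w[idx])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a similarity graph as GraphML
#' @param graph a `similarity_graph`.
#' @param path output .graphml path.
#' @export
write_graphml <- function(graph, path) {
  w <- graph$weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="w" for="edge" attr.name="weight" attr.type="double"/>',
    '  <graph edgedefault="undirected">',
    sprintf('    <node id="%s"/>', graph$nodes),
    sprintf('    <edge source="%s" target="%s"><data key="w">%.10g</data></edge>',
            graph$nodes[idx[, 1]], graph$nodes[idx[, 2]], w[idx]),
    '  </graph>', '</graphml>')
  writeLines(lines, path)
  invisible(path)
}
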