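#' Modularity Q of a node partition
#'
#' For a partition of the nodes into k communities,
#' `Q = sum_i (e_ii - a_i^2)`, where `e_ii` is the fraction of edges with
#' both endpoints in community i and `a_i` the fraction of edge ends
#' attached to community i (degree sum over 2m). Q measures the excess of
#' within-community edge density over the expectation for a degree-matched
#' random graph; `-1 <= Q < 1`, and the trivial one-community partition has
#' Q = 0.
#'
#' @param network a `ppi_network` with at least one edge.
#' @param membership community labels: a vector named by node symbol, or an
#'   unnamed vector parallel to `sort(network$nodes)`.
#' @return the modularity (a single number).
#' @export
modularity_q <- function(network, membership) {
  stopifnot(inherits(network, "ppi_network"))
  m <- n_edges(network)
  if (m == 0) stop("modularity is undefined for a network with no edges")
  nodes <- network$nodes
  if (!is.null(names(membership))) {
    if (!all(nodes %in% names(membership)))
      stop("membership must cover every network node")
    mem <- membership[nodes]
  } else {
    if (length(membership) != length(nodes))
      stop("unnamed membership must have one entry per node")
    mem <- membership
  }
  mem <- as.integer(factor(mem))
  e1 <- match(network$edges$from, nodes)
  e2 <- match(network$edges$to, nodes)
  within <- sum(mem[e1] == mem[e2]) / m
  deg <- tabulate(c(mem[e1], mem[e2]), nbins = max(mem))
  a <- deg / (2 * m)
  within - sum(a^2)
}

#' Greedy agglomerative modularity maximization (CNM)
#'
#' Community detection by the classical greedy algorithm: every node starts
#' in its own community; at each step the connected pair of communities whose
#' merge gives the largest modularity increase `dQ = 2 (e_ij - a_i a_j)` is
#' merged (ties broken by the lexicographically smallest community-label
#' pair, which makes the algorithm fully deterministic), until no connected
#' pair remains. The partition attaining the maximum Q along the merge path
#' is returned together with the full merge history. Isolated nodes remain
#' singleton communities; disconnected components never merge with each
#' other (merging disconnected communities cannot increase Q).
#'
#' @param network a `ppi_network` with at least one edge.
#' @return a `ppi_communities` object: `membership` (named integer vector,
#'   contiguous community ids 1..k), `k`, `Q` (modularity of the returned
#'   partition), `history` (data frame: `step`, `merge_a`, `merge_b`
#'   (representative node symbols of the merged communities), `dQ`, `Q`),
#'   `best_step` (0 = the all-singleton start), `q_trace`, and `nodes`.
#' @examples
#' net <- ppi_network(c("A","B","C","D","E","F","A"),
#'                    c("B","C","A","E","F","D","D"))
#' cm <- greedy_modularity(net)
#' cm$Q  # two triangles joined by a bridge: Q = 5/14
#' @export
greedy_modularity <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  m <- n_edges(network)
  if (m == 0) stop("community detection needs at least one edge")
  nodes <- network$nodes
  n <- length(nodes)
  e1 <- match(network$edges$from, nodes)
  e2 <- match(network$edges$to, nodes)

  ## Newman's convention: off-diagonal E[i,j] = m_ij/(2m) on each side,
  ## diagonal E[i,i] = (edges within i)/m, so rowSums(E) = a and the merge
  ## update (add row j to row i, column j to column i) preserves both.
  E <- matrix(0, n, n)
  for (k in seq_len(m)) {
    E[e1[k], e2[k]] <- E[e1[k], e2[k]] + 1 / (2 * m)
    E[e2[k], e1[k]] <- E[e2[k], e1[k]] + 1 / (2 * m)
  }
  a <- tabulate(c(e1, e2), nbins = n) / (2 * m)
  active <- rep(TRUE, n)
  mem <- seq_len(n)
  Q <- -sum(a^2)

  best_Q <- Q
  best_mem <- mem
  best_step <- 0L
  steps <- vector("list", n - 1L)
  step <- 0L
  upper <- upper.tri(E)

  repeat {
    cand <- which(upper & E > 0, arr.ind = TRUE)
    if (!nrow(cand)) break
    dq <- 2 * (E[cand] - a[cand[, 1L]] * a[cand[, 2L]])
    maxv <- max(dq)
    tie <- which(dq >= maxv - 1e-15)
    if (length(tie) > 1L) {
      ord <- order(cand[tie, 1L], cand[tie, 2L])
      pick <- tie[ord[1L]]
    } else pick <- tie
    i <- cand[pick, 1L]; j <- cand[pick, 2L]
    dq_pick <- 2 * (E[i, j] - a[i] * a[j])

    step <- step + 1L
    E[i, ] <- E[i, ] + E[j, ]
    E[, i] <- E[, i] + E[, j]
    E[j, ] <- 0; E[, j] <- 0
    a[i] <- a[i] + a[j]; a[j] <- 0
    active[j] <- FALSE
    mem[mem == j] <- i
    Q <- Q + dq_pick
    steps[[step]] <- data.frame(step = step, merge_a = nodes[i],
                                merge_b = nodes[j], dQ = dq_pick, Q = Q,
                                stringsAsFactors = FALSE)
    if (Q > best_Q + 1e-12) {
      best_Q <- Q
      best_mem <- mem
      best_step <- step
    }
  }

  membership <- as.integer(factor(best_mem, levels = unique(best_mem[order(best_mem)])))
  names(membership) <- nodes
  history <- if (step > 0) do.call(rbind, steps[seq_len(step)]) else
    data.frame(step = integer(), merge_a = character(), merge_b = character(),
               dQ = numeric(), Q = numeric())
  structure(
    list(membership = membership,
         k = length(unique(membership)),
         Q = best_Q,
         history = history,
         best_step = best_step,
         q_trace = c(-sum(tabulate(c(e1, e2), nbins = n)^2) / (4 * m^2), history$Q),
         nodes = nodes,
         n_edges = m),
    class = "ppi_communities"
  )
}

#' @export
print.ppi_communities <- function(x, ...) {
  sizes <- sort(table(x$membership), decreasing = TRUE)
  cat(sprintf("Greedy-modularity communities: k = %d, Q = %.4f (best at merge step %d of %d)\n",
              x$k, x$Q, x$best_step, nrow(x$history)))
  cat("  community sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.ppi_communities <- function(x, ...) {
  plot(seq_along(x$q_trace) - 1L, x$q_trace, type = "l",
       xlab = "merge step", ylab = "modularity Q",
       main = "Greedy modularity merge trace", ...)
  abline(v = x$best_step, col = "red3", lty = 2)
  invisible(x)
}

#' Order nodes by community for adjacency-matrix display
#'
#' Sorts nodes by (community id, degree descending, symbol) so communities
#' form contiguous blocks; the boundary indices delimit the blocks, suitable
#' for drawing cluster boundaries on an adjacency-matrix heatmap.
#'
#' @param network the `ppi_network` the partition refers to.
#' @param communities a `ppi_communities` object or a membership vector named
#'   by node symbol.
#' @return a `community_ordering`: `order` (character vector of node
#'   symbols), `boundaries` (cumulative community sizes), `membership`
#'   (in the returned order).
#' @export
order_by_community <- function(network, communities) {
  stopifnot(inherits(network, "ppi_network"))
  mem <- if (inherits(communities, "ppi_communities")) communities$membership
         else communities
  if (is.null(names(mem)) || !all(network$nodes %in% names(mem)))
    stop("membership must be named and cover every network node")
  mem <- mem[network$nodes]
  deg <- node_degrees(network)
  ord <- order(mem, -deg[network$nodes], network$nodes)
  ordered_nodes <- network$nodes[ord]
  structure(
    list(order = ordered_nodes,
         boundaries = cumsum(as.integer(table(mem))),
         membership = mem[ord]),
    class = "community_ordering"
  )
}

#' Dense adjacency matrix in a given node order
#'
#' @param network a `ppi_network`.
#' @param order node ordering (defaults to sorted nodes); typically the
#'   `order` component of [order_by_community()].
#' @return 0/1 integer matrix with dimnames.
#' @export
adjacency_matrix <- function(network, order = NULL) {
  stopifnot(inherits(network, "ppi_network"))
  ord <- order %||% network$nodes
  stopifnot(setequal(ord, network$nodes))
  n <- length(ord)
  A <- matrix(0L, n, n, dimnames = list(ord, ord))
  i <- match(network$edges$from, ord)
  j <- match(network$edges$to, ord)
  A[cbind(i, j)] <- 1L
  A[cbind(j, i)] <- 1L
  A
}

#' Write a partition as a two-column TSV (node, community)
#'
#' @param communities a `ppi_communities`.
#' @param path output file.
#' @export
write_partition <- function(communities, path) {
  stopifnot(inherits(communities, "ppi_communities"))
  write.table(data.frame(node = names(communities$membership),
                         community = unname(communities$membership)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
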