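# Independent oracles and graph fixtures used across the suite. Everything
# here is written from first principles (enumeration / direct summation) so
# it does not share code paths with the package implementation.

## All set partitions of n labelled items, as restricted-growth strings.
all_set_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1L))
      recurse(c(prefix, lab), max(maxlab, lab))
  }
  recurse(integer(), 0L)
  out
}

## Modularity computed directly from an edge index matrix (two integer
## columns), node count and a membership vector.
oracle_modularity <- function(eidx, n, mem) {
  m <- nrow(eidx)
  deg <- tabulate(c(eidx[, 1], eidx[, 2]), nbins = n)
  within <- sum(mem[eidx[, 1]] == mem[eidx[, 2]]) / m
  a2 <- 0
  for (comm in unique(mem)) a2 <- a2 + (sum(deg[mem == comm]) / (2 * m))^2
  within - a2
}

## Brute-force maximum modularity over every partition of the nodes.
oracle_max_modularity <- function(eidx, n) {
  best <- -Inf
  for (mem in all_set_partitions(n))
    best <- max(best, oracle_modularity(eidx, n, mem))
  best
}

## Hypergeometric upper tail P(X >= k) by explicit summation over choose().
oracle_hyper_tail <- function(k, K, s, N) {
  j <- k:min(K, s)
  if (k == 0) return(1)
  sum(choose(K, j) * choose(N - K, s - j)) / choose(N, s)
}

## Is the labelled graph (edge index matrix over n nodes) connected?
oracle_connected <- function(eidx, n) {
  if (n == 1) return(TRUE)
  adj <- lapply(seq_len(n), function(i)
    c(eidx[eidx[, 1] == i, 2], eidx[eidx[, 2] == i, 1]))
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]][!seen[adj[[v]]]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

## All labelled connected graphs on n nodes, as edge index matrices.
all_connected_graphs <- function(n) {
  pairs <- t(combn(n, 2))
  M <- nrow(pairs)
  out <- list()
  for (code in seq_len(2^M) - 1L) {
    sel <- as.logical(bitwAnd(code, 2^(seq_len(M) - 1L)))
    if (sum(sel) < n - 1) next
    eidx <- pairs[sel, , drop = FALSE]
    if (oracle_connected(eidx, n)) out[[length(out) + 1L]] <- eidx
  }
  out
}

## A random connected G(n, p) as an edge index matrix (resamples until
## connected; deterministic given the RNG state).
random_connected_eidx <- function(n, p) {
  pairs <- t(combn(n, 2))
  repeat {
    sel <- runif(nrow(pairs)) < p
    if (sum(sel) == 0) next
    eidx <- pairs[sel, , drop = FALSE]
    if (oracle_connected(eidx, n)) return(eidx)
  }
}

## Build a ppi_network from an edge index matrix with letter node names.
net_from_eidx <- function(eidx, n) {
  nm <- sprintf("N%02d", seq_len(n))
  ppi_network(nm[eidx[, 1]], nm[eidx[, 2]], nodes = nm)
}

## Two disjoint triangles ABC / DEF.
two_triangles <- function() {
  ppi_network(c("A", "B", "C", "D", "E", "F"),
              c("B", "C", "A", "E", "F", "D"))
}

## Two triangles joined by the bridge A-D (m = 7).
bridged_triangles <- function() {
  ppi_network(c("A", "B", "C", "D", "E", "F", "A"),
              c("B", "C", "A", "E", "F", "D", "D"))
}

extdata <- function(f) system.file("extdata", f, package = "ipmsnet")
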