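## Sample edges among `nodes` where each of the C(n,2) pairs is present
## independently with probability p; returns a two-column character matrix.
## Uses binomial edge-count + index sampling so no n^2 structure is built.
sample_pairs <- function(nodes, p) {
  n <- length(nodes)
  if (n < 2 || p <= 0) return(cbind(character(), character()))
  M <- n * (n - 1) / 2
  m <- rbinom(1L, M, p)
  if (m == 0) return(cbind(character(), character()))
  idx <- sort(sample.int(M, m))
  ij <- pair_from_index(idx, n)
  cbind(nodes[ij[, 1L]], nodes[ij[, 2L]])
}

#' Generate a planted-partition (stochastic block model) network
#'
#' k communities of given sizes; node pairs within a community are edged
#' independently with probability `p_in`, pairs across communities with
#' `p_out`. The planted assignment is returned as ground truth for recovery
#' scoring. Seed-deterministic.
#'
#' @param k number of communities.
#' @param sizes per-community node counts (recycled to length `k`).
#' @param p_in,p_out within / between edge probabilities,
#'   `0 <= p_out < p_in <= 1`.
#' @param seed RNG seed.
#' @param prefix node-name prefix; nodes are named like `C01N003`.
#' @return list with `network` (a `ppi_network`) and `membership` (named
#'   integer vector, the planted assignment).
#' @export
generate_planted_partition <- function(k, sizes, p_in, p_out, seed = NULL,
                                       prefix = "C") {
  stopifnot(k >= 1, all(sizes >= 1), p_out >= 0, p_in <= 1, p_out < p_in)
  sizes <- rep_len(sizes, k)
  mem <- rep(seq_len(k), sizes)
  nodes <- sprintf("%s%02dN%03d", prefix, mem,
                   unlist(lapply(sizes, seq_len)))
  names(mem) <- nodes
  edges <- with_seed(seed, {
    within <- do.call(rbind, lapply(split(nodes, mem), sample_pairs, p = p_in))
    between <- if (p_out > 0) {
      ## sample over all pairs, keep cross-community ones (within-community
      ## pairs are regenerated above at p_in)
      all_pairs <- sample_pairs(nodes, p_out)
      keep <- mem[all_pairs[, 1L]] != mem[all_pairs[, 2L]]
      all_pairs[keep, , drop = FALSE]
    } else cbind(character(), character())
    rbind(within, between)
  })
  net <- ppi_network(edges[, 1L], edges[, 2L], nodes = nodes,
                     source = "planted_partition")
  list(network = net, membership = mem)
}

#' Generate a background interactome
#'
#' Emulates a literature PPI compendium at a requested scale and mean degree.
#' `model = "uniform_random"` is the Erdős–Rényi G(n, p) graph with
#' `p = mean_degree / (n - 1)`; `model = "power_law"` is a Chung–Lu
#' expected-degree graph with weights `w_i` proportional to
#' `(i + i0)^(-1/(gamma-1))` scaled to the requested mean degree, giving a
#' heavy-tailed (hub-containing) degree distribution at the same mean.
#' Always a simple graph; seed-deterministic.
#'
#' @param n_nodes number of nodes (>= 2); nodes named `P000001`, ...
#' @param mean_degree requested mean degree (< `n_nodes - 1`).
#' @param model `"uniform_random"` or `"power_law"`.
#' @param gamma power-law exponent for the tail (default 2.5).
#' @param seed RNG seed.
#' @return a `ppi_network`.
#' @export
generate_background_network <- function(n_nodes, mean_degree,
                                        model = c("uniform_random", "power_law"),
                                        gamma = 2.5, seed = NULL) {
  model <- match.arg(model)
  stopifnot(n_nodes >= 2, mean_degree > 0, mean_degree < n_nodes - 1)
  nodes <- sprintf("P%06d", seq_len(n_nodes))
  edges <- with_seed(seed, {
    if (model == "uniform_random") {
      sample_pairs(nodes, mean_degree / (n_nodes - 1))
    } else {
      ## Chung-Lu: P(i~j) = min(1, w_i w_j / S), E[deg_i] ~ w_i
      i0 <- 10
      w <- (seq_len(n_nodes) + i0)^(-1 / (gamma - 1))
      w <- w * n_nodes * mean_degree / sum(w)
      S <- sum(w)
      ij <- pair_from_index(seq_len(n_nodes * (n_nodes - 1) / 2), n_nodes)
      pr <- pmin(1, w[ij[, 1L]] * w[ij[, 2L]] / S)
      keep <- runif(length(pr)) < pr
      cbind(nodes[ij[keep, 1L]], nodes[ij[keep, 2L]])
    }
  })
  ppi_network(edges[, 1L], edges[, 2L], nodes = nodes,
              source = paste0("synthetic_", model))
}

#' Overlay planted modules on a background network
#'
#' Adds within-module edges with probability `p_in` (union with existing
#' edges) for each given module — the synthetic analogue of dense protein
#' complexes embedded in a sparse interactome.
#'
#' @param network background `ppi_network`.
#' @param modules list of character vectors (each a module's node symbols;
#'   must be nodes of `network`).
#' @param p_in within-module edge probability.
#' @param seed RNG seed.
#' @return the augmented `ppi_network`.
#' @export
plant_modules <- function(network, modules, p_in, seed = NULL) {
  stopifnot(inherits(network, "ppi_network"),
            all(unlist(modules) %in% network$nodes))
  extra <- with_seed(seed, {
    do.call(rbind, lapply(modules, sample_pairs, p = p_in))
  })
  add <- ppi_network(extra[, 1L], extra[, 2L], source = "planted_module")
  merge_networks(network, add)
}

#' Generate a contaminated hit list from a planted module
#'
#' Emulates an IP-MS pull-down: true complex members plus nonspecific
#' binders. The list contains `round(list_size * (1 - contamination))`
#' module members and `round(list_size * contamination)` contaminants drawn
#' uniformly from the non-module nodes (degree-uniform: the synthetic screen
#' has no hub bias). Per-symbol ground-truth labels are attached.
#'
#' @param network background `ppi_network`.
#' @param module_nodes character vector: the true module members.
#' @param contamination fraction of the list that is background noise,
#'   in \[0, 1\].
#' @param list_size total list length; default takes every module member
#'   plus the implied number of contaminants.
#' @param seed RNG seed.
#' @param label provenance label.
#' @return a [hit_list()] with attribute `"truth"`: named character vector
#'   (`"module"` / `"contaminant"`).
#' @export
generate_hit_list <- function(network, module_nodes, contamination = 0,
                              list_size = NULL, seed = NULL,
                              label = "synthetic hits") {
  stopifnot(inherits(network, "ppi_network"),
            contamination >= 0, contamination <= 1,
            all(module_nodes %in% network$nodes))
  n_mod_avail <- length(module_nodes)
  list_size <- list_size %||% round(n_mod_avail / (1 - contamination))
  stopifnot(list_size <= length(network$nodes))
  n_contam <- round(list_size * contamination)
  n_mod <- list_size - n_contam
  if (n_mod > n_mod_avail)
    stop(sprintf("list budget needs %d module members but the module has only %d",
                 n_mod, n_mod_avail))
  pool <- setdiff(network$nodes, module_nodes)
  if (n_contam > length(pool)) stop("not enough non-module nodes for contaminants")
  syms <- with_seed(seed, {
    mod <- if (n_mod == n_mod_avail) module_nodes else sample(module_nodes, n_mod)
    con <- if (n_contam > 0) sample(pool, n_contam) else character()
    c(mod, con)
  })
  hl <- hit_list(syms, label = label)
  attr(hl, "truth") <- setNames(
    ifelse(hl$symbols %in% module_nodes, "module", "contaminant"), hl$symbols)
  hl
}

#' Generate two hit lists with a planted shared core
#'
#' Emulates a two-screen (e.g. two-species) IP-MS design: both lists contain
#' the planted core; the remainders are drawn disjointly from the namespace
#' so the intersection equals the core exactly.
#'
#' @param core_size shared-core size (`<= min(size_a, size_b)`).
#' @param size_a,size_b list sizes.
#' @param namespace character vector of available symbols (must fit
#'   `size_a + size_b - core_size` distinct symbols).
#' @param seed RNG seed.
#' @param labels character(2) provenance labels.
#' @return list with `list_a`, `list_b` ([hit_list()]s) and `core`
#'   (character vector).
#' @export
generate_two_species_lists <- function(core_size, size_a, size_b, namespace,
                                       seed = NULL,
                                       labels = c("screen A", "screen B")) {
  namespace <- unique(normalize_symbol(namespace))
  stopifnot(core_size >= 0, core_size <= min(size_a, size_b),
            length(namespace) >= size_a + size_b - core_size)
  parts <- with_seed(seed, {
    picked <- sample(namespace, size_a + size_b - core_size)
    list(core = picked[seq_len(core_size)],
         rest_a = picked[core_size + seq_len(size_a - core_size)],
         rest_b = picked[size_a + seq_len(size_b - core_size)])
  })
  list(list_a = hit_list(c(parts$core, parts$rest_a), labels[1L]),
       list_b = hit_list(c(parts$core, parts$rest_b), labels[2L]),
       core = parts$core)
}

#' Score recovery of planted modules by a detected partition
#'
#' For each planted module, finds the detected community with the largest
#' member overlap and reports the adjusted Rand index between the binary
#' indicator partitions (module vs rest, best-matching community vs rest)
#' over the scored node set. An ARI near 1 means the module was recovered
#' as (essentially) one community.
#'
#' @param communities a `ppi_communities` or membership vector named by node
#'   symbol (e.g. from the induced subnetwork).
#' @param modules named list of character vectors: the planted modules.
#' @return data frame with one row per module: `module`, `n_nodes` (module
#'   nodes present in the partition), `best_community`, `overlap`, `ari`.
#' @export
score_module_recovery <- function(communities, modules) {
  mem <- if (inherits(communities, "ppi_communities")) communities$membership
         else communities
  stopifnot(!is.null(names(mem)), length(modules) >= 1)
  if (is.null(names(modules)))
    names(modules) <- sprintf("module_%d", seq_along(modules))
  nodes <- names(mem)
  rows <- lapply(names(modules), function(mn) {
    inside <- nodes %in% modules[[mn]]
    if (!any(inside))
      return(data.frame(module = mn, n_nodes = 0L, best_community = NA_character_,
                        overlap = 0L, ari = NA_real_, stringsAsFactors = FALSE))
    tab <- table(as.character(mem[inside]))
    best <- names(tab)[which.max(tab)]
    data.frame(module = mn, n_nodes = sum(inside),
               best_community = best,
               overlap = as.integer(max(tab)),
               ari = adjusted_rand_index(inside, as.character(mem) == best),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a gene-set library with planted terms
#'
#' Planted terms are inserted verbatim; decoy terms are sampled uniformly
#' from the namespace with sizes uniform in `term_size_range`. Stand-in for
#' GO/CORUM-style libraries with known enriched terms.
#'
#' @param n_decoys number of decoy terms (0 gives exactly the planted terms).
#' @param term_size_range integer length-2: min/max decoy term size.
#' @param planted named list of character vectors inserted verbatim.
#' @param namespace symbols decoys are drawn from.
#' @param seed RNG seed.
#' @param name library label.
#' @return a [gene_set_library()].
#' @export
generate_gmt <- function(n_decoys, term_size_range = c(5, 50),
                         planted = list(), namespace, seed = NULL,
                         name = "synthetic library") {
  namespace <- unique(normalize_symbol(namespace))
  stopifnot(n_decoys >= 0, length(term_size_range) == 2,
            term_size_range[1] >= 1,
            term_size_range[2] <= length(namespace),
            all(unlist(planted) %in% namespace) || length(planted) == 0)
  decoys <- with_seed(seed, {
    if (n_decoys == 0) list() else {
      sizes <- sample(seq(term_size_range[1], term_size_range[2]),
                      n_decoys, replace = TRUE)
      setNames(lapply(sizes, function(sz) sample(namespace, sz)),
               sprintf("DECOY_TERM_%03d", seq_len(n_decoys)))
    }
  })
  gene_set_library(c(planted, decoys), name = name)
}
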