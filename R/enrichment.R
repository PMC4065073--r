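## One-sided (greater) Fisher exact p for a 2x2 overlap table with fixed
## margins: P(X >= k) with X ~ Hypergeometric(N, K, s).
hyper_upper_tail <- function(k, K, s, N) {
  stopifnot(k >= 0, K >= 0, s >= 0, N >= 1, K <= N, s <= N, k <= min(K, s))
  phyper(k - 1, K, N - K, s, lower.tail = FALSE)
}

enrichment_row <- function(term, k, K, s, N, overlap) {
  or_num <- k * (N - K - s + k)
  or_den <- (K - k) * (s - k)
  data.frame(
    term = term, k = k, K = K, s = s, N = N,
    odds_ratio = if (or_den == 0) Inf else or_num / or_den,
    p = hyper_upper_tail(k, K, s, N),
    overlap = paste(sort(overlap), collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Fisher-exact gene-set enrichment of a hit list
#'
#' For every term of a gene-set library, tests whether the query over-represents
#' the term relative to a background universe, with the one-sided Fisher exact
#' test (equivalently the hypergeometric upper tail `P(X >= k)` for the 2x2
#' table with fixed margins): `k` = query-term overlap, `K` = term size within
#' the universe, `s` = query size within the universe, `N` = universe size.
#' P-values are Benjamini-Hochberg adjusted across all terms of the library.
#' Only enrichment (never depletion) is tested.
#'
#' @param query a [hit_list()] or character vector of symbols. The query is
#'   restricted to the universe before testing; out-of-universe symbols are
#'   counted in the `"n_query_outside_universe"` attribute.
#' @param library a [gene_set_library()].
#' @param universe background symbol set; defaults to the library's own
#'   universe (the union of its term sets).
#' @return an `enrichment_result` data frame, one row per term, sorted by
#'   `(p, term)`: columns `term`, `k`, `K`, `s`, `N`, `odds_ratio`, `p`,
#'   `p_adj`, `overlap` (semicolon-joined symbols), `rank`.
#' @export
fisher_enrichment <- function(query, library, universe = NULL) {
  stopifnot(inherits(library, "gene_set_library"))
  if (!inherits(query, "hit_list")) query <- hit_list(query)
  universe <- sort(unique(normalize_symbol(universe %||% library$universe)))
  if (!length(universe)) stop("empty universe")
  q <- intersect(query$symbols, universe)
  n_out <- length(query$symbols) - length(q)
  if (!length(q))
    stop(sprintf(
      "no query symbol of '%s' is in the %d-symbol universe: query and universe namespaces do not match",
      query$label, length(universe)))
  s <- length(q)
  N <- length(universe)
  rows <- lapply(names(library$terms), function(tm) {
    tset <- intersect(library$terms[[tm]], universe)
    ov <- intersect(q, tset)
    enrichment_row(tm, length(ov), length(tset), s, N, ov)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$term), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  attr(res, "library") <- library$name
  attr(res, "query") <- query$label
  attr(res, "n_query_outside_universe") <- n_out
  res
}

#' @export
print.enrichment_result <- function(x, n = 10, ...) {
  cat(sprintf("Enrichment of '%s' against '%s' (%d terms; %d query symbols outside universe)\n",
              attr(x, "query") %||% "query", attr(x, "library") %||% "library",
              nrow(x), attr(x, "n_query_outside_universe") %||% 0L))
  print.data.frame(head(as.data.frame(x)[, c("term", "k", "K", "s", "N",
                                             "odds_ratio", "p", "p_adj")], n),
                   digits = 4)
  if (nrow(x) > n) cat(sprintf("  ... %d more terms\n", nrow(x) - n))
  invisible(x)
}

#' Cross-screen overlap test (Fisher exact)
#'
#' Tests whether two hit lists (e.g. the murine and human screens of a
#' two-species IP-MS design) share more symbols than expected by chance,
#' with the one-sided Fisher exact test on the table `k = |A intersect B|`,
#' `K = |B|`, `s = |A|`, `N = universe_size`. Lists must be in one namespace;
#' apply [apply_ortholog_map()] first for cross-species pairs.
#'
#' @param list_a,list_b [hit_list()]s (or character vectors).
#' @param universe_size background size; the default 20000 is
#'   protein-coding-genome scale and is always reported alongside the result.
#' @return a one-row `enrichment_result` (term = "overlap").
#' @export
overlap_test <- function(list_a, list_b, universe_size = 20000) {
  if (!inherits(list_a, "hit_list")) list_a <- hit_list(list_a, "A")
  if (!inherits(list_b, "hit_list")) list_b <- hit_list(list_b, "B")
  A <- list_a$symbols; B <- list_b$symbols
  if (universe_size < length(union(A, B)))
    stop(sprintf("universe_size (%d) is smaller than |A union B| (%d)",
                 as.integer(universe_size), length(union(A, B))))
  ov <- intersect(A, B)
  res <- enrichment_row("overlap", length(ov), length(B), length(A),
                        as.integer(universe_size), ov)
  res$p_adj <- res$p
  res$rank <- 1L
  class(res) <- c("enrichment_result", "data.frame")
  attr(res, "library") <- list_b$label
  attr(res, "query") <- list_a$label
  res
}

#' Annotate communities by gene-set enrichment
#'
#' Runs [fisher_enrichment()] on every community of at least `min_size`
#' members against each library; communities below the size threshold are
#' skipped with a notice. The per-community top term (smallest p) across
#' libraries is collected in a summary table.
#'
#' @param communities a `ppi_communities` object (or a membership vector
#'   named by node symbol).
#' @param libraries a [gene_set_library()] or list of them.
#' @param universe background symbol set; default: each library's own
#'   universe.
#' @param min_size smallest community size tested (default 3).
#' @return a `cluster_annotation`: list with `results` (nested list,
#'   community id -> library name -> `enrichment_result`), `summary`
#'   (data frame: community, size, library, top_term, top_p, top_p_adj),
#'   and `skipped` (ids of communities below `min_size`).
#' @export
annotate_clusters <- function(communities, libraries, universe = NULL,
                              min_size = 3) {
  mem <- if (inherits(communities, "ppi_communities")) communities$membership
         else communities
  stopifnot(!is.null(names(mem)))
  if (inherits(libraries, "gene_set_library")) libraries <- list(libraries)
  names(libraries) <- vapply(libraries, `[[`, character(1), "name")
  groups <- split(names(mem), mem)
  small <- names(groups)[lengths(groups) < min_size]
  if (length(small))
    message(sprintf("annotate_clusters: skipping %d communit%s below min size %d (%s)",
                    length(small), if (length(small) == 1) "y" else "ies",
                    min_size, paste(small, collapse = ", ")))
  tested <- groups[lengths(groups) >= min_size]
  results <- lapply(tested, function(members) {
    lapply(libraries, function(lib) {
      fisher_enrichment(hit_list(members, "community"), lib, universe = universe)
    })
  })
  summ <- do.call(rbind, lapply(names(results), function(cid) {
    do.call(rbind, lapply(names(results[[cid]]), function(ln) {
      top <- results[[cid]][[ln]][1L, ]
      data.frame(community = cid, size = length(tested[[cid]]), library = ln,
                 top_term = top$term, top_k = top$k, top_p = top$p,
                 top_p_adj = top$p_adj, stringsAsFactors = FALSE)
    }))
  }))
  structure(list(results = results,
                 summary = summ %||% data.frame(),
                 skipped = small),
            class = "cluster_annotation")
}

#' @export
print.cluster_annotation <- function(x, ...) {
  cat(sprintf("Community annotation: %d communities tested, %d skipped\n",
              length(x$results), length(x$skipped)))
  if (nrow(x$summary)) print.data.frame(x$summary, digits = 4)
  invisible(x)
}

#' Disease-term membership lookup
#'
#' Pure set-membership listing of which hit symbols fall in each term of a
#' disease gene-set library (no statistic) — the classic "which of my hits
#' are known disease genes" table.
#'
#' @param hits a [hit_list()] or character vector.
#' @param disease_library a [gene_set_library()] of disease gene sets.
#' @return data frame with columns `disease` and `gene`, one row per
#'   (term, member-found) pair; zero rows if no hit belongs to any term.
#' @export
disease_lookup <- function(hits, disease_library) {
  stopifnot(inherits(disease_library, "gene_set_library"))
  if (!inherits(hits, "hit_list")) hits <- hit_list(hits)
  rows <- lapply(names(disease_library$terms), function(tm) {
    found <- intersect(hits$symbols, disease_library$terms[[tm]])
    if (!length(found)) return(NULL)
    data.frame(disease = tm, gene = found, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out %||% data.frame(disease = character(), gene = character(),
                      stringsAsFactors = FALSE)
}

#' Write an enrichment table as TSV
#'
#' @param result an `enrichment_result` (or the `summary` of a
#'   `cluster_annotation`).
#' @param path output file.
#' @export
write_enrichment <- function(result, path) {
  write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
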