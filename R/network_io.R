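## Internal constructor. `from`/`to` are normalized symbols with from < to,
## deduplicated; `sources` is a list of character vectors parallel to edges.
new_ppi_network <- function(nodes, from, to, sources) {
  structure(
    list(
      nodes = nodes,
      edges = data.frame(from = from, to = to, stringsAsFactors = FALSE),
      sources = sources
    ),
    class = "ppi_network"
  )
}

#' Build an undirected PPI network from interactor pairs
#'
#' Symbols are normalized (see [normalize_symbol()]); self-loops are dropped;
#' duplicate pairs (in either orientation) collapse to one edge. The result is
#' always a simple undirected graph.
#'
#' @param a,b character vectors of interactor symbols (parallel).
#' @param nodes optional extra node symbols to include even if isolated.
#' @param source single resource label attached to every edge.
#' @return a `ppi_network` object with components `nodes` (sorted character
#'   vector), `edges` (two-column data frame, `from < to`), and `sources`
#'   (per-edge list of contributing resource labels). The number of input
#'   rows dropped as self-loops or duplicates is recorded in attribute
#'   `"dropped"`.
#' @seealso [read_edge_list()], [merge_networks()]
#' @export
ppi_network <- function(a = character(), b = character(), nodes = NULL,
                        source = "user") {
  stopifnot(length(a) == length(b))
  a <- normalize_symbol(a)
  b <- normalize_symbol(b)
  keep <- nzchar(a) & nzchar(b)
  a <- a[keep]; b <- b[keep]
  n_in <- length(a)
  ## canonical orientation
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  self <- lo == hi
  lo <- lo[!self]; hi <- hi[!self]
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  lo <- lo[!dup]; hi <- hi[!dup]
  ord <- order(lo, hi)
  lo <- lo[ord]; hi <- hi[ord]
  all_nodes <- sort(unique(c(lo, hi, normalize_symbol(nodes %||% character()))))
  all_nodes <- all_nodes[nzchar(all_nodes)]
  net <- new_ppi_network(all_nodes, lo, hi,
                         rep(list(source), length(lo)))
  attr(net, "dropped") <- n_in - length(lo)
  net
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("PPI network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  srcs <- unique(unlist(x$sources))
  if (length(srcs)) cat("  sources:", paste(srcs, collapse = ", "), "\n")
  invisible(x)
}

n_edges <- function(net) nrow(net$edges)

edge_keys <- function(net) paste(net$edges$from, net$edges$to, sep = "\r")

#' Node degrees of a PPI network
#'
#' @param net a `ppi_network`.
#' @return named integer vector over all nodes (isolated nodes have degree 0).
#' @export
node_degrees <- function(net) {
  d <- setNames(integer(length(net$nodes)), net$nodes)
  tab <- table(c(net$edges$from, net$edges$to))
  d[names(tab)] <- as.integer(tab)
  d
}

#' Read an undirected edge list
#'
#' Supports plain two-column interactor files (`tsv2col`, whitespace- or
#' tab-separated) and SIF rows (`nodeA<TAB>relation<TAB>nodeB`; the relation
#' is ignored). Lines starting with `#` and blank lines are skipped. Edge
#' direction in the file is ignored: the network is undirected. Self-loops
#' and duplicate rows are dropped and counted (reported via a message and the
#' `"dropped"` attribute).
#'
#' @param path file path.
#' @param dialect `"tsv2col"` or `"sif"`.
#' @param source resource label recorded on every edge; defaults to the
#'   file's base name.
#' @return a `ppi_network`. An empty file yields an empty network with a
#'   warning. A row with the wrong number of fields is a parse error naming
#'   the offending line.
#' @export
read_edge_list <- function(path, dialect = c("tsv2col", "sif"),
                           source = basename(path)) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    warning(sprintf("'%s' contains no data rows; returning an empty network", path))
    return(ppi_network(source = source))
  }
  want <- if (dialect == "tsv2col") 2L else 3L
  split_re <- if (dialect == "tsv2col") "[\t ]+" else "\t"
  parts <- strsplit(trimws(lines[idx]), split_re)
  nf <- lengths(parts)
  if (any(nf != want)) {
    bad <- idx[which(nf != want)[1L]]
    stop(sprintf("parse error in '%s' line %d: expected %d fields, found %d",
                 path, bad, want, nf[which(nf != want)[1L]]))
  }
  a <- vapply(parts, `[[`, character(1), 1L)
  b <- vapply(parts, `[[`, character(1), want)
  net <- ppi_network(a, b, source = source)
  if (attr(net, "dropped") > 0)
    message(sprintf("read_edge_list: dropped %d self-loop/duplicate row(s) from '%s'",
                    attr(net, "dropped"), path))
  net
}

#' Write a network as a two-column TSV edge list
#'
#' Isolated nodes cannot be represented in an edge list and are omitted;
#' round-tripping is exact for networks whose every node has degree >= 1.
#'
#' @param net a `ppi_network`.
#' @param path output file path.
#' @export
write_edge_list <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# undirected edge list (ipmsnet)", con)
  if (n_edges(net))
    writeLines(paste(net$edges$from, net$edges$to, sep = "\t"), con)
  invisible(path)
}

#' Merge PPI networks by union
#'
#' Node and edge sets are unioned; an edge contributed by several resources
#' becomes one edge whose `sources` is the union of the contributing labels.
#' Commutative, associative and idempotent on node and edge sets.
#'
#' @param ... `ppi_network` objects, or a single list of them.
#' @return the merged `ppi_network`.
#' @export
merge_networks <- function(...) {
  nets <- list(...)
  if (length(nets) == 1L && !inherits(nets[[1L]], "ppi_network"))
    nets <- nets[[1L]]
  stopifnot(length(nets) >= 1L,
            all(vapply(nets, inherits, logical(1), "ppi_network")))
  from <- unlist(lapply(nets, function(n) n$edges$from), use.names = FALSE)
  to <- unlist(lapply(nets, function(n) n$edges$to), use.names = FALSE)
  srcs <- do.call(c, lapply(nets, `[[`, "sources"))
  key <- paste(from, to, sep = "\r")
  merged_src <- lapply(split(srcs, key), function(s) sort(unique(unlist(s))))
  ukey <- sort(unique(key))
  pieces <- strsplit(ukey, "\r", fixed = TRUE)
  lo <- vapply(pieces, `[[`, character(1), 1L)
  hi <- vapply(pieces, `[[`, character(1), 2L)
  nodes <- sort(unique(unlist(lapply(nets, `[[`, "nodes"))))
  new_ppi_network(nodes, lo, hi, unname(merged_src[ukey]))
}

#' Hit list: ordered, deduplicated protein symbols with a provenance label
#'
#' @param symbols character vector of protein symbols (input order preserved;
#'   duplicates after normalization are removed, keeping the first).
#' @param label provenance string, e.g. `"human IP-MS"`.
#' @return a `hit_list` object with components `symbols` and `label`.
#' @export
hit_list <- function(symbols, label = "hits") {
  s <- normalize_symbol(symbols)
  s <- s[nzchar(s)]
  s <- s[!duplicated(s)]
  structure(list(symbols = s, label = label), class = "hit_list")
}

#' @export
print.hit_list <- function(x, ...) {
  cat(sprintf("Hit list '%s': %d symbols\n", x$label, length(x$symbols)))
  cat("  ", paste(head(x$symbols, 8), collapse = ", "),
      if (length(x$symbols) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Read a gene list (one symbol per line)
#'
#' `#` comment lines and blank lines are skipped; symbols are normalized and
#' deduplicated, preserving file order.
#'
#' @param path file path.
#' @param label provenance label; defaults to the file's base name.
#' @return a [hit_list()].
#' @export
read_gene_list <- function(path, label = basename(path)) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  hit_list(lines[nzchar(trimws(lines))], label = label)
}

#' @rdname read_gene_list
#' @param hits a `hit_list` to write.
#' @export
write_gene_list <- function(hits, path) {
  writeLines(hits$symbols, path)
  invisible(path)
}

#' Gene-set library
#'
#' A named collection of gene sets (e.g. GO terms, CORUM complexes, disease
#' gene sets). Member symbols are normalized and deduplicated; the library
#' `universe` is the union of all term sets.
#'
#' @param terms named list of character vectors (term name -> member symbols).
#' @param name library label.
#' @param descriptions optional named character vector of term descriptions.
#' @return a `gene_set_library` with components `name`, `terms`,
#'   `descriptions`, `universe`.
#' @export
gene_set_library <- function(terms, name = "library", descriptions = NULL) {
  stopifnot(is.list(terms), length(names(terms)) == length(terms),
            all(nzchar(names(terms))))
  terms <- lapply(terms, function(g) {
    g <- normalize_symbol(g)
    unique(g[nzchar(g)])
  })
  if (any(lengths(terms) == 0L))
    stop("every term must contain at least one symbol after normalization")
  structure(
    list(name = name, terms = terms,
         descriptions = descriptions %||% setNames(rep("na", length(terms)), names(terms)),
         universe = sort(unique(unlist(terms, use.names = FALSE)))),
    class = "gene_set_library"
  )
}

#' @export
print.gene_set_library <- function(x, ...) {
  cat(sprintf("Gene-set library '%s': %d terms, %d distinct symbols\n",
              x$name, length(x$terms), length(x$universe)))
  invisible(x)
}

#' Read / write a GMT gene-set library
#'
#' Standard GMT: `term<TAB>description<TAB>gene1<TAB>gene2...` per row. The
#' description column is preserved but unused by the statistics.
#'
#' @param path file path.
#' @param name library label; defaults to the file's base name.
#' @return `read_gmt` returns a [gene_set_library()]. A row with fewer than
#'   3 columns is a parse error naming the line.
#' @export
read_gmt <- function(path, name = basename(path)) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    bad <- which(nf < 3L)[1L]
    stop(sprintf("parse error in '%s' line %d: GMT rows need >= 3 tab-separated columns, found %d",
                 path, keep[bad], nf[bad]))
  }
  terms <- lapply(parts, function(p) p[-(1:2)])
  names(terms) <- vapply(parts, `[[`, character(1), 1L)
  desc <- setNames(vapply(parts, `[[`, character(1), 2L), names(terms))
  gene_set_library(terms, name = name, descriptions = desc)
}

#' @rdname read_gmt
#' @param library a `gene_set_library` to write.
#' @export
write_gmt <- function(library, path) {
  rows <- vapply(names(library$terms), function(tm) {
    paste(c(tm, unname(library$descriptions[tm]), library$terms[[tm]]),
          collapse = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Read an ortholog map (two-column TSV, source -> target symbol)
#'
#' The map is a function: one target per source. Both columns are normalized.
#'
#' @param path file path; `#` comments skipped.
#' @return named character vector (names = source symbols, values = targets).
#' @export
read_ortholog_map <- function(path) {
  stopifnot(file.exists(path))
  tab <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    colClasses = "character", quote = "",
                    col.names = c("source", "target"))
  src <- normalize_symbol(tab$source)
  tgt <- normalize_symbol(tab$target)
  keep <- nzchar(src) & nzchar(tgt)
  src <- src[keep]; tgt <- tgt[keep]
  dup <- duplicated(src)
  if (any(tgt[dup] != tgt[match(src[dup], src)]))
    stop("ortholog map is not a function: a source symbol maps to two targets")
  setNames(tgt[!dup], src[!dup])
}

#' Translate a hit list through an ortholog map
#'
#' Symbols present in the map are replaced by their targets; symbols absent
#' from the map pass through unchanged. The result is re-deduplicated,
#' preserving order of first appearance.
#'
#' @param hits a [hit_list()].
#' @param map named character vector from [read_ortholog_map()].
#' @return a `hit_list` in the target namespace.
#' @export
apply_ortholog_map <- function(hits, map) {
  stopifnot(inherits(hits, "hit_list"))
  s <- hits$symbols
  mapped <- ifelse(s %in% names(map), unname(map[s]), s)
  hit_list(mapped, label = paste0(hits$label, " (mapped)"))
}
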