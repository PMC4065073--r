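#' Build and validate an analysis configuration
#'
#' Collects every input and parameter of the full pipeline into one
#' validated object. Inputs may be given as file paths (read with the
#' package's parsers) or as in-memory objects (`ppi_network`, `hit_list`,
#' `gene_set_library`), which is convenient for synthetic runs. A YAML file
#' with the same field names can be loaded via `config_file`; explicit
#' arguments override the file.
#'
#' @param networks list of edge-list file paths and/or `ppi_network`
#'   objects (merged by union).
#' @param hits a gene-list path / `hit_list`, or a list of up to two of them
#'   (a second list triggers the cross-screen overlap test).
#' @param gmt_libraries list of GMT paths and/or `gene_set_library` objects
#'   used for hit-list and community enrichment.
#' @param disease_library optional GMT path / `gene_set_library` for the
#'   disease membership lookup.
#' @param ortholog_map optional two-column TSV path or named character
#'   vector, applied to the second hit list before the overlap test.
#' @param n_samples permutation-null sample count (default 1e5).
#' @param seed RNG seed for the permutation null.
#' @param set_size_policy `"matched"` (default: random sets have the size of
#'   the hit set matched to the network — only matched symbols can contribute
#'   edges) or `"total"` (full hit-list size).
#' @param universe optional enrichment universe (character vector); default:
#'   each library's own universe.
#' @param overlap_universe_size background size for the overlap test
#'   (default 20000, protein-coding-genome scale).
#' @param min_cluster_size smallest community annotated (default 3).
#' @param bh_alpha BH significance level used in report summaries
#'   (default 0.05).
#' @param dialect edge-list dialect, `"tsv2col"` or `"sif"`.
#' @param config_file optional YAML file providing any of the above fields.
#' @return a validated `ppi_config` list.
#' @export
ppi_config <- function(networks = NULL, hits = NULL, gmt_libraries = list(),
                       disease_library = NULL, ortholog_map = NULL,
                       n_samples = 1e5, seed = 1L,
                       set_size_policy = c("matched", "total"),
                       universe = NULL, overlap_universe_size = 20000,
                       min_cluster_size = 3, bh_alpha = 0.05,
                       dialect = c("tsv2col", "sif"), config_file = NULL) {
  if (!is.null(config_file)) {
    stopifnot(file.exists(config_file))
    y <- yaml::read_yaml(config_file)
    call_args <- as.list(match.call())[-1]
    for (f in setdiff(names(y), c(names(call_args), "config_file")))
      assign(f, y[[f]])
  }
  set_size_policy <- match.arg(set_size_policy)
  dialect <- match.arg(dialect)
  stopifnot(n_samples >= 1, min_cluster_size >= 1,
            bh_alpha > 0, bh_alpha < 1, overlap_universe_size >= 1)
  if (is.null(networks)) stop("config needs at least one background network")
  if (inherits(networks, "ppi_network") || is.character(networks))
    networks <- list(networks)
  if (is.null(hits)) stop("config needs at least one hit list")
  if (inherits(hits, "hit_list") || (is.character(hits) && length(hits) == 1))
    hits <- list(hits)
  stopifnot(length(hits) >= 1, length(hits) <= 2)
  if (inherits(gmt_libraries, "gene_set_library")) gmt_libraries <- list(gmt_libraries)
  for (x in c(networks, hits, gmt_libraries,
              if (!is.null(disease_library)) list(disease_library)))
    if (is.character(x) && !all(file.exists(x)))
      stop(sprintf("input file not found: %s", x[!file.exists(x)][1]))
  if (is.character(ortholog_map) && length(ortholog_map) == 1 &&
      is.null(names(ortholog_map)) && !file.exists(ortholog_map))
    stop(sprintf("ortholog map file not found: %s", ortholog_map))
  structure(
    list(networks = networks, hits = hits, gmt_libraries = gmt_libraries,
         disease_library = disease_library, ortholog_map = ortholog_map,
         n_samples = as.integer(n_samples), seed = seed,
         set_size_policy = set_size_policy, universe = universe,
         overlap_universe_size = overlap_universe_size,
         min_cluster_size = min_cluster_size, bh_alpha = bh_alpha,
         dialect = dialect),
    class = "ppi_config"
  )
}

load_input <- function(x, kind, config) {
  if (kind == "network" && inherits(x, "ppi_network")) return(x)
  if (kind == "hits" && inherits(x, "hit_list")) return(x)
  if (kind == "gmt" && inherits(x, "gene_set_library")) return(x)
  if (kind == "orthomap" && is.character(x) && !is.null(names(x))) return(x)
  stopifnot(is.character(x), length(x) == 1)
  switch(kind,
         network = read_edge_list(x, dialect = config$dialect),
         hits = read_gene_list(x),
         gmt = read_gmt(x),
         orthomap = read_ortholog_map(x))
}

input_digests <- function(config) {
  paths <- unlist(Filter(is.character,
                         c(config$networks, config$hits, config$gmt_libraries,
                           list(config$disease_library, config$ortholog_map))))
  paths <- paths[!is.null(paths) & file.exists(paths %||% character())]
  if (!length(paths)) return(character())
  setNames(as.character(tools::md5sum(paths)), basename(paths))
}

#' Run the full IP-MS network analysis
#'
#' Orchestrates the pipeline: merge background networks, match the hit
#' list(s), extract the induced subnetwork, run the permutation
#' interaction-density test, compare degree distributions (hub check),
#' detect communities by greedy modularity, enrich the hit list and each
#' community against the gene-set libraries, look up disease-term
#' membership, and (with two hit lists) test the cross-screen overlap. Any
#' stage failure aborts with the stage name. A hit list disjoint from the
#' network yields a report with empty subnetwork sections and a prominent
#' warning rather than an error.
#'
#' @param config a [ppi_config()].
#' @param output_dir optional directory; when given, every stage output is
#'   written there (TSV/JSON) together with a `manifest.json` recording
#'   parameters, seeds and input digests.
#' @param verbose print stage progress messages.
#' @return a `ppi_report` object; see its `print`, `summary` and `plot`
#'   methods.
#' @export
run_ppi_analysis <- function(config, output_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "ppi_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  run_stage <- function(stage, expr) {
    say("stage: %s", stage)
    tryCatch(expr, error = function(e) stop_stage(stage, e))
  }

  network <- run_stage("load_networks", {
    merge_networks(lapply(config$networks, load_input, kind = "network",
                          config = config))
  })
  hits <- run_stage("load_hits", {
    hl <- lapply(config$hits, load_input, kind = "hits", config = config)
    if (!is.null(config$ortholog_map) && length(hl) == 2) {
      om <- load_input(config$ortholog_map, "orthomap", config)
      hl[[2]] <- apply_ortholog_map(hl[[2]], om)
    }
    hl
  })
  libraries <- run_stage("load_libraries", {
    lapply(config$gmt_libraries, load_input, kind = "gmt", config = config)
  })
  disease <- if (!is.null(config$disease_library))
    run_stage("load_disease_library",
              load_input(config$disease_library, "gmt", config))

  sub <- run_stage("induce_subnetwork", induce_subnetwork(network, hits[[1]]))
  empty_sub <- n_edges(sub$network) == 0
  if (sub$n_hits_in_network == 0)
    warning("hit list is disjoint from the background network; ",
            "subnetwork, density and community sections are empty",
            call. = FALSE)

  perm <- if (sub$n_hits_in_network >= 1) run_stage("permutation_density_test", {
    set_size <- if (config$set_size_policy == "matched")
      sub$n_hits_in_network else min(sub$n_hits_total, length(network$nodes))
    permutation_density_test(network, set_size = set_size,
                             observed = n_edges(sub$network),
                             n_samples = config$n_samples, seed = config$seed)
  })

  degcmp <- if (sub$n_hits_in_network >= 1) run_stage("degree_comparison", {
    compare_degree_distributions(degree_distribution(sub$network),
                                 degree_distribution(network))
  })

  communities <- if (!empty_sub)
    run_stage("greedy_modularity", greedy_modularity(sub$network))
  ordering <- if (!is.null(communities))
    run_stage("order_by_community", order_by_community(sub$network, communities))

  list_enrichment <- if (length(libraries)) run_stage("list_enrichment", {
    lapply(libraries, function(lib)
      fisher_enrichment(hits[[1]], lib, universe = config$universe))
  })
  cluster_annotation <- if (!is.null(communities) && length(libraries))
    run_stage("annotate_clusters",
              annotate_clusters(communities, libraries,
                                universe = config$universe,
                                min_size = config$min_cluster_size))
  disease_table <- if (!is.null(disease))
    run_stage("disease_lookup", disease_lookup(hits[[1]], disease))
  overlap <- if (length(hits) == 2)
    run_stage("overlap_test",
              overlap_test(hits[[1]], hits[[2]],
                           universe_size = config$overlap_universe_size))

  report <- structure(
    list(config = config,
         network = network,
         hits = hits,
         subnetwork = sub,
         permutation = perm,
         degree_comparison = degcmp,
         communities = communities,
         ordering = ordering,
         list_enrichment = list_enrichment,
         cluster_annotation = cluster_annotation,
         disease_table = disease_table,
         overlap = overlap,
         seeds = list(permutation = config$seed),
         input_digests = input_digests(config),
         incomplete = empty_sub),
    class = "ppi_report"
  )
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

## Write every stage output plus a manifest under one run directory.
write_report <- function(report, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(output_dir, ...)
  written <- character()
  add <- function(path) written <<- c(written, basename(path))

  write_edge_list(report$network, p("background_network.tsv")); add("background_network.tsv")
  if (!is.null(report$subnetwork)) {
    write_edge_list(report$subnetwork$network, p("induced_subnetwork.tsv"))
    add("induced_subnetwork.tsv")
  }
  if (!is.null(report$permutation)) {
    write_null_counts(report$permutation, p("null_counts.tsv")); add("null_counts.tsv")
  }
  if (!is.null(report$communities)) {
    write_partition(report$communities, p("partition.tsv")); add("partition.tsv")
    A <- adjacency_matrix(report$subnetwork$network, report$ordering$order)
    write.table(A, p("adjacency_community_order.tsv"), sep = "\t", quote = FALSE)
    add("adjacency_community_order.tsv")
  }
  for (nm in names(report$list_enrichment %||% list())) {
    f <- sprintf("enrichment_%s.tsv", gsub("[^A-Za-z0-9._-]", "_", nm))
    write_enrichment(report$list_enrichment[[nm]], p(f)); add(f)
  }
  if (!is.null(report$cluster_annotation) && nrow(report$cluster_annotation$summary)) {
    write_enrichment(report$cluster_annotation$summary, p("cluster_top_terms.tsv"))
    add("cluster_top_terms.tsv")
    for (cid in names(report$cluster_annotation$results))
      for (ln in names(report$cluster_annotation$results[[cid]])) {
        f <- sprintf("cluster_%s_%s.tsv", cid, gsub("[^A-Za-z0-9._-]", "_", ln))
        write_enrichment(report$cluster_annotation$results[[cid]][[ln]], p(f)); add(f)
      }
  }
  if (!is.null(report$disease_table)) {
    write.table(report$disease_table, p("disease_lookup.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    add("disease_lookup.tsv")
  }
  if (!is.null(report$overlap)) {
    write_enrichment(report$overlap, p("overlap_test.tsv")); add("overlap_test.tsv")
  }
  manifest <- list(
    parameters = report$config[c("n_samples", "seed", "set_size_policy",
                                 "overlap_universe_size", "min_cluster_size",
                                 "bh_alpha", "dialect")],
    seeds = report$seeds,
    input_digests = as.list(report$input_digests),
    incomplete = report$incomplete,
    files = written)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(output_dir)
}

#' @export
print.ppi_report <- function(x, ...) {
  cat("IP-MS network analysis report\n")
  cat(sprintf("  background: %d nodes, %d edges\n",
              length(x$network$nodes), n_edges(x$network)))
  s <- x$subnetwork
  cat(sprintf("  hit list '%s': %d symbols, %d matched; induced subnetwork: %d edges\n",
              s$label, s$n_hits_total, s$n_hits_in_network, n_edges(s$network)))
  if (!is.null(x$permutation))
    cat(sprintf("  density: observed %d vs null mean %.1f; empirical p = %.3g\n",
                x$permutation$observed, mean(x$permutation$null_counts),
                x$permutation$p_empirical))
  if (!is.null(x$degree_comparison))
    cat(sprintf("  hub check: KS D = %.3f, p = %.3g (%s)\n",
                x$degree_comparison$statistic, x$degree_comparison$p_value,
                x$degree_comparison$verdict))
  if (!is.null(x$communities))
    cat(sprintf("  communities: k = %d, Q = %.4f\n",
                x$communities$k, x$communities$Q))
  if (!is.null(x$overlap))
    cat(sprintf("  cross-screen overlap: %d shared symbols, p = %.3g (N = %d)\n",
                x$overlap$k, x$overlap$p, x$overlap$N))
  if (x$incomplete)
    cat("  ** INCOMPLETE: induced subnetwork empty; downstream sections missing **\n")
  invisible(x)
}

#' @export
summary.ppi_report <- function(object, n_terms = 5, ...) {
  print(object)
  if (!is.null(object$list_enrichment)) {
    cat("\nTop hit-list enrichment terms:\n")
    for (nm in names(object$list_enrichment))
      print(object$list_enrichment[[nm]], n = n_terms)
  }
  if (!is.null(object$cluster_annotation)) {
    cat("\nPer-community top terms:\n")
    print(object$cluster_annotation)
  }
  if (!is.null(object$disease_table) && nrow(object$disease_table)) {
    cat("\nDisease-term membership:\n")
    print.data.frame(object$disease_table)
  }
  invisible(object)
}

#' @export
plot.ppi_report <- function(x, ...) {
  has_perm <- !is.null(x$permutation)
  has_comm <- !is.null(x$communities)
  op <- par(mfrow = c(1, has_perm + has_comm))
  on.exit(par(op))
  if (has_perm) plot(x$permutation)
  if (has_comm) {
    A <- adjacency_matrix(x$subnetwork$network, x$ordering$order)
    n <- nrow(A)
    image(seq_len(n), seq_len(n), A[, n:1, drop = FALSE],
          col = c("white", "grey20"), xlab = "", ylab = "",
          main = "Adjacency in community order", axes = FALSE)
    for (b in head(x$ordering$boundaries, -1)) {
      abline(v = b + 0.5, col = "orange", lwd = 1.5)
      abline(h = n - b + 0.5, col = "orange", lwd = 1.5)
    }
  }
  invisible(x)
}
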