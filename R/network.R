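# Degree-based connectivity null on protein-protein interaction edge lists:
# size-matched random gene sets give a range of mean induced degrees; a
# disorder set is significantly connected when its observed mean degree
# exceeds the maximum control-run mean, and a protein is a hub when its
# within-network degree is at least one above the control mean.

#' Read a PPI edge list
#'
#' Two- or three-column TSV: `protein_a`, `protein_b` and an optional
#' `combined_score`. A header row is detected (and skipped) when the third
#' field of the first line is non-numeric or the line matches the expected
#' column names.
#'
#' @param path Path to the TSV file.
#' @param min_score Optional minimum `combined_score`; edges below it are
#'   dropped (default: no filter).
#' @return A tibble with columns `protein_a`, `protein_b` (and
#'   `combined_score` when present).
#' @export
read_edge_list <- function(path, min_score = NULL) {
  if (!file.exists(path)) {
    abort(paste0("Edge list not found: ", path), class = "matrixgc_io_error")
  }
  first <- strsplit(readLines(path, n = 1L, warn = FALSE), "\t")[[1]]
  has_header <- length(first) >= 2 &&
    (tolower(first[1]) %in% c("protein_a", "protein1", "node1") ||
       (length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3])))))
  tbl <- readr::read_tsv(
    path,
    col_names = has_header,
    show_col_types = FALSE, progress = FALSE
  )
  if (ncol(tbl) < 2) {
    abort("Edge list needs at least two columns", class = "matrixgc_parse_error")
  }
  names(tbl)[1:2] <- c("protein_a", "protein_b")
  if (ncol(tbl) >= 3) names(tbl)[3] <- "combined_score"
  tbl <- tbl[, seq_len(min(3, ncol(tbl)))]
  if (!is.null(min_score)) {
    if (!"combined_score" %in% names(tbl)) {
      abort("`min_score` given but the edge list has no score column",
            class = "matrixgc_validation_error")
    }
    tbl <- tbl[tbl$combined_score >= min_score, ]
  }
  as_tibble(tbl)
}

#' Build an undirected, simplified PPI graph from an edge table
#'
#' Self-loops are removed and duplicate edges (in either orientation)
#' collapsed.
#'
#' @param edges Tibble/data frame with columns `protein_a`, `protein_b`, or
#'   an existing igraph object (returned as is after simplification).
#' @return An undirected igraph graph.
#' @export
ppi_graph <- function(edges) {
  g <- if (igraph::is_igraph(edges)) {
    edges
  } else {
    igraph::graph_from_data_frame(
      edges[, c("protein_a", "protein_b")],
      directed = FALSE
    )
  }
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Within-set degrees of a gene set on a PPI graph
#'
#' Degrees are computed on the subgraph induced by `gene_set`; genes absent
#' from the graph get degree 0.
#'
#' @param graph An igraph graph or an edge table accepted by [ppi_graph()].
#' @param gene_set Character vector of gene/protein symbols.
#' @return Tibble with `protein` and `degree`, one row per unique gene in
#'   `gene_set`, input order preserved.
#' @export
induced_degrees <- function(graph, gene_set) {
  gene_set <- unique(gene_set)
  if (length(gene_set) == 0) {
    abort("`gene_set` is empty", class = "matrixgc_validation_error")
  }
  g <- ppi_graph(graph)
  present <- intersect(gene_set, igraph::V(g)$name)
  deg <- stats::setNames(rep(0L, length(gene_set)), gene_set)
  if (length(present) > 0) {
    sub <- igraph::induced_subgraph(g, present)
    deg[igraph::V(sub)$name] <- igraph::degree(sub)
  }
  tibble(protein = gene_set, degree = as.integer(deg))
}

#' Connectivity null from size-matched random gene sets
#'
#' Draws `n_runs` random gene sets of `set_size` without replacement from the
#' universe, computes each run's mean induced degree, and records the
#' extremes and the mean of the run means.
#'
#' @param graph An igraph graph or edge table.
#' @param universe Character vector of symbols to draw from.
#' @param set_size Genes per draw (must not exceed the universe).
#' @param n_runs Number of random draws (default 20).
#' @param seed Integer seed.
#' @return An object of class `matrixgc_connectivity_null`: `set_size`,
#'   `n_runs`, `run_means`, `min_degree`, `max_degree`, `mean_of_means`.
#' @export
connectivity_null <- function(graph, universe, set_size, n_runs = 20,
                              seed = NULL) {
  universe <- unique(universe)
  if (set_size > length(universe)) {
    abort(paste0("set_size ", set_size, " exceeds universe size ",
                 length(universe)),
          class = "matrixgc_validation_error")
  }
  g <- ppi_graph(graph)
  run_means <- with_seed(seed, {
    vapply(seq_len(n_runs), function(i) {
      draw <- universe[sample.int(length(universe), set_size)]
      mean(induced_degrees(g, draw)$degree)
    }, numeric(1))
  })
  structure(
    list(
      set_size = as.integer(set_size),
      n_runs = as.integer(n_runs),
      run_means = run_means,
      min_degree = min(run_means),
      max_degree = max(run_means),
      mean_of_means = mean(run_means)
    ),
    class = "matrixgc_connectivity_null"
  )
}

#' @export
print.matrixgc_connectivity_null <- function(x, ...) {
  cat(sprintf(
    "<matrixgc_connectivity_null> size %d | %d runs | mean degree %.3f [%.3f, %.3f]\n",
    x$set_size, x$n_runs, x$mean_of_means, x$min_degree, x$max_degree
  ))
  invisible(x)
}

#' @export
tidy.matrixgc_connectivity_null <- function(x, ...) {
  tibble(run = seq_len(x$n_runs), mean_degree = x$run_means)
}

#' @export
glance.matrixgc_connectivity_null <- function(x, ...) {
  tibble(
    set_size = x$set_size, n_runs = x$n_runs,
    min_degree = x$min_degree, max_degree = x$max_degree,
    mean_of_means = x$mean_of_means
  )
}

#' @export
autoplot.matrixgc_connectivity_null <- function(object, observed = NULL, ...) {
  p <- ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$mean_degree)) +
    ggplot2::geom_histogram(bins = 15, fill = "grey70", colour = "grey40") +
    ggplot2::labs(
      x = sprintf("Mean induced degree of random sets (size %d)",
                  object$set_size),
      y = "Runs"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_vline(xintercept = observed, colour = "red")
  }
  p
}

#' Is a gene set's connectivity outside the control range?
#'
#' Significant when the observed mean degree strictly exceeds the maximum
#' control-run mean.
#'
#' @param observed_mean_degree Mean induced degree of the disorder gene set.
#' @param null A [connectivity_null()] built at the matching set size.
#' @param set_size Optional observed set size; when given, it must equal
#'   `null$set_size`.
#' @return One-row tibble: `observed_mean_degree`, `null_min`, `null_max`,
#'   `null_mean`, `significant`.
#' @export
assess_significance <- function(observed_mean_degree, null, set_size = NULL) {
  stopifnot(inherits(null, "matrixgc_connectivity_null"))
  if (!is.null(set_size) && set_size != null$set_size) {
    abort(paste0("Observed set size ", set_size,
                 " does not match null set size ", null$set_size),
          class = "matrixgc_validation_error")
  }
  tibble(
    observed_mean_degree = observed_mean_degree,
    null_min = null$min_degree,
    null_max = null$max_degree,
    null_mean = null$mean_of_means,
    significant = observed_mean_degree > null$max_degree
  )
}

#' Call hub proteins against a connectivity null
#'
#' A protein is a hub when its within-network degree is at least one greater
#' than the mean control degree: `degree >= mean_of_means + 1` (inclusive).
#'
#' @param degrees Tibble with `protein` and `degree`, as from
#'   [induced_degrees()].
#' @param null A [connectivity_null()] for the matching set size.
#' @return Tibble `protein`, `degree`, `control_mean`, `is_hub`, sorted by
#'   degree descending with alphabetical tie-break.
#' @export
call_hubs <- function(degrees, null) {
  stopifnot(inherits(null, "matrixgc_connectivity_null"))
  out <- tibble(
    protein = degrees$protein,
    degree = degrees$degree,
    control_mean = null$mean_of_means,
    is_hub = degrees$degree >= null$mean_of_means + 1
  )
  arrange(out, desc(.data$degree), .data$protein)
}
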