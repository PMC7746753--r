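# Fisher-exact tissue-expression contrasts, Monte Carlo permutation test of
# DEG enrichment in candidate gene sets, and permutation-control exclusion of
# enrichment terms.

#' Tabulate a 2x2 bound-by-expressed contingency table
#'
#' Cross-tabulates membership in the bound set against expression above the
#' cutoff (strict inequality: a value exactly at the cutoff counts as not
#' expressed). Genes in `all_genes` missing from `expression` are dropped and
#' counted.
#'
#' @param bound Character vector of bound gene symbols (subset of `all_genes`).
#' @param all_genes Character vector: every gene of the study set.
#' @param expression Named numeric vector (gene -> expression level) for one
#'   tissue.
#' @param cutoff Expression cutoff; a gene is expressed when its level is
#'   strictly greater (default 0).
#' @return A list of class `matrixgc_contingency` with integer cells `a`
#'   (bound & expressed), `b` (bound & not expressed), `c` (not bound &
#'   expressed), `d` (not bound & not expressed), and `n_dropped`.
#' @export
tissue_contingency <- function(bound, all_genes, expression, cutoff = 0) {
  extra <- setdiff(bound, all_genes)
  if (length(extra) > 0) {
    abort(paste0("Bound genes not in `all_genes`: ",
                 paste(head(extra, 5), collapse = ", ")),
          class = "matrixgc_validation_error")
  }
  all_genes <- unique(all_genes)
  have <- all_genes[all_genes %in% names(expression)]
  n_dropped <- length(all_genes) - length(have)
  if (length(have) == 0) {
    abort("No genes with expression data after dropping missing entries",
          class = "matrixgc_validation_error")
  }
  is_bound <- have %in% bound
  is_expr <- expression[have] > cutoff
  structure(
    list(
      a = sum(is_bound & is_expr),
      b = sum(is_bound & !is_expr),
      c = sum(!is_bound & is_expr),
      d = sum(!is_bound & !is_expr),
      n_dropped = n_dropped
    ),
    class = "matrixgc_contingency"
  )
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p-value from the hypergeometric distribution (the sum of
#' probabilities of all tables with the observed margins at most as probable
#' as the observed one), with the sample odds ratio `a*d / (b*c)` — reported
#' as `Inf` when `b*c == 0` and `a*d > 0`, and `NaN` when both products are 0
#' (degenerate margin).
#'
#' @param a,b,c,d Non-negative integer cell counts; `a` may also be a
#'   `matrixgc_contingency` object, in which case `b`, `c`, `d` are taken
#'   from it.
#' @return One-row tibble with `odds_ratio` and `p_value`.
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  if (inherits(a, "matrixgc_contingency")) {
    tab <- a
    a <- tab$a; b <- tab$b; c <- tab$c; d <- tab$d
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("Cells must be non-negative integers",
          class = "matrixgc_validation_error")
  }
  m <- matrix(as.integer(cells), nrow = 2, byrow = TRUE)
  p <- if (sum(m) == 0) 1 else stats::fisher.test(m, alternative = "two.sided")$p.value
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c)
  }
  tibble(odds_ratio = or, p_value = p)
}

#' Fisher-exact expression contrasts for every tissue
#'
#' For each tissue column of an expression matrix, tabulates bound vs
#' expressed ([tissue_contingency()]) and tests the difference in expressed
#' proportion between bound and not-bound genes ([fisher_exact()]). Raw
#' p-values are reported without multiplicity correction.
#'
#' @param expression Tibble with a `gene` column and one numeric column per
#'   tissue (as from [synth_expression()]).
#' @param bound Character vector of bound gene symbols.
#' @param all_genes Study gene universe; defaults to `expression$gene`.
#' @param cutoff Expression cutoff (strict; default 0).
#' @return Tidy tibble with one row per tissue: `tissue`, `a`, `b`, `c`, `d`,
#'   `n_dropped`, `odds_ratio`, `p_value`.
#' @export
tissue_expression_test <- function(expression, bound, all_genes = NULL,
                                   cutoff = 0) {
  stopifnot("gene" %in% names(expression))
  all_genes <- all_genes %||% expression$gene
  tissues <- setdiff(names(expression), "gene")
  purrr::map_dfr(tissues, function(ts) {
    expr_vec <- stats::setNames(expression[[ts]], expression$gene)
    tab <- tissue_contingency(bound, all_genes, expr_vec, cutoff = cutoff)
    ft <- fisher_exact(tab)
    tibble(
      tissue = ts, a = tab$a, b = tab$b, c = tab$c, d = tab$d,
      n_dropped = tab$n_dropped,
      odds_ratio = ft$odds_ratio, p_value = ft$p_value
    )
  })
}

#' Monte Carlo test of differential-expression enrichment in a gene set
#'
#' Compares the percentage of candidate genes that are differentially
#' expressed (DE p-value at most `alpha`) with the same percentage in
#' `n_perm` random gene sets of equal size drawn without replacement from the
#' DE-table universe. Candidates absent from the DE table are dropped and the
#' effective size used for the draws. The empirical p-value uses the add-one
#' convention, `(1 + #\{null >= observed\}) / (1 + n_perm)`, so it is never
#' zero and ties count against the candidate set.
#'
#' @param de_table Tibble with columns `gene` and `pvalue` (the permutation
#'   universe is all its genes).
#' @param candidates Character vector of candidate gene symbols.
#' @param n_perm Number of permutations (default 1000).
#' @param alpha DE significance level (default 0.05, inclusive).
#' @param seed Integer seed.
#' @return An object of class `matrixgc_deg_test`: `observed_pct`,
#'   `observed_frac`, `null_pcts` (length `n_perm`), `empirical_p`, `n_perm`,
#'   `alpha`, `n_candidates_used`, `n_candidates_dropped`.
#' @export
monte_carlo_deg <- function(de_table, candidates, n_perm = 1000,
                            alpha = 0.05, seed = NULL) {
  if (n_perm < 1) {
    abort("`n_perm` must be >= 1", class = "matrixgc_validation_error")
  }
  stopifnot(all(c("gene", "pvalue") %in% names(de_table)))
  universe <- de_table$gene
  sig <- de_table$pvalue <= alpha
  used <- unique(candidates[candidates %in% universe])
  n_dropped <- length(unique(candidates)) - length(used)
  if (length(used) == 0) {
    abort(paste0("None of the ", length(unique(candidates)),
                 " candidate genes overlap the DE table"),
          class = "matrixgc_validation_error")
  }
  m <- length(used)
  observed_frac <- mean(sig[match(used, universe)])
  null_fracs <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) mean(sig[sample.int(length(universe), m)]),
           numeric(1))
  })
  observed_pct <- 100 * observed_frac
  null_pcts <- 100 * null_fracs
  empirical_p <- (1 + sum(null_pcts >= observed_pct)) / (1 + n_perm)
  structure(
    list(
      observed_pct = observed_pct,
      observed_frac = observed_frac,
      null_pcts = null_pcts,
      empirical_p = empirical_p,
      n_perm = as.integer(n_perm),
      alpha = alpha,
      n_candidates_used = m,
      n_candidates_dropped = n_dropped
    ),
    class = "matrixgc_deg_test"
  )
}

#' @export
print.matrixgc_deg_test <- function(x, ...) {
  cat(sprintf(
    "<matrixgc_deg_test> observed %.2f%% DEGs in %d genes | null mean %.2f%% | empirical p = %.4g (%d permutations)\n",
    x$observed_pct, x$n_candidates_used, mean(x$null_pcts),
    x$empirical_p, x$n_perm
  ))
  invisible(x)
}

#' @export
tidy.matrixgc_deg_test <- function(x, ...) {
  tibble(replicate = seq_len(x$n_perm), null_pct = x$null_pcts)
}

#' @export
glance.matrixgc_deg_test <- function(x, ...) {
  tibble(
    observed_pct = x$observed_pct,
    observed_frac = x$observed_frac,
    null_mean_pct = mean(x$null_pcts),
    empirical_p = x$empirical_p,
    n_perm = x$n_perm,
    alpha = x$alpha,
    n_candidates_used = x$n_candidates_used,
    n_candidates_dropped = x$n_candidates_dropped
  )
}

#' @export
autoplot.matrixgc_deg_test <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$null_pct)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_pct, colour = "red") +
    ggplot2::labs(
      x = "% DEGs in random size-matched gene sets",
      y = "Permutations",
      title = sprintf("Observed %.2f%% (red), empirical p = %.4g",
                      object$observed_pct, object$empirical_p)
    ) +
    ggplot2::theme_minimal()
}

#' Exclude enrichment terms that are significant in control gene sets
#'
#' Terms significantly enriched in any of the random control gene sets are
#' removed from the disorder term list; the remainder is kept.
#'
#' @param disorder_terms Character vector of enrichment term identifiers
#'   significant in the disorder gene set.
#' @param control_term_sets List of character vectors: terms significant in
#'   each control gene set.
#' @return A list of class `matrixgc_term_filter` with `kept_terms` and
#'   `excluded_terms` (disjoint; union = unique input terms). [tidy()]
#'   returns a tibble (`term`, `status`).
#' @export
exclude_control_terms <- function(disorder_terms, control_term_sets = list()) {
  disorder_terms <- unique(as.character(disorder_terms))
  control_union <- unique(unlist(control_term_sets, use.names = FALSE))
  excluded <- intersect(disorder_terms, control_union)
  structure(
    list(
      kept_terms = setdiff(disorder_terms, excluded),
      excluded_terms = excluded
    ),
    class = "matrixgc_term_filter"
  )
}

#' @export
tidy.matrixgc_term_filter <- function(x, ...) {
  bind_rows(
    tibble(term = x$kept_terms, status = "kept"),
    tibble(term = x$excluded_terms, status = "excluded")
  )
}
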