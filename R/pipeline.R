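# End-to-end pipeline: classify promoters, then any of the optional
# validation stages (roc / tissue / network / deg / terms) named by the run
# configuration. Every run writes the resolved configuration beside its
# outputs and a structured log with per-stage gene counts; a single base seed
# fans out to per-stage sub-seeds by fixed offsets so stages are
# independently reproducible.

STAGE_SEED_OFFSETS <- c(roc = 1L, network = 2L, deg = 3L, synth = 4L)

default_run_config <- function() {
  list(
    pwm_threshold = 65, gc_threshold = 60, upstream = 1000, flank = 100,
    grid = seq(5, 100, by = 5), n_bootstrap = 10,
    n_perm = 1000, alpha = 0.05, n_runs = 20,
    seed = 1L
  )
}

#' Read a run configuration from JSON
#'
#' Unspecified fields fall back to the defaults (PWM threshold 65, GC
#' threshold 60, 1000 bp promoters, 100 bp flanks, grid 5..100 by 5, 10
#' bootstraps, 1000 permutations, alpha 0.05, 20 network runs, seed 1).
#'
#' @param path Path to a JSON config file.
#' @return A named list of class `matrixgc_run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  resolve_run_config(cfg)
}

resolve_run_config <- function(cfg) {
  base <- default_run_config()
  merged <- utils::modifyList(base, cfg)
  structure(merged, class = c("matrixgc_run_config", "list"))
}

stage_seed <- function(config, stage) {
  off <- STAGE_SEED_OFFSETS[[stage]] %||% 0L
  as.integer(config$seed) + off
}

write_stage_tsv <- function(x, out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".tsv"))
  readr::write_tsv(as_tibble(x), path)
  path
}

#' Run the full classification-and-validation pipeline
#'
#' Executes the binding classification stage (genome + gene table, or a
#' promoter FASTA keyed by gene name, plus a PFM), then each optional stage
#' whose inputs are configured:
#' * `roc`: `positives_fasta` + `negatives_fasta` -> threshold calibration
#'   curves across GC settings (`gc_thresholds`, default none/50/60),
#' * `tissue`: `expression_tsv` (gene x tissue) -> Fisher contrasts of the
#'   bound vs not-bound genes per tissue,
#' * `network`: `edges_tsv` -> observed connectivity of the bound genes vs a
#'   size-matched null, plus hub calls,
#' * `deg`: `de_tsv` (gene, pvalue) -> Monte Carlo DEG-percentage test of the
#'   bound genes,
#' * `terms`: `disorder_terms` + `control_terms` (files, one id per line) ->
#'   control-permutation term exclusion.
#'
#' @param config A list / `matrixgc_run_config` (or path to a JSON file).
#'   Required fields: `pfm` and either (`genome_fasta` + `genes_tsv`) or
#'   `promoters_fasta`; `out_dir`.
#' @return The output directory, invisibly. Side effects: one TSV per stage,
#'   `config.json` (resolved config), `run.log`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- read_run_config(config)
  } else {
    config <- resolve_run_config(config)
  }
  out_dir <- config$out_dir %||% abort("`out_dir` is required",
                                       class = "matrixgc_validation_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    paste0("matrixgc ", as.character(utils::packageVersion("matrixgc"))),
    paste0("config_hash ", rlang::hash(config[setdiff(names(config), "out_dir")])),
    paste0("seed ", config$seed)
  )
  logit <- function(...) log_lines <<- c(log_lines, paste0(...))

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(
        paste0("Stage '", stage, "' failed: ", conditionMessage(e)),
        class = paste0("matrixgc_stage_error_", stage),
        parent = e
      )
    })
  }

  cfg <- matrixgc_config(config$pwm_threshold, config$gc_threshold,
                         config$upstream, config$flank)

  # -- classify (always) ------------------------------------------------
  calls <- run_stage("classify", {
    if (is.null(config$pfm)) {
      abort("`pfm` path is required", class = "matrixgc_validation_error")
    }
    pwm <- build_pwm(read_pfm(config$pfm))
    promoters <- if (!is.null(config$promoters_fasta)) {
      seqs <- read_fasta(config$promoters_fasta)
      tibble(gene = names(seqs), seq = unname(seqs),
             length = nchar(seqs), clipped = NA)
    } else if (!is.null(config$genome_fasta) && !is.null(config$genes_tsv)) {
      genome <- read_fasta(config$genome_fasta)
      genes <- read_gene_table(config$genes_tsv,
                               coord_base = config$coord_base %||% 0)
      extract_promoters(genes, genome, upstream = cfg$upstream)
    } else {
      abort("Provide `promoters_fasta` or `genome_fasta` + `genes_tsv`",
            class = "matrixgc_validation_error")
    }
    calls <- classify_gene_set(promoters, pwm, cfg)
    write_stage_tsv(tidy(calls), out_dir, "binding_calls")
    logit("classify genes=", nrow(calls), " bound=", sum(calls$bound),
          " bound_pct=", glance(calls)$bound_pct)
    attr(calls, "pwm") <- pwm
    calls
  })
  pwm <- attr(calls, "pwm")
  bound_genes <- calls$gene[calls$bound]

  # -- roc (optional) ---------------------------------------------------
  if (!is.null(config$positives_fasta) && !is.null(config$negatives_fasta)) {
    run_stage("roc", {
      as_prom <- function(path) {
        seqs <- read_fasta(path)
        tibble(gene = names(seqs), seq = unname(seqs))
      }
      curves <- compare_gc_settings(
        as_prom(config$positives_fasta), as_prom(config$negatives_fasta),
        pwm, cfg,
        gc_thresholds = config$gc_thresholds %||% c(NA, 50, 60),
        grid = config$grid, n_bootstrap = config$n_bootstrap,
        seed = stage_seed(config, "roc")
      )
      write_stage_tsv(tidy(curves), out_dir, "roc_points")
      write_stage_tsv(glance(curves), out_dir, "roc_auc")
      logit("roc settings=", length(curves), " auc=",
            paste(sprintf("%.4f", glance(curves)$auc), collapse = ","))
    })
  }

  # -- tissue (optional) ------------------------------------------------
  if (!is.null(config$expression_tsv)) {
    run_stage("tissue", {
      expr <- readr::read_tsv(config$expression_tsv, show_col_types = FALSE,
                              progress = FALSE)
      res <- tissue_expression_test(expr, bound_genes,
                                    all_genes = calls$gene)
      write_stage_tsv(res, out_dir, "tissue_fisher")
      logit("tissue tissues=", nrow(res), " min_p=",
            signif(min(res$p_value), 3))
    })
  }

  # -- network (optional) -----------------------------------------------
  if (!is.null(config$edges_tsv)) {
    run_stage("network", {
      g <- ppi_graph(read_edge_list(config$edges_tsv,
                                    min_score = config$min_score))
      universe <- config$network_universe %||% igraph::V(g)$name
      deg <- induced_degrees(g, bound_genes)
      null <- connectivity_null(g, universe, set_size = length(bound_genes),
                                n_runs = config$n_runs,
                                seed = stage_seed(config, "network"))
      sig <- assess_significance(mean(deg$degree), null)
      hubs <- call_hubs(deg, null)
      write_stage_tsv(glance(null), out_dir, "network_null")
      write_stage_tsv(sig, out_dir, "network_significance")
      write_stage_tsv(hubs, out_dir, "network_hubs")
      logit("network genes=", nrow(deg), " observed_mean=",
            signif(mean(deg$degree), 4), " significant=", sig$significant,
            " hubs=", sum(hubs$is_hub))
    })
  }

  # -- deg (optional) ---------------------------------------------------
  if (!is.null(config$de_tsv)) {
    run_stage("deg", {
      de <- readr::read_tsv(config$de_tsv, show_col_types = FALSE,
                            progress = FALSE)
      res <- monte_carlo_deg(de, bound_genes, n_perm = config$n_perm,
                             alpha = config$alpha,
                             seed = stage_seed(config, "deg"))
      write_stage_tsv(glance(res), out_dir, "deg_test")
      logit("deg used=", res$n_candidates_used, " observed_pct=",
            signif(res$observed_pct, 4), " empirical_p=",
            signif(res$empirical_p, 4))
    })
  }

  # -- terms (optional) -------------------------------------------------
  if (!is.null(config$disorder_terms)) {
    run_stage("terms", {
      disorder <- readLines(config$disorder_terms, warn = FALSE)
      controls <- lapply(config$control_terms %||% character(0),
                         readLines, warn = FALSE)
      res <- exclude_control_terms(disorder, controls)
      write_stage_tsv(tidy(res), out_dir, "term_filter")
      logit("terms kept=", length(res$kept_terms), " excluded=",
            length(res$excluded_terms))
    })
  }

  jsonlite::write_json(
    unclass(config), file.path(out_dir, "config.json"),
    auto_unbox = TRUE, pretty = TRUE, null = "null"
  )
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
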