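# Deterministic synthetic-data generators for every input class of the
# toolkit, with ground truth recorded so expected downstream outputs can be
# computed without re-deriving any randomness.
#
# Default study conditions: 1000 bp promoters, a 15 bp motif with 100 bp GC
# flanks, planted sites at 70% window GC for positives, background at 40% GC
# (close to the genome-wide human average), motif-free negatives.

sample_bases <- function(n, gc_percent) {
  p_gc <- gc_percent / 100
  sample(BASES[1:4], n, replace = TRUE,
         prob = c((1 - p_gc) / 2, p_gc / 2, p_gc / 2, (1 - p_gc) / 2))
}

count_gc <- function(chars) sum(chars %in% c("C", "G"))

# Synthesise 2*flank flanking bases so the realized GC of the
# (site + flanks) window is within `tol` points of `target`; bounded retries.
synth_flanks <- function(site_chars, flank, target, tol = 2, max_tries = 100) {
  W <- length(site_chars)
  win_len <- W + 2 * flank
  site_gc <- count_gc(site_chars)
  needed <- target / 100 * win_len - site_gc
  p_flank <- needed / (2 * flank)
  if (p_flank < -1e-9 || p_flank > 1 + 1e-9) {
    abort(
      sprintf(
        "GC target %.1f%% infeasible: site GC fixes flank GC probability at %.3f",
        target, p_flank
      ),
      class = "matrixgc_generation_error"
    )
  }
  p_flank <- min(max(p_flank, 0), 1)
  for (i in seq_len(max_tries)) {
    fl <- sample_bases(2 * flank, 100 * p_flank)
    gc <- 100 * (site_gc + count_gc(fl)) / win_len
    if (abs(gc - target) <= tol) {
      return(list(left = fl[seq_len(flank)],
                  right = fl[flank + seq_len(flank)],
                  window_gc = gc))
    }
  }
  abort(
    sprintf("Could not hit GC target %.1f%% within %d attempts", target, max_tries),
    class = "matrixgc_generation_error"
  )
}

degrade_site <- function(site_chars, k) {
  if (k == 0) return(site_chars)
  pos <- sample.int(length(site_chars), k)
  for (p in pos) {
    site_chars[p] <- sample(setdiff(BASES[1:4], site_chars[p]), 1)
  }
  site_chars
}

synth_one_promoter <- function(len, consensus, plant, gc_context,
                               background_gc, flank, degrade) {
  chars <- sample_bases(len, background_gc)
  if (!plant) {
    return(list(seq = paste(chars, collapse = ""), plant_pos = NA_integer_,
                window_gc = NA_real_, site_seq = NA_character_))
  }
  W <- nchar(consensus)
  if (len < W + 2 * flank) {
    abort("Promoter too short to hold the site plus both flanks",
          class = "matrixgc_generation_error")
  }
  site <- degrade_site(strsplit(consensus, "")[[1]], degrade)
  flank <- as.integer(flank)
  pos <- flank + sample.int(len - W - 2 * flank + 1, 1) - 1L # 0-based
  fl <- synth_flanks(site, flank, gc_context)
  chars[(pos - flank + 1):pos] <- fl$left
  chars[(pos + 1):(pos + W)] <- site
  chars[(pos + W + 1):(pos + W + flank)] <- fl$right
  list(seq = paste(chars, collapse = ""), plant_pos = pos,
       window_gc = fl$window_gc, site_seq = paste(site, collapse = ""))
}

#' Generate a synthetic promoter cohort with known binding ground truth
#'
#' Positive promoters receive an exact planted consensus site (optionally
#' degraded) with probability `plant_rate_pos`, embedded in flanks
#' synthesised to hit the target window GC within 2 points; negatives
#' likewise with their own parameters. The remainder of each promoter is
#' background sequence at `background_gc`. Planted sites always sit at least
#' `flank` bp from both promoter ends so their GC window is never clipped.
#'
#' @param n_positive,n_negative Cohort sizes.
#' @param pwm A `matrixgc_pwm` whose consensus is planted (alternative:
#'   `consensus`).
#' @param consensus Consensus site to plant (character); overrides `pwm`.
#' @param promoter_len Promoter length in bp (default 1000).
#' @param plant_rate_pos,plant_rate_neg Per-gene planting probabilities
#'   (defaults 1 and 0).
#' @param gc_context_pos,gc_context_neg Target GC percent of the planted
#'   site's window (defaults 70 and 40).
#' @param background_gc Background GC percent (default 40).
#' @param flank GC-window flank, bp (default 100).
#' @param degrade Number of consensus positions mutated in each planted site
#'   (default 0, i.e. percent score 100).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return A list with `promoters` (tibble `gene`, `seq`, `length`,
#'   `clipped`) and `truth` (tibble `gene`, `class`, `planted`, `plant_pos`,
#'   `window_gc`, `site_seq`).
#' @export
synth_cohort <- function(n_positive, n_negative, pwm = NULL, consensus = NULL,
                         promoter_len = 1000L,
                         plant_rate_pos = 1, plant_rate_neg = 0,
                         gc_context_pos = 70, gc_context_neg = 40,
                         background_gc = 40, flank = 100L, degrade = 0L,
                         seed = NULL) {
  consensus <- consensus %||% (if (!is.null(pwm)) pwm_consensus(pwm) else NULL)
  if (is.null(consensus)) {
    abort("Provide `pwm` or `consensus`", class = "matrixgc_validation_error")
  }
  stopifnot(
    plant_rate_pos >= 0, plant_rate_pos <= 1,
    plant_rate_neg >= 0, plant_rate_neg <= 1,
    gc_context_pos >= 0, gc_context_pos <= 100,
    gc_context_neg >= 0, gc_context_neg <= 100
  )
  spec <- tibble(
    gene = c(sprintf("POS%04d", seq_len(n_positive)),
             sprintf("NEG%04d", seq_len(n_negative))),
    class = rep(c("positive", "negative"), c(n_positive, n_negative)),
    rate = rep(c(plant_rate_pos, plant_rate_neg), c(n_positive, n_negative)),
    gc_ctx = rep(c(gc_context_pos, gc_context_neg), c(n_positive, n_negative))
  )
  rows <- with_seed(seed, {
    purrr::map(seq_len(nrow(spec)), function(i) {
      plant <- runif(1) < spec$rate[i]
      synth_one_promoter(promoter_len, consensus, plant, spec$gc_ctx[i],
                         background_gc, flank, degrade)
    })
  })
  promoters <- tibble(
    gene = spec$gene,
    seq = purrr::map_chr(rows, "seq"),
    length = promoter_len,
    clipped = FALSE
  )
  truth <- tibble(
    gene = spec$gene,
    class = spec$class,
    planted = !is.na(purrr::map_int(rows, "plant_pos")),
    plant_pos = purrr::map_int(rows, "plant_pos"),
    window_gc = purrr::map_dbl(rows, "window_gc"),
    site_seq = purrr::map_chr(rows, "site_seq")
  )
  list(promoters = promoters, truth = truth)
}

#' Generate a synthetic gene-by-tissue expression matrix
#'
#' Each tissue gets exactly `round(frac_expressed * n_genes)` expressed
#' genes (values drawn log-normal); all other entries are exactly 0.
#'
#' @param n_genes Number of genes (ignored when `genes` is given).
#' @param tissues Character vector of tissue names.
#' @param frac_expressed Expressed fraction per tissue, recycled to
#'   `length(tissues)`.
#' @param genes Optional gene symbols (default `G0001`, ...).
#' @param meanlog,sdlog Log-normal parameters for expressed values
#'   (defaults 2 and 1).
#' @param seed Integer seed.
#' @return Tibble with a `gene` column and one numeric column per tissue.
#' @export
synth_expression <- function(n_genes, tissues, frac_expressed = 0.7,
                             genes = NULL, meanlog = 2, sdlog = 1,
                             seed = NULL) {
  stopifnot(all(frac_expressed >= 0), all(frac_expressed <= 1))
  genes <- genes %||% sprintf("G%04d", seq_len(n_genes))
  n_genes <- length(genes)
  frac <- rep_len(frac_expressed, length(tissues))
  cols <- with_seed(seed, {
    purrr::map(seq_along(tissues), function(i) {
      k <- round(frac[i] * n_genes)
      vals <- rep(0, n_genes)
      if (k > 0) {
        idx <- sample.int(n_genes, k)
        vals[idx] <- stats::rlnorm(k, meanlog = meanlog, sdlog = sdlog)
      }
      vals
    })
  })
  names(cols) <- tissues
  dplyr::bind_cols(tibble(gene = genes), as_tibble(cols))
}

#' Generate a synthetic differential-expression result table
#'
#' Non-enriched genes get p ~ Uniform(0, 1); each gene of the enriched set is
#' significant (p <= `alpha`, drawn uniform on (0, alpha]) with probability
#' `effect`, and otherwise gets p uniform on (alpha, 1].
#'
#' @param n_genes Universe size.
#' @param enriched_set_size Number of enriched genes (the candidate truth
#'   set).
#' @param effect Probability that an enriched gene is significant; must be at
#'   least `alpha` (the baseline uniform rate).
#' @param alpha Significance level (default 0.05).
#' @param genes Optional gene symbols.
#' @param seed Integer seed.
#' @return A list with `de_table` (tibble `gene`, `pvalue`) and `enriched`
#'   (character vector of the enriched genes).
#' @export
synth_de_table <- function(n_genes, enriched_set_size, effect, alpha = 0.05,
                           genes = NULL, seed = NULL) {
  if (effect < alpha) {
    abort("`effect` must be at least the baseline rate `alpha`",
          class = "matrixgc_validation_error")
  }
  stopifnot(enriched_set_size <= n_genes)
  genes <- genes %||% sprintf("G%04d", seq_len(n_genes))
  out <- with_seed(seed, {
    enriched <- sample(genes, enriched_set_size)
    p <- runif(n_genes)
    is_enr <- genes %in% enriched
    hit <- is_enr & (runif(n_genes) < effect)
    p[hit] <- runif(sum(hit), 0, alpha)
    p[is_enr & !hit] <- runif(sum(is_enr & !hit), alpha, 1)
    list(de_table = tibble(gene = genes, pvalue = p), enriched = enriched)
  })
  out
}

#' Generate a synthetic PPI edge list with an optional planted clique
#'
#' An Erdos-Renyi random graph G(n, p) over named nodes, optionally with all
#' edges among a random subset of `planted_clique_size` nodes added (a
#' clique), whose members then have induced degree `clique_size - 1` within
#' the clique set.
#'
#' @param n_nodes Number of nodes.
#' @param edge_prob Background edge probability.
#' @param planted_clique_size Clique size (default 0, no clique).
#' @param seed Integer seed.
#' @return A list with `edges` (tibble `protein_a`, `protein_b`), `nodes`
#'   (all node names) and `clique` (clique member names).
#' @export
synth_ppi <- function(n_nodes, edge_prob, planted_clique_size = 0,
                      seed = NULL) {
  stopifnot(edge_prob >= 0, edge_prob <= 1,
            planted_clique_size <= n_nodes)
  nodes <- sprintf("P%04d", seq_len(n_nodes))
  out <- with_seed(seed, {
    g <- igraph::sample_gnp(n_nodes, edge_prob)
    igraph::V(g)$name <- nodes
    clique <- character(0)
    if (planted_clique_size >= 2) {
      clique <- sort(sample(nodes, planted_clique_size))
      g <- igraph::add_edges(g, as.vector(utils::combn(clique, 2)))
      g <- igraph::simplify(g)
    }
    el <- igraph::as_edgelist(g)
    list(
      edges = tibble(protein_a = el[, 1], protein_b = el[, 2]),
      nodes = nodes,
      clique = clique
    )
  })
  out
}
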