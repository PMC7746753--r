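# ROC calibration of the PWM percent-score threshold against positive
# control promoters and bootstrapped size-matched negative draws.
#
# A gene "classifies bound" at threshold t when its promoter has at least one
# match with percent score >= t passing the active GC filter. Each promoter
# is therefore summarised once by its best GC-passing match score; per-
# threshold classification is then a comparison against that score. TPR at t
# is the bound fraction of positives; FPR at t is the mean over bootstrap
# replicates of the bound fraction of the size-matched negative draws.

#' A single gene-level ROC point
#'
#' Maps the bound fraction of the positive set and the (bootstrap-averaged)
#' bound fraction of the negative set at one threshold to an (FPR, TPR) pair.
#'
#' @param bound_fraction_positives Fraction of positive genes classified
#'   bound at the threshold, in `[0, 1]`.
#' @param bound_fraction_negatives Fraction (or mean fraction over bootstrap
#'   replicates) of negative genes classified bound, in `[0, 1]`.
#' @return One-row tibble with `fpr` and `tpr`.
#' @export
gene_tpr_fpr <- function(bound_fraction_positives, bound_fraction_negatives) {
  stopifnot(
    bound_fraction_positives >= 0, bound_fraction_positives <= 1,
    bound_fraction_negatives >= 0, bound_fraction_negatives <= 1
  )
  tibble(fpr = bound_fraction_negatives, tpr = bound_fraction_positives)
}

#' Trapezoidal area under an ROC point set
#'
#' Anchors the points at (0, 0) and (1, 1), sorts by (FPR, TPR), and
#' integrates TPR over FPR by the trapezoid rule.
#'
#' @param fpr,tpr Numeric vectors of equal length with values in `[0, 1]`.
#' @param anchor Add the (0,0) and (1,1) anchors before integrating
#'   (default TRUE).
#' @return The AUC, a number in `[0, 1]`.
#' @export
trapezoid_auc <- function(fpr, tpr, anchor = TRUE) {
  stopifnot(length(fpr) == length(tpr))
  if (anchor) {
    fpr <- c(0, fpr, 1)
    tpr <- c(0, tpr, 1)
  }
  ord <- order(fpr, tpr)
  x <- fpr[ord]
  y <- tpr[ord]
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

# Bootstrap index draws: n_bootstrap without-replacement samples of
# `size` indices from 1..pool_size, deterministic given seed.
bootstrap_draws <- function(pool_size, size, n_bootstrap, seed) {
  if (size > pool_size) {
    abort(
      paste0("Bootstrap size ", size, " exceeds negative pool (", pool_size, ")"),
      class = "matrixgc_validation_error"
    )
  }
  with_seed(seed, {
    lapply(seq_len(n_bootstrap), function(i) sample.int(pool_size, size))
  })
}

# withr::with_seed when a seed is given, plain evaluation otherwise.
with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

roc_from_best_scores <- function(best_pos, best_neg, draws, grid) {
  points <- purrr::map_dfr(grid, function(t) {
    tpr <- mean(best_pos >= t)
    fpr <- mean(vapply(draws, function(ix) mean(best_neg[ix] >= t), numeric(1)))
    tibble(threshold = t, fpr = fpr, tpr = tpr)
  })
  auc <- trapezoid_auc(points$fpr, points$tpr)
  structure(
    list(points = points, auc = auc, grid = grid,
         n_positive = length(best_pos), n_bootstrap = length(draws),
         set_size = if (length(draws) > 0) length(draws[[1]]) else 0L),
    class = "matrixgc_roc"
  )
}

#' Build a gene-level ROC curve for threshold calibration
#'
#' Classifies the positive promoters once per threshold and each of
#' `n_bootstrap` seeded, size-matched, without-replacement draws from the
#' negative pool; the per-threshold FPR is the mean bound fraction over the
#' draws. Points are anchored at (0,0) and (1,1) and integrated by the
#' trapezoid rule.
#'
#' @param positives,negative_pool Promoter tibbles (`gene`, `seq`).
#' @param pwm A `matrixgc_pwm`.
#' @param config A [matrixgc_config()]; its `pwm_threshold` is ignored (the
#'   grid stratifies it), its `gc_threshold` and `flank` define the active GC
#'   filter. Use `gc_threshold = 0` for a PWM-only curve.
#' @param grid Strictly increasing percent-score thresholds in `[0, 100]`
#'   (default 5 to 100 in steps of 5).
#' @param n_bootstrap Number of negative resamples per threshold (default 10).
#' @param size Genes per negative draw (default: size-matched to
#'   `nrow(positives)`).
#' @param seed Integer seed for the bootstrap draws.
#' @return An object of class `matrixgc_roc`: `points` (tibble `threshold`,
#'   `fpr`, `tpr`), `auc`, `grid`, `n_positive`, `n_bootstrap`, `set_size`.
#'   [tidy()] returns the points; [glance()] the AUC and sizes.
#' @export
build_roc <- function(positives, negative_pool, pwm,
                      config = matrixgc_config(), grid = seq(5, 100, by = 5),
                      n_bootstrap = 10, size = NULL, seed = NULL) {
  if (nrow(positives) == 0) {
    abort("Positive set is empty", class = "matrixgc_validation_error")
  }
  if (is.unsorted(grid, strictly = TRUE) || any(grid < 0) || any(grid > 100)) {
    abort("`grid` must be strictly increasing within [0, 100]",
          class = "matrixgc_validation_error")
  }
  size <- size %||% nrow(positives)
  draws <- bootstrap_draws(nrow(negative_pool), size, n_bootstrap, seed)
  best_pos <- vapply(positives$seq, best_passing_score, numeric(1),
                     pwm = pwm, gc_threshold = config$gc_threshold,
                     flank = config$flank, USE.NAMES = FALSE)
  best_neg <- vapply(negative_pool$seq, best_passing_score, numeric(1),
                     pwm = pwm, gc_threshold = config$gc_threshold,
                     flank = config$flank, USE.NAMES = FALSE)
  roc_from_best_scores(best_pos, best_neg, draws, grid)
}

#' Compare ROC curves across GC-filter settings
#'
#' Builds one ROC curve per GC threshold setting with identical bootstrap
#' draws across settings, so curves differ only through the GC filter.
#' `NA` (or `0`) denotes no GC filtering (PWM only).
#'
#' @inheritParams build_roc
#' @param gc_thresholds Numeric vector of GC thresholds; `NA` = PWM only
#'   (default `c(NA, 50, 60)`).
#' @return A named list of `matrixgc_roc` objects (class `matrixgc_roc_set`),
#'   names like `"gc60"` / `"pwm_only"`. [glance()] tabulates the AUCs.
#' @export
compare_gc_settings <- function(positives, negative_pool, pwm,
                                config = matrixgc_config(),
                                gc_thresholds = c(NA, 50, 60),
                                grid = seq(5, 100, by = 5),
                                n_bootstrap = 10, size = NULL, seed = NULL) {
  size <- size %||% nrow(positives)
  draws <- bootstrap_draws(nrow(negative_pool), size, n_bootstrap, seed)
  curves <- purrr::map(gc_thresholds, function(gc) {
    gc_eff <- if (is.na(gc)) 0 else gc
    best_pos <- vapply(positives$seq, best_passing_score, numeric(1),
                       pwm = pwm, gc_threshold = gc_eff,
                       flank = config$flank, USE.NAMES = FALSE)
    best_neg <- vapply(negative_pool$seq, best_passing_score, numeric(1),
                       pwm = pwm, gc_threshold = gc_eff,
                       flank = config$flank, USE.NAMES = FALSE)
    roc_from_best_scores(best_pos, best_neg, draws, grid)
  })
  names(curves) <- ifelse(is.na(gc_thresholds), "pwm_only",
                          paste0("gc", gc_thresholds))
  structure(curves, class = "matrixgc_roc_set")
}

#' @export
print.matrixgc_roc <- function(x, ...) {
  cat(sprintf(
    "<matrixgc_roc> %d thresholds | %d positives vs %d x %d negatives | AUC %.4f\n",
    nrow(x$points), x$n_positive, x$n_bootstrap, x$set_size, x$auc
  ))
  invisible(x)
}

#' @export
tidy.matrixgc_roc <- function(x, ...) x$points

#' @export
glance.matrixgc_roc <- function(x, ...) {
  tibble(auc = x$auc, n_positive = x$n_positive,
         n_bootstrap = x$n_bootstrap, set_size = x$set_size)
}

#' @export
tidy.matrixgc_roc_set <- function(x, ...) {
  purrr::map_dfr(x, function(r) r$points, .id = "gc_setting")
}

#' @export
glance.matrixgc_roc_set <- function(x, ...) {
  purrr::map_dfr(x, glance, .id = "gc_setting")
}

#' @export
autoplot.matrixgc_roc <- function(object, ...) {
  pts <- bind_rows(
    tibble(threshold = NA_real_, fpr = 0, tpr = 0),
    object$points,
    tibble(threshold = NA_real_, fpr = 1, tpr = 1)
  )
  pts <- arrange(pts, .data$fpr, .data$tpr)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = pts[!is.na(pts$threshold), ]) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("Gene-level ROC (AUC = %.4f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.matrixgc_roc_set <- function(object, ...) {
  pts <- tidy(object)
  aucs <- glance(object)
  labs <- stats::setNames(
    sprintf("%s (AUC %.4f)", aucs$gc_setting, aucs$auc),
    aucs$gc_setting
  )
  pts$gc_setting <- labs[pts$gc_setting]
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$gc_setting)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = "GC filter") +
    ggplot2::theme_minimal()
}
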