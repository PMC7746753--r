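test_that("gene_tpr_fpr maps bound fractions onto ROC coordinates", {
  expect_equal(gene_tpr_fpr(1, 0), tibble::tibble(fpr = 0, tpr = 1))
  expect_equal(gene_tpr_fpr(0, 0), tibble::tibble(fpr = 0, tpr = 0))
  expect_equal(gene_tpr_fpr(0.6, 0.3), tibble::tibble(fpr = 0.3, tpr = 0.6))
})

test_that("trapezoid AUC: hand curve, anchored diagonal, degenerate corners", {
  # hand trapezoid over {(0,0), (0.2,0.8), (1,1)} = 0.2*0.4 + 0.8*0.9 = 0.8
  expect_equal(trapezoid_auc(0.2, 0.8), 0.8, tolerance = 1e-12)
  # hand trapezoid over {(0,0), (0.2,1), (1,1)} = 0.2*0.5 + 0.8*1 = 0.9
  expect_equal(trapezoid_auc(0.2, 1), 0.9, tolerance = 1e-12)
  # anchored diagonal is the random classifier
  expect_equal(trapezoid_auc(seq(0, 1, 0.05), seq(0, 1, 0.05)), 0.5,
               tolerance = 1e-12)
  # all points at (0,1): perfect separation
  expect_equal(trapezoid_auc(rep(0, 5), rep(1, 5)), 1, tolerance = 1e-12)
  # all points at (1,0): always-wrong classifier
  expect_equal(trapezoid_auc(rep(1, 5), rep(0, 5)), 0, tolerance = 1e-12)
})

make_separable_cohort <- function(n_pos = 12, n_neg = 24, seed = 41) {
  pwm <- build_pwm(example_pfm())
  co <- synth_cohort(n_pos, n_neg, pwm = pwm, promoter_len = 600,
                     plant_rate_pos = 1, plant_rate_neg = 0,
                     gc_context_pos = 70, background_gc = 20, seed = seed)
  list(
    pwm = pwm,
    pos = co$promoters[co$truth$class == "positive", ],
    neg = co$promoters[co$truth$class == "negative", ]
  )
}

test_that("a perfectly separable cohort gives AUC exactly 1", {
  ch <- make_separable_cohort()
  roc <- build_roc(ch$pos, ch$neg, ch$pwm, size = nrow(ch$pos),
                   n_bootstrap = 5, seed = 42)
  expect_equal(roc$auc, 1)
  expect_true(all(roc$points$tpr == 1))
  expect_true(all(roc$points$fpr == 0))
})

test_that("build_roc is deterministic given seed and validates its inputs", {
  ch <- make_separable_cohort(6, 12, seed = 43)
  r1 <- build_roc(ch$pos, ch$neg, ch$pwm, n_bootstrap = 3, seed = 7)
  r2 <- build_roc(ch$pos, ch$neg, ch$pwm, n_bootstrap = 3, seed = 7)
  expect_identical(r1$points, r2$points)
  expect_identical(r1$auc, r2$auc)

  expect_error(build_roc(ch$pos[0, ], ch$neg, ch$pwm),
               class = "matrixgc_validation_error")
  expect_error(build_roc(ch$pos, ch$neg, ch$pwm, grid = c(10, 5)),
               class = "matrixgc_validation_error")
  expect_error(build_roc(ch$pos, ch$neg, ch$pwm, size = 1000, seed = 1),
               class = "matrixgc_validation_error")
})

test_that("bootstrap-averaged FPR equals pooling for equal-size replicates", {
  ch <- make_separable_cohort(6, 12, seed = 44)
  # plant some negatives so FPR is non-trivial
  co <- synth_cohort(6, 12, pwm = ch$pwm, promoter_len = 600,
                     plant_rate_pos = 1, plant_rate_neg = 0.5,
                     gc_context_pos = 70, gc_context_neg = 65,
                     background_gc = 30, seed = 45)
  pos <- co$promoters[co$truth$class == "positive", ]
  neg <- co$promoters[co$truth$class == "negative", ]
  roc <- build_roc(pos, neg, ch$pwm, n_bootstrap = 4, size = 6, seed = 9)

  # recompute: mean over replicates of per-replicate fractions must equal
  # the pooled fraction over the concatenated draws
  draws <- matrixgc:::bootstrap_draws(nrow(neg), 6, 4, seed = 9)
  best <- vapply(neg$seq, matrixgc:::best_passing_score, numeric(1),
                 pwm = ch$pwm, gc_threshold = 60, flank = 100,
                 USE.NAMES = FALSE)
  for (k in c(1, 7, 13)) {
    t <- roc$points$threshold[k]
    pooled <- mean(best[unlist(draws)] >= t)
    expect_equal(roc$points$fpr[k], pooled, tolerance = 1e-12)
  }
})

test_that("GC filtering carries signal when truth requires high GC", {
  pwm <- build_pwm(example_pfm())
  # positives: planted site in high-GC context; negatives: planted site in
  # GC-poor context -> only the GC filter separates them
  pos <- synth_cohort(10, 0, pwm = pwm, promoter_len = 600,
                      plant_rate_pos = 1, gc_context_pos = 72,
                      background_gc = 35, seed = 46)$promoters
  neg <- synth_cohort(10, 0, pwm = pwm, promoter_len = 600,
                      plant_rate_pos = 1, gc_context_pos = 45,
                      background_gc = 35, seed = 47)$promoters
  neg$gene <- sub("POS", "NEG", neg$gene)
  curves <- compare_gc_settings(pos, neg, pwm,
                                gc_thresholds = c(NA, 60),
                                n_bootstrap = 5, seed = 48)
  aucs <- glance(curves)
  expect_gt(aucs$auc[aucs$gc_setting == "gc60"],
            aucs$auc[aucs$gc_setting == "pwm_only"])
})

test_that("a zero GC threshold reproduces the PWM-only curve", {
  ch <- make_separable_cohort(8, 16, seed = 49)
  curves <- compare_gc_settings(ch$pos, ch$neg, ch$pwm,
                                gc_thresholds = c(NA, 0),
                                n_bootstrap = 4, seed = 50)
  expect_identical(curves$pwm_only$points, curves$gc0$points)
  expect_identical(curves$pwm_only$auc, curves$gc0$auc)
})

test_that("roc tidiers and autoplot expose points and AUC", {
  ch <- make_separable_cohort(5, 10, seed = 51)
  roc <- build_roc(ch$pos, ch$neg, ch$pwm, n_bootstrap = 2, seed = 1)
  td <- tidy(roc)
  expect_named(td, c("threshold", "fpr", "tpr"))
  expect_identical(nrow(td), 20L)
  gl <- glance(roc)
  expect_equal(gl$auc, roc$auc)
  expect_s3_class(autoplot(roc), "ggplot")

  curves <- compare_gc_settings(ch$pos, ch$neg, ch$pwm,
                                gc_thresholds = c(NA, 60),
                                n_bootstrap = 2, seed = 1)
  expect_identical(sort(unique(tidy(curves)$gc_setting)),
                   c("gc60", "pwm_only"))
  expect_s3_class(autoplot(curves), "ggplot")
})
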