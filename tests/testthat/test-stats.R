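test_that("tissue_contingency tabulates bound x expressed with strict cutoff", {
  expr <- c(g1 = 5, g2 = 0, g3 = 1, g4 = 0)
  tab <- tissue_contingency(c("g1", "g2"), paste0("g", 1:4), expr)
  expect_identical(c(tab$a, tab$b, tab$c, tab$d), c(1L, 1L, 1L, 1L))
  expect_identical(tab$n_dropped, 0L)

  # all expressed -> b = d = 0
  all_on <- tissue_contingency(c("g1", "g2"), paste0("g", 1:4),
                               c(g1 = 1, g2 = 2, g3 = 3, g4 = 4))
  expect_identical(c(all_on$b, all_on$d), c(0L, 0L))

  # exactly at the cutoff counts as not expressed
  at_cut <- tissue_contingency("g1", c("g1", "g2"), c(g1 = 0, g2 = 0.1))
  expect_identical(c(at_cut$a, at_cut$b), c(0L, 1L))

  # missing genes dropped with count; cell sum equals genes with data
  miss <- tissue_contingency(c("g1", "g2"), paste0("g", 1:4),
                             c(g1 = 1, g3 = 0))
  expect_identical(miss$n_dropped, 2L)
  expect_identical(miss$a + miss$b + miss$c + miss$d, 2L)

  expect_error(tissue_contingency("g1", "g1", c(other = 1)),
               class = "matrixgc_validation_error")
  expect_error(tissue_contingency("gX", "g1", c(g1 = 1)),
               class = "matrixgc_validation_error")
})

test_that("fisher_exact: symmetric and degenerate tables", {
  res <- fisher_exact(1, 1, 1, 1)
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p_value, 1)

  # a zero row is a degenerate margin
  expect_equal(fisher_exact(0, 0, 3, 5)$p_value, 1)
  expect_identical(fisher_exact(0, 0, 3, 5)$odds_ratio, NaN)
  expect_identical(fisher_exact(4, 0, 0, 4)$odds_ratio, Inf)
  expect_equal(fisher_exact(0, 0, 0, 0)$p_value, 1)
  expect_error(fisher_exact(-1, 1, 1, 1), class = "matrixgc_validation_error")
})

test_that("fisher_exact matches exhaustive hypergeometric enumeration", {
  expect_equal(fisher_exact(8, 2, 1, 5)$p_value, oracle_fisher_p(8, 2, 1, 5),
               tolerance = 1e-12)
  set.seed(61)
  for (i in 1:60) {
    cells <- as.integer(stats::rmultinom(1, sample(2:30, 1), rep(0.25, 4)))
    got <- fisher_exact(cells[1], cells[2], cells[3], cells[4])$p_value
    want <- oracle_fisher_p(cells[1], cells[2], cells[3], cells[4])
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("tissue_expression_test produces one tidy row per tissue", {
  expr <- synth_expression(60, c("brain", "blood", "skin"),
                           frac_expressed = c(0.8, 0.5, 0.3), seed = 62)
  bound <- expr$gene[1:20]
  res <- tissue_expression_test(expr, bound)
  expect_identical(res$tissue, c("brain", "blood", "skin"))
  expect_true(all(res$a + res$b == 20))
  expect_true(all(res$a + res$b + res$c + res$d == 60))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
})

test_that("monte_carlo_deg: whole-universe candidates tie every permutation", {
  de <- synth_de_table(300, 30, effect = 0.9, seed = 63)
  res <- monte_carlo_deg(de$de_table, de$de_table$gene, n_perm = 50, seed = 64)
  global_pct <- 100 * mean(de$de_table$pvalue <= 0.05)
  expect_equal(res$observed_pct, global_pct)
  expect_true(all(res$null_pcts == global_pct))
  expect_equal(res$empirical_p, 1)
})

test_that("monte_carlo_deg floors at the add-one minimum and is deterministic", {
  # candidates all significant, planted in a mostly-uniform universe
  set.seed(65)
  genes <- sprintf("G%04d", 1:5000)
  p <- runif(5000)
  p[1:40] <- 0.001
  de <- tibble::tibble(gene = genes, pvalue = p)
  res <- monte_carlo_deg(de, genes[1:40], n_perm = 1000, seed = 66)
  expect_equal(res$observed_pct, 100)
  expect_equal(res$empirical_p, 1 / 1001)

  res2 <- monte_carlo_deg(de, genes[1:40], n_perm = 1000, seed = 66)
  expect_identical(res$null_pcts, res2$null_pcts)
  expect_gte(res$empirical_p, 1 / (res$n_perm + 1))
})

test_that("monte_carlo_deg drops candidates missing from the DE table", {
  de <- synth_de_table(100, 10, effect = 1, seed = 67)
  cands <- c(de$enriched[1:5], "NOT_A_GENE")
  res <- monte_carlo_deg(de$de_table, cands, n_perm = 20, seed = 68)
  expect_identical(res$n_candidates_used, 5L)
  expect_identical(res$n_candidates_dropped, 1L)
  expect_error(monte_carlo_deg(de$de_table, "NOPE", n_perm = 20),
               class = "matrixgc_validation_error")
  expect_error(monte_carlo_deg(de$de_table, de$enriched, n_perm = 0),
               class = "matrixgc_validation_error")
})

test_that("permutation draws are without replacement", {
  # with candidates = nearly the whole universe, any within-draw duplicate
  # would shift the null percentages off the exact k/m grid
  de <- tibble::tibble(gene = paste0("g", 1:20),
                       pvalue = rep(c(0.01, 0.9), 10))
  res <- monte_carlo_deg(de, paste0("g", 1:19), n_perm = 200, seed = 69)
  grid <- 100 * (0:19) / 19
  off_grid <- vapply(res$null_pcts,
                     function(x) min(abs(x - grid)), numeric(1))
  expect_true(all(off_grid < 1e-9))
  # 19 of 20 genes drawn without replacement always catch >= 9 of the 10
  # significant ones
  expect_true(all(res$null_pcts >= 100 * 9 / 19 - 1e-9))
})

test_that("exclude_control_terms removes exactly the control-significant overlap", {
  res <- exclude_control_terms(c("A", "B", "C"), list("B", "D"))
  expect_identical(res$kept_terms, c("A", "C"))
  expect_identical(res$excluded_terms, "B")

  expect_identical(exclude_control_terms(c("A", "B"), list())$kept_terms,
                   c("A", "B"))
  all_gone <- exclude_control_terms(c("A", "B"), list(c("A", "B", "C")))
  expect_length(all_gone$kept_terms, 0)

  td <- tidy(res)
  expect_identical(td$status[td$term == "B"], "excluded")
  expect_setequal(td$term, c("A", "B", "C"))
})
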