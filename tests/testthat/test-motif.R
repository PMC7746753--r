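test_that("read_pfm parses labelled tables and JASPAR blocks identically", {
  tf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("A 3 0 1", "C 1 4 1", "G 0 0 1", "T 0 0 1"), tf)
  m1 <- read_pfm(tf)
  expect_identical(dim(m1), c(4L, 3L))
  expect_equal(unname(m1["A", 1]), 3)

  writeLines(c(">MA0000.1 toy", "A [ 3 0 1 ]", "C [ 1 4 1 ]",
               "G [ 0 0 1 ]", "T [ 0 0 1 ]"), tf)
  expect_identical(read_pfm(tf), m1)

  writeLines(c("A 1 1", "C 1 1", "G 1 1"), tf)
  expect_error(read_pfm(tf), class = "matrixgc_parse_error")
})

test_that("build_pwm validates inputs and rejects zero-sum columns", {
  pfm <- rbind(A = c(1, 0), C = c(1, 0), G = c(1, 0), T = c(1, 0))
  expect_error(build_pwm(pfm), "zero total",
               class = "matrixgc_validation_error")
  good <- matrix(1, 4, 2, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_error(build_pwm(good, pseudocount = 0),
               class = "matrixgc_validation_error")
  expect_error(build_pwm(good, background = c(0.5, 0.5, 0, 0)),
               class = "matrixgc_validation_error")
})

test_that("log-odds weights match the defining formula and preserve structure", {
  # consensus base keeps the column maximum under the monotone transform
  single <- matrix(c(4, 0, 0, 0), 4, 1,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- build_pwm(single)
  expect_identical(which.max(pwm$weights[, 1]), c(A = 1L))

  # a flat column gives four equal weights
  flat <- build_pwm(matrix(1, 4, 1, dimnames = list(c("A", "C", "G", "T"), NULL)))
  expect_equal(max(flat$weights) - min(flat$weights), 0, tolerance = 1e-12)

  # scalar recomputation of a (3,1,0,0) column at pseudocount 0.01
  counts <- matrix(c(3, 1, 0, 0), 4, 1,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- build_pwm(counts, pseudocount = 0.01)
  expect_equal(pwm$weights, oracle_pwm_weights(counts, 0.01),
               tolerance = 1e-12)
  expect_equal(pwm$smin, sum(apply(oracle_pwm_weights(counts, 0.01), 2, min)),
               tolerance = 1e-12)
  expect_lte(pwm$smin, pwm$smax)
})

test_that("percent score hits 100 at consensus, 0 at anti-consensus, oracle in between", {
  set.seed(21)
  for (rep in 1:5) {
    pfm <- random_pfm(15)
    pwm <- build_pwm(pfm)
    cons <- paste(oracle_bases[apply(pwm$weights, 2, which.max)], collapse = "")
    anti <- paste(oracle_bases[apply(pwm$weights, 2, which.min)], collapse = "")
    expect_equal(percent_score(pwm, cons), 100, tolerance = 1e-12)
    expect_equal(percent_score(pwm, anti), 0, tolerance = 1e-12)
    kmer <- random_seq(15)
    expect_equal(percent_score(pwm, kmer),
                 oracle_percent(pwm$weights, kmer), tolerance = 1e-12)
  }
  pwm <- build_pwm(random_pfm(15))
  expect_error(percent_score(pwm, "ACGTNACGTACGTAC"),
               class = "matrixgc_scoring_error")
  expect_error(percent_score(pwm, "ACGT"), class = "matrixgc_scoring_error")
})

test_that("scanning finds a planted consensus and skips N windows", {
  pwm <- build_pwm(example_pfm())
  cons <- pwm_consensus(pwm)
  seq <- paste0("ATATATA", cons, paste(rep("TA", 10), collapse = ""))
  hits <- scan_sequence(pwm, seq, threshold = 65)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$position, 7L)
  expect_equal(hits$percent_score, 100, tolerance = 1e-12)
  expect_identical(hits$matched_seq, cons)

  all_n <- paste(rep("N", 60), collapse = "")
  empty <- scan_sequence(pwm, all_n, threshold = 0)
  expect_identical(nrow(empty), 0L)
  expect_identical(attr(empty, "n_skipped"), 46L)

  # shorter than the motif: empty, not an error
  expect_identical(nrow(scan_sequence(pwm, "ACGT")), 0L)
})

test_that("scanning equals exhaustive window enumeration on random input", {
  set.seed(23)
  pfm <- random_pfm(8)
  pwm <- build_pwm(pfm)
  seq <- random_seq(60, n_prob = 0.05)
  got <- scan_sequence(pwm, seq, threshold = 40)
  want <- oracle_scan(pwm$weights, seq, 40)
  expect_identical(got$position, as.integer(want$position))
  expect_equal(got$percent_score, want$percent_score, tolerance = 1e-12)
  expect_identical(got$matched_seq, want$matched_seq)
})

test_that("percent scores are invariant to per-column constant shifts", {
  set.seed(24)
  pwm <- build_pwm(random_pfm(10))
  shifted <- pwm
  shifts <- runif(10, -3, 3)
  shifted$weights <- sweep(pwm$weights, 2, shifts, "+")
  shifted$smin <- sum(apply(shifted$weights, 2, min))
  shifted$smax <- sum(apply(shifted$weights, 2, max))
  for (i in 1:10) {
    kmer <- random_seq(10)
    expect_equal(percent_score(pwm, kmer), percent_score(shifted, kmer),
                 tolerance = 1e-9)
  }
})

test_that("threshold filtering is exhaustive at 0 and monotone above", {
  set.seed(25)
  pwm <- build_pwm(random_pfm(15))
  seq <- random_seq(200)
  all_hits <- scan_sequence(pwm, seq, threshold = 0)
  expect_identical(nrow(all_hits), 200L - 15L + 1L)
  prev <- nrow(all_hits)
  for (t in c(20, 40, 60, 80, 100)) {
    n_t <- nrow(scan_sequence(pwm, seq, threshold = t))
    expect_lte(n_t, prev)
    prev <- n_t
  }
})

test_that("both-strand scans of a sequence and its reverse complement mirror", {
  set.seed(26)
  pwm <- build_pwm(random_pfm(9))
  seq <- random_seq(80)
  rc <- oracle_revcomp(seq)
  fwd <- scan_sequence(pwm, seq, threshold = 30, both_strands = TRUE)
  rev <- scan_sequence(pwm, rc, threshold = 30, both_strands = TRUE)
  # a hit at position p, strand s maps to position L - W - p on the other
  # strand of the reverse complement
  remap <- function(h, L, W) {
    d <- data.frame(
      position = as.integer(L - W - h$position),
      strand = ifelse(h$strand == "+", "-", "+"),
      percent_score = h$percent_score,
      matched_seq = h$matched_seq
    )
    d[order(d$position, d$strand), ]
  }
  want <- remap(fwd, 80, 9)
  expect_identical(as.integer(rev$position), want$position)
  expect_identical(rev$strand, want$strand)
  expect_equal(rev$percent_score, want$percent_score, tolerance = 1e-9)
  expect_identical(rev$matched_seq, want$matched_seq)
})
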