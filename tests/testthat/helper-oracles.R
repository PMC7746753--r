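# Independent oracles, written against the definitions rather than the
# package implementation: plain per-window loops, exhaustive hypergeometric
# enumeration, and a hand-coded reverse complement.

oracle_bases <- c("A", "C", "G", "T")

# Reverse complement by lookup table and string reversal.
oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(seq), "")[[1]]]), collapse = "")
}

# Log-odds weights recomputed scalar-by-scalar from the defining formula.
oracle_pwm_weights <- function(counts, pseudocount = 0.01,
                               background = rep(0.25, 4)) {
  W <- ncol(counts)
  w <- matrix(NA_real_, 4, W, dimnames = list(oracle_bases, NULL))
  for (j in seq_len(W)) {
    tot <- sum(counts[, j])
    for (b in 1:4) {
      w[b, j] <- log2(
        (counts[b, j] + pseudocount * background[b]) /
          (tot + pseudocount) / background[b]
      )
    }
  }
  w
}

# Percent score of one k-mer by explicit per-column summation.
oracle_percent <- function(weights, kmer) {
  chars <- strsplit(kmer, "")[[1]]
  s <- 0
  for (j in seq_along(chars)) s <- s + unname(weights[chars[j], j])
  smin <- sum(apply(weights, 2, min))
  smax <- sum(apply(weights, 2, max))
  if (smax == smin) return(100)
  100 * (s - smin) / (smax - smin)
}

# Exhaustive forward-strand window enumeration; windows with non-ACGT skipped.
# Returns a data frame (position 0-based, percent_score, matched_seq).
oracle_scan <- function(weights, seq, threshold) {
  W <- ncol(weights)
  L <- nchar(seq)
  out <- list()
  if (L >= W) {
    for (pos in 0:(L - W)) {
      kmer <- substr(seq, pos + 1, pos + W)
      if (grepl("[^ACGT]", kmer)) next
      pct <- oracle_percent(weights, kmer)
      if (pct >= threshold) {
        out[[length(out) + 1]] <- data.frame(
          position = pos, percent_score = pct, matched_seq = kmer,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(position = integer(0), percent_score = numeric(0),
                      matched_seq = character(0)))
  }
  do.call(rbind, out)
}

# GC percent over [start, end) (0-based half-open), N excluded both sides.
oracle_window_gc <- function(seq, start, end) {
  chars <- strsplit(substr(seq, start + 1, end), "")[[1]]
  acgt <- sum(chars %in% oracle_bases)
  if (acgt == 0) return(NA_real_)
  100 * sum(chars %in% c("C", "G")) / acgt
}

# Bound/not-bound call by the full brute-force route: enumerate windows,
# threshold the percent score, compute each hit's flanking-window GC, and
# require at least one hit at or above the GC threshold.
oracle_classify <- function(weights, seq, pwm_threshold, gc_threshold, flank) {
  W <- ncol(weights)
  hits <- oracle_scan(weights, seq, pwm_threshold)
  if (nrow(hits) == 0) return(FALSE)
  L <- nchar(seq)
  for (pos in hits$position) {
    gc <- oracle_window_gc(seq, max(0, pos - flank), min(L, pos + W + flank))
    if (!is.na(gc) && gc >= gc_threshold) return(TRUE)
  }
  FALSE
}

# Two-sided Fisher p by exhaustive enumeration of all tables with the
# observed margins: sum the hypergeometric probabilities of tables at most as
# probable as the observed one (standard relative tolerance for ties).
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  if (r1 + r2 == 0) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(ks, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Random valid PFM (positive column sums) of width W; deterministic given the
# caller's RNG state.
random_pfm <- function(W = 15, max_count = 20) {
  repeat {
    m <- matrix(sample(0:max_count, 4 * W, replace = TRUE), nrow = 4,
                dimnames = list(oracle_bases, NULL))
    if (all(colSums(m) > 0)) return(m)
  }
}

# Random DNA string, optionally with Ns.
random_seq <- function(len, n_prob = 0) {
  alpha <- c(oracle_bases, if (n_prob > 0) "N")
  prob <- c(rep((1 - n_prob) / 4, 4), if (n_prob > 0) n_prob)
  paste(sample(alpha, len, replace = TRUE, prob = prob), collapse = "")
}
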