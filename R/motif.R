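# Position frequency / weight matrices and percent-scored sequence scanning.
#
# The PWM is a log2-odds transform of the PFM against an explicit background
# with a small additive pseudocount. A window's raw score S (sum of one
# weight per column) is reported on a 0-100 "percent" scale by min-max
# normalisation against the matrix's achievable score bounds:
#   percent = 100 * (S - smin) / (smax - smin).

BASES <- c("A", "C", "G", "T")

#' Read a position frequency matrix
#'
#' Accepts two tabular layouts: a 4-row whitespace/tab-separated table whose
#' rows start with the base labels A, C, G, T, and JASPAR-style blocks
#' (`A [ 4 19 0 ... ]`). Lines starting with `>` or `#` are ignored.
#'
#' @param path Path to the matrix file.
#' @return A 4 x W numeric matrix with rownames A, C, G, T.
#' @export
read_pfm <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("PFM file not found: ", path), class = "matrixgc_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, ">") & !startsWith(lines, "#")]
  base_lines <- lines[toupper(substr(lines, 1, 1)) %in% BASES]
  if (length(base_lines) != 4) {
    abort(
      "PFM file must contain exactly one row for each of A, C, G, T",
      class = "matrixgc_parse_error"
    )
  }
  rows <- lapply(base_lines, function(l) {
    base <- toupper(substr(l, 1, 1))
    nums <- gsub("[][]", " ", substr(l, 2, nchar(l)))
    vals <- suppressWarnings(as.numeric(strsplit(trimws(nums), "\\s+")[[1]]))
    if (any(is.na(vals))) {
      abort(
        paste0("Non-numeric count in PFM row ", base),
        class = "matrixgc_parse_error"
      )
    }
    stats::setNames(list(vals), base)
  })
  rows <- unlist(rows, recursive = FALSE)
  widths <- lengths(rows)
  if (length(unique(widths)) != 1) {
    abort("PFM rows have unequal widths", class = "matrixgc_parse_error")
  }
  counts <- do.call(rbind, rows[BASES])
  validate_pfm(counts)
}

#' Bundled synthetic example PFM
#'
#' A GC-rich 4 x 15 count matrix constructed for examples and tests (it is
#' synthetic, not derived from any experimental dataset).
#'
#' @return A 4 x 15 count matrix, as from [read_pfm()].
#' @export
example_pfm <- function() {
  read_pfm(system.file("extdata", "pfm_example_synthetic.txt",
                       package = "matrixgc", mustWork = TRUE))
}

validate_pfm <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) {
    abort("PFM must have 4 rows (A, C, G, T)", class = "matrixgc_validation_error")
  }
  rownames(counts) <- BASES
  if (any(counts < 0) || any(!is.finite(counts))) {
    abort("PFM entries must be finite and >= 0", class = "matrixgc_validation_error")
  }
  if (any(colSums(counts) <= 0)) {
    abort(
      paste0("PFM column(s) with zero total count: ",
             paste(which(colSums(counts) <= 0), collapse = ", ")),
      class = "matrixgc_validation_error"
    )
  }
  counts
}

#' Build a position weight matrix from a position frequency matrix
#'
#' Converts per-position base counts into log2-odds weights against a
#' background model, with an additive pseudocount shared across the column in
#' proportion to the background:
#' `w[b, j] = log2( (n[b, j] + pc * bg[b]) / (sum_b n[b, j] + pc) / bg[b] )`.
#'
#' @param pfm 4 x W numeric count matrix (rows A, C, G, T).
#' @param pseudocount Positive pseudocount total per column (default 0.01).
#' @param background Length-4 base probability vector summing to 1, all
#'   components positive (default uniform).
#' @return An object of class `matrixgc_pwm`: a list with `weights`
#'   (4 x W log2-odds matrix), `smin`/`smax` (sum of column minima/maxima,
#'   the achievable raw-score bounds), `width`, `pseudocount`, `background`.
#' @export
build_pwm <- function(pfm, pseudocount = 0.01, background = rep(0.25, 4)) {
  counts <- validate_pfm(pfm)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0) {
    abort("`pseudocount` must be a single positive number",
          class = "matrixgc_validation_error")
  }
  if (length(background) != 4 || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-8) {
    abort("`background` must be 4 positive probabilities summing to 1",
          class = "matrixgc_validation_error")
  }
  background <- as.numeric(background)
  col_tot <- colSums(counts)
  prob <- sweep(counts + pseudocount * background, 2, col_tot + pseudocount, "/")
  weights <- log2(prob / background)
  dimnames(weights) <- list(BASES, NULL)
  structure(
    list(
      weights = weights,
      smin = sum(apply(weights, 2, min)),
      smax = sum(apply(weights, 2, max)),
      width = ncol(weights),
      pseudocount = pseudocount,
      background = background
    ),
    class = "matrixgc_pwm"
  )
}

#' @export
print.matrixgc_pwm <- function(x, ...) {
  cat("<matrixgc_pwm> width", x$width,
      sprintf("| raw score range [%.4f, %.4f]\n", x$smin, x$smax))
  cat("consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM (column-wise argmax)
#'
#' @param pwm A `matrixgc_pwm`.
#' @return Character scalar of length `pwm$width`. Ties resolve to the first
#'   base in A, C, G, T order.
#' @export
pwm_consensus <- function(pwm) {
  paste(BASES[apply(pwm$weights, 2, which.max)], collapse = "")
}

#' Percent score of a k-mer against a PWM
#'
#' The raw score `S` is the sum over columns of the weight of the observed
#' base; the percent score rescales it to `[0, 100]` between the minimal and
#' maximal achievable raw scores. A degenerate matrix with `smax == smin`
#' scores 100.
#'
#' @param pwm A `matrixgc_pwm`.
#' @param kmer Character vector of DNA strings, each of length `pwm$width`,
#'   over A/C/G/T only.
#' @return Numeric vector of percent scores in `[0, 100]`.
#' @export
percent_score <- function(pwm, kmer) {
  W <- pwm$width
  if (any(nchar(kmer) != W)) {
    abort(paste0("k-mer length must equal motif width ", W),
          class = "matrixgc_scoring_error")
  }
  vapply(kmer, function(k) {
    idx <- match(strsplit(k, "")[[1]], BASES)
    if (anyNA(idx)) {
      abort(paste0("k-mer '", k, "' contains non-ACGT characters"),
            class = "matrixgc_scoring_error")
    }
    s <- sum(pwm$weights[cbind(idx, seq_len(W))])
    raw_to_percent(s, pwm$smin, pwm$smax)
  }, numeric(1), USE.NAMES = FALSE)
}

raw_to_percent <- function(s, smin, smax) {
  if (smax == smin) return(rep(100, length(s)))
  100 * (s - smin) / (smax - smin)
}

# Vectorised raw scores of all windows of `idx` (integer base codes, NA = N)
# against a 4 x W weight matrix. Returns list(score, valid) of length
# length(idx) - W + 1; invalid windows contain an NA base.
window_scores <- function(idx, weights) {
  W <- ncol(weights)
  L <- length(idx)
  n_win <- L - W + 1L
  if (n_win < 1L) {
    return(list(score = numeric(0), valid = logical(0)))
  }
  na_cum <- c(0L, cumsum(is.na(idx)))
  valid <- (na_cum[seq_len(n_win) + W] - na_cum[seq_len(n_win)]) == 0L
  idx0 <- idx
  idx0[is.na(idx0)] <- 1L
  score <- numeric(n_win)
  for (j in seq_len(W)) {
    score <- score + weights[cbind(idx0[j:(j + n_win - 1L)], j)]
  }
  list(score = score, valid = valid)
}

#' Scan a sequence for PWM matches above a percent-score threshold
#'
#' Every window of width `pwm$width` consisting solely of A/C/G/T is scored;
#' windows containing N (or any other symbol) are skipped. Overlapping
#' matches are all reported. With `both_strands = TRUE` the reverse
#' complement of each window is also scored and reported with strand `"-"`
#' (position still refers to the forward-strand window start).
#'
#' @param pwm A `matrixgc_pwm`.
#' @param seq A single DNA string.
#' @param threshold Minimum percent score in `[0, 100]` (default 65).
#' @param both_strands Also score reverse-complement windows (default FALSE).
#' @param seq_id Optional sequence id copied into the output.
#' @param verbose Emit a message with the number of skipped windows.
#' @return A tibble sorted by `position` then `strand` with columns `seq_id`,
#'   `position` (0-based window start), `strand`, `percent_score`,
#'   `matched_seq` (the W-mer as read on the matching strand). A sequence
#'   shorter than the motif yields zero rows. The number of windows skipped
#'   for non-ACGT content is attached as attribute `n_skipped`.
#' @export
scan_sequence <- function(pwm, seq, threshold = 65, both_strands = FALSE,
                          seq_id = NA_character_, verbose = FALSE) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 100) {
    abort("`threshold` must be in [0, 100]", class = "matrixgc_validation_error")
  }
  stopifnot(length(seq) == 1)
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  idx <- match(chars, BASES)
  W <- pwm$width
  empty <- tibble(
    seq_id = character(0), position = integer(0), strand = character(0),
    percent_score = numeric(0), matched_seq = character(0)
  )
  fwd <- window_scores(idx, pwm$weights)
  n_win <- length(fwd$score)
  if (n_win == 0L) {
    attr(empty, "n_skipped") <- 0L
    return(empty)
  }
  pct_fwd <- raw_to_percent(fwd$score, pwm$smin, pwm$smax)
  hits <- list()
  keep_f <- which(fwd$valid & pct_fwd >= threshold)
  if (length(keep_f) > 0) {
    hits$fwd <- tibble(
      seq_id = seq_id,
      position = keep_f - 1L,
      strand = "+",
      percent_score = pct_fwd[keep_f],
      matched_seq = substring(seq, keep_f, keep_f + W - 1L)
    )
  }
  if (both_strands) {
    # reverse-complement the matrix instead of the sequence: swap A<->T,
    # C<->G rows and reverse the columns; smin/smax are unchanged.
    rc_weights <- pwm$weights[4:1, rev(seq_len(W)), drop = FALSE]
    rev_sc <- window_scores(idx, rc_weights)
    pct_rev <- raw_to_percent(rev_sc$score, pwm$smin, pwm$smax)
    keep_r <- which(rev_sc$valid & pct_rev >= threshold)
    if (length(keep_r) > 0) {
      hits$rev <- tibble(
        seq_id = seq_id,
        position = keep_r - 1L,
        strand = "-",
        percent_score = pct_rev[keep_r],
        matched_seq = reverse_complement(
          substring(seq, keep_r, keep_r + W - 1L)
        )
      )
    }
  }
  out <- if (length(hits) > 0) {
    arrange(bind_rows(hits), .data$position, .data$strand)
  } else {
    empty
  }
  n_skipped <- sum(!fwd$valid)
  if (verbose && n_skipped > 0) {
    inform(paste0(n_skipped, " window(s) skipped for non-ACGT content"))
  }
  attr(out, "n_skipped") <- n_skipped
  out
}
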