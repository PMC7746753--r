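# The combined Matrix-GC filter: a gene's promoter is called bound when at
# least one PWM match at or above the percent-score threshold sits in a
# flanking-GC context at or above the GC threshold. The GC window spans the
# match plus `flank` bp on each side (215 bp for a 15 bp motif with 100 bp
# flanks), truncated at the promoter boundaries.

#' GC content of a DNA sequence, in percent
#'
#' N (and any other non-ACGT) characters are excluded from both numerator and
#' denominator.
#'
#' @param seq Character vector of DNA strings.
#' @return Numeric vector: `100 * (#G + #C) / (#A + #C + #G + #T)` per string.
#' @export
gc_content <- function(seq) {
  vapply(toupper(seq), function(s) {
    chars <- strsplit(s, "")[[1]]
    acgt <- sum(chars %in% BASES)
    if (acgt == 0) {
      abort("Sequence has no A/C/G/T characters: GC content undefined",
            class = "matrixgc_undefined_content_error")
    }
    100 * sum(chars %in% c("G", "C")) / acgt
  }, numeric(1), USE.NAMES = FALSE)
}

#' Bounds of the flanking-GC window around a motif match
#'
#' The window covers the match plus `flank` bp on each side, clipped to the
#' sequence: `[max(0, pos - flank), min(seq_len, pos + width + flank))`.
#'
#' @param seq_len Length of the scanned sequence.
#' @param match_position 0-based window start of the match.
#' @param width Motif width (default 15).
#' @param flank Flank size in bp on each side (default 100).
#' @return A list with `start`, `end` (0-based half-open) and `clipped`.
#' @export
gc_window <- function(seq_len, match_position, width = 15L, flank = 100L) {
  if (match_position < 0 || match_position > seq_len - width) {
    abort(
      paste0("match_position ", match_position, " out of range [0, ",
             seq_len - width, "]"),
      class = "matrixgc_validation_error"
    )
  }
  start <- max(0L, as.integer(match_position - flank))
  end <- min(as.integer(seq_len), as.integer(match_position + width + flank))
  list(
    start = start,
    end = end,
    clipped = (end - start) < (width + 2L * flank)
  )
}

#' Matrix-GC configuration
#'
#' Bundles the four tunable parameters of the classifier: the PWM
#' percent-score threshold, the flanking GC-content threshold, the promoter
#' length, and the flank size of the GC window.
#'
#' @param pwm_threshold Minimum PWM percent score, in `[0, 100]` (default 65).
#' @param gc_threshold Minimum GC percent of the flanking window, in
#'   `[0, 100]` (default 60). Use 0 to disable GC filtering.
#' @param upstream Promoter length in bp (default 1000).
#' @param flank GC-window flank in bp on each side of a match (default 100).
#' @return A list of class `matrixgc_config`.
#' @export
matrixgc_config <- function(pwm_threshold = 65, gc_threshold = 60,
                            upstream = 1000L, flank = 100L) {
  if (pwm_threshold < 0 || pwm_threshold > 100 ||
      gc_threshold < 0 || gc_threshold > 100) {
    abort("Thresholds must lie in [0, 100]", class = "matrixgc_validation_error")
  }
  if (upstream <= 0 || flank <= 0) {
    abort("`upstream` and `flank` must be positive",
          class = "matrixgc_validation_error")
  }
  structure(
    list(
      pwm_threshold = pwm_threshold,
      gc_threshold = gc_threshold,
      upstream = as.integer(upstream),
      flank = as.integer(flank)
    ),
    class = "matrixgc_config"
  )
}

# Matches of `pwm` in `seq` at `threshold`, annotated with the GC percent of
# each match's flanking window (computed from cumulative base counts, N
# excluded from numerator and denominator). Windows with undefined GC (all N)
# get NA and never pass the GC filter.
matches_with_gc <- function(pwm, seq, threshold, flank) {
  m <- scan_sequence(pwm, seq, threshold = threshold)
  if (nrow(m) == 0) {
    m$gc_percent <- numeric(0)
    return(m)
  }
  chars <- strsplit(toupper(seq), "")[[1]]
  cum_gc <- c(0, cumsum(chars %in% c("G", "C")))
  cum_acgt <- c(0, cumsum(chars %in% BASES))
  L <- length(chars)
  m$gc_percent <- vapply(m$position, function(pos) {
    w <- gc_window(L, pos, width = pwm$width, flank = flank)
    acgt <- cum_acgt[w$end + 1L] - cum_acgt[w$start + 1L]
    gc <- cum_gc[w$end + 1L] - cum_gc[w$start + 1L]
    if (acgt == 0) NA_real_ else 100 * gc / acgt
  }, numeric(1))
  m
}

#' Classify one promoter as bound / not bound
#'
#' Scans the promoter at `config$pwm_threshold`; each match's flanking window
#' GC percent is computed, and the gene is bound if at least one match has
#' `gc_percent >= config$gc_threshold`. The `best_*` fields report the
#' passing match with the highest percent score.
#'
#' @param promoter A one-row data frame (or list) with `gene` and `seq`, as
#'   produced by [extract_promoters()] or [synth_cohort()].
#' @param pwm A `matrixgc_pwm`.
#' @param config A [matrixgc_config()].
#' @return One-row tibble: `gene`, `bound`, `n_passing_matches`,
#'   `best_percent_score`, `best_gc`.
#' @export
classify_gene <- function(promoter, pwm, config = matrixgc_config()) {
  m <- matches_with_gc(pwm, promoter$seq, config$pwm_threshold, config$flank)
  passing <- m[!is.na(m$gc_percent) & m$gc_percent >= config$gc_threshold, ]
  n_pass <- nrow(passing)
  best <- if (n_pass > 0) passing[which.max(passing$percent_score), ] else NULL
  tibble(
    gene = promoter$gene,
    bound = n_pass >= 1,
    n_passing_matches = n_pass,
    best_percent_score = if (n_pass > 0) best$percent_score else NA_real_,
    best_gc = if (n_pass > 0) best$gc_percent else NA_real_
  )
}

#' Classify a set of promoters with the Matrix-GC filter
#'
#' @param promoters Tibble with columns `gene` (unique) and `seq`.
#' @param pwm A `matrixgc_pwm`.
#' @param config A [matrixgc_config()].
#' @return A tibble of class `matrixgc_calls` with one row per gene (columns
#'   as in [classify_gene()]); [glance()] on it reports `n_genes`, `n_bound`
#'   and `bound_pct` (percentage bound, rounded to 2 decimals).
#' @export
classify_gene_set <- function(promoters, pwm, config = matrixgc_config()) {
  if (nrow(promoters) == 0) {
    abort("`promoters` is empty", class = "matrixgc_validation_error")
  }
  if (anyDuplicated(promoters$gene)) {
    abort("Gene names must be unique", class = "matrixgc_validation_error")
  }
  calls <- purrr::map_dfr(
    seq_len(nrow(promoters)),
    function(i) classify_gene(promoters[i, ], pwm, config)
  )
  structure(
    calls,
    config = config,
    class = c("matrixgc_calls", class(calls))
  )
}

#' @rdname classify_gene_set
#' @param x A `matrixgc_calls` object.
#' @param ... Unused.
#' @export
glance.matrixgc_calls <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_bound = sum(x$bound),
    bound_pct = round(100 * sum(x$bound) / nrow(x), 2)
  )
}

#' @export
tidy.matrixgc_calls <- function(x, ...) {
  as_tibble(unclass(x)[c("gene", "bound", "n_passing_matches",
                         "best_percent_score", "best_gc")])
}

# Best percent score among GC-passing matches of a promoter, scanning with no
# score threshold; -Inf when no window passes the GC filter. A gene is bound
# at PWM threshold t iff this value >= t (match sets are nested in t and the
# GC window does not depend on t), which lets ROC construction scan each
# promoter once.
best_passing_score <- function(pwm, seq, gc_threshold, flank) {
  m <- matches_with_gc(pwm, seq, threshold = 0, flank = flank)
  ok <- !is.na(m$gc_percent) & m$gc_percent >= gc_threshold
  if (!any(ok)) return(-Inf)
  max(m$percent_score[ok])
}
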