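# Sequence and gene-table I/O, strand-aware promoter extraction.
#
# Coordinates are 0-based, half-open internally. Gene tables may declare a
# 1-based convention via `coord_base = 1`, in which case the TSS column is
# shifted down by one on read.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased; each record id is the first whitespace-delimited
#' token of its header line.
#'
#' @param path Path to a FASTA file (multi-record, wrapped or unwrapped).
#' @return Named character vector mapping sequence id to an uppercase DNA
#'   string. An empty file yields an empty vector.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 description", "acgtACGT"), tf)
#' read_fasta(tf)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "matrixgc_io_error")
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || all(!nzchar(trimws(first)))) {
    return(stats::setNames(character(0), character(0)))
  }
  if (!startsWith(trimws(first)[1], ">")) {
    abort(
      "Malformed FASTA: sequence data before any '>' header (line 1)",
      class = "matrixgc_parse_error"
    )
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(
    strsplit(names(set), "\\s+"),
    function(x) x[1],
    character(1)
  )
  seqs
}

#' Write a named character vector of sequences to FASTA
#'
#' @param seqs Named character vector (id -> DNA string).
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (length(seqs) > 0 && (is.null(names(seqs)) || any(!nzchar(names(seqs))))) {
    abort("All sequences must be named", class = "matrixgc_validation_error")
  }
  set <- Biostrings::BStringSet(toupper(seqs))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a gene coordinate table
#'
#' Expects a TSV with a header row and columns `name`, `chrom`, `tss`,
#' `strand`. The TSS is the transcription start site on the forward strand.
#'
#' @param path Path to the TSV file.
#' @param coord_base Coordinate convention of the `tss` column: 0 (default,
#'   0-based) or 1 (1-based; values are shifted down by one on read).
#' @return A tibble with columns `name`, `chrom`, `tss` (0-based integer)
#'   and `strand` ("+" or "-"), one row per gene, input order preserved.
#' @export
read_gene_table <- function(path, coord_base = 0) {
  if (!coord_base %in% c(0, 1)) {
    abort("`coord_base` must be 0 or 1", class = "matrixgc_validation_error")
  }
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(
      name = readr::col_character(),
      chrom = readr::col_character(),
      tss = readr::col_double(),
      strand = readr::col_character()
    ),
    progress = FALSE
  )
  required <- c("name", "chrom", "tss", "strand")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    abort(
      paste0("Gene table missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "matrixgc_validation_error"
    )
  }
  tbl$tss <- tbl$tss - coord_base
  validate_gene_table(tbl[required])
}

validate_gene_table <- function(tbl) {
  tbl <- as_tibble(tbl)
  bad_strand <- which(!tbl$strand %in% c("+", "-"))
  if (length(bad_strand) > 0) {
    abort(
      paste0(
        "Unknown strand symbol '", tbl$strand[bad_strand[1]],
        "' at row ", bad_strand[1]
      ),
      class = "matrixgc_validation_error"
    )
  }
  neg <- which(tbl$tss < 0 | is.na(tbl$tss))
  if (length(neg) > 0) {
    abort(
      paste0("Negative or missing tss at row ", neg[1]),
      class = "matrixgc_validation_error"
    )
  }
  if (any(!nzchar(tbl$name) | is.na(tbl$name))) {
    abort("Gene names must be non-empty", class = "matrixgc_validation_error")
  }
  dups <- unique(tbl$name[duplicated(tbl$name)])
  if (length(dups) > 0) {
    abort(
      paste0("Duplicate gene name(s): ", paste(dups, collapse = ", ")),
      class = "matrixgc_validation_error"
    )
  }
  tbl$tss <- as.integer(tbl$tss)
  tbl
}

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Extract the promoter sequence of one gene
#'
#' The promoter is the `upstream` bases immediately 5' of the transcription
#' start site, read toward the TSS. For a "+"-strand gene this is the forward
#' strand over `[tss - upstream, tss)`; for a "-"-strand gene it is the
#' reverse complement of `[tss + 1, tss + 1 + upstream)`, so the returned
#' sequence always reads 5' to 3' relative to the gene. Windows overlapping a
#' chromosome boundary are clipped, and the realized length reported.
#'
#' @param genome Named character vector (chromosome id -> sequence), e.g.
#'   from [read_fasta()].
#' @param gene A one-row data frame (or list) with `name`, `chrom`, `tss`,
#'   `strand`.
#' @param upstream Promoter length in bp (default 1000).
#' @return A one-row tibble with `gene`, `seq`, `length`, `clipped`.
#' @export
extract_promoter <- function(genome, gene, upstream = 1000L) {
  stopifnot(upstream >= 1)
  chrom <- gene$chrom
  tss <- as.integer(gene$tss)
  strand <- gene$strand
  if (!chrom %in% names(genome)) {
    abort(
      paste0("Chromosome '", chrom, "' not present in genome"),
      class = "matrixgc_lookup_error"
    )
  }
  chrom_seq <- genome[[chrom]]
  chrom_len <- nchar(chrom_seq)
  if (tss < 0 || tss >= chrom_len) {
    abort(
      paste0(
        "tss ", tss, " of gene '", gene$name,
        "' is outside chromosome '", chrom, "' (length ", chrom_len, ")"
      ),
      class = "matrixgc_validation_error"
    )
  }
  if (strand == "+") {
    start0 <- max(0L, tss - upstream)
    end0 <- tss # half-open
    seq <- substr(chrom_seq, start0 + 1L, end0)
  } else if (strand == "-") {
    start0 <- tss + 1L
    end0 <- min(chrom_len, tss + 1L + upstream)
    seq <- reverse_complement(substr(chrom_seq, start0 + 1L, end0))
  } else {
    abort(
      paste0("Unknown strand '", strand, "' for gene '", gene$name, "'"),
      class = "matrixgc_validation_error"
    )
  }
  tibble(
    gene = gene$name,
    seq = toupper(seq),
    length = nchar(seq),
    clipped = nchar(seq) < upstream
  )
}

#' Extract promoter sequences for a table of genes
#'
#' Data-frame-first wrapper around [extract_promoter()]: applies it to each
#' row of a gene table.
#'
#' @param genes A gene table as returned by [read_gene_table()].
#' @param genome Named character vector (chromosome id -> sequence).
#' @inheritParams extract_promoter
#' @return A tibble with one row per gene: `gene`, `seq`, `length`, `clipped`.
#' @export
extract_promoters <- function(genes, genome, upstream = 1000L) {
  genes <- validate_gene_table(genes)
  purrr::map_dfr(
    seq_len(nrow(genes)),
    function(i) extract_promoter(genome, genes[i, ], upstream = upstream)
  )
}
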