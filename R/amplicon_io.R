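# Reading/writing clone-read FASTA, sample metadata and variant tables.
# Coordinates are 1-based within each amplicon fragment throughout the
# package, matching the convention of published variant-position tables.

#' Construct a validated amplicon set
#'
#' An amplicon set bundles the clone reads of one gene fragment with the
#' strain consensus they are compared against. The consensus is an explicit
#' input (typically a published reference haplotype), never derived from the
#' reads; use [majority_consensus()] to build one for synthetic data.
#'
#' @param gene one of `"gatB"`, `"coxA"`, `"ftsZ"`, `"wsp"`.
#' @param consensus consensus nucleotide string.
#' @param reads named character vector of clone reads; names are clone ids.
#' @param expected_length expected fragment length in bp. Defaults to the
#'   standard fragment length for the gene (404/444/478) when one exists,
#'   otherwise to the consensus length.
#' @param meta optional data frame of per-clone metadata (see
#'   [read_sample_meta()]); attached as the `"meta"` attribute.
#' @return an object of class `amplicon_set`: a list with elements `gene`,
#'   `consensus`, `reads`, `expected_length`.
#' @export
amplicon_set <- function(gene, consensus, reads, expected_length = NULL,
                         meta = NULL) {
  assert_gene(gene)
  if (is.null(expected_length)) {
    expected_length <- GENE_LENGTHS[[gene]]
    if (is.na(expected_length)) expected_length <- nchar(consensus)
  }
  expected_length <- as.integer(expected_length)
  reads <- setNames(toupper(as.character(reads)), names(reads))
  consensus <- toupper(consensus)
  if (is.null(names(reads)) || anyNA(names(reads)) || any(names(reads) == "")) {
    stop("all reads must be named by clone_id", call. = FALSE)
  }
  if (anyDuplicated(names(reads))) {
    stop("duplicated clone_id: ",
         paste(unique(names(reads)[duplicated(names(reads))]), collapse = ", "),
         call. = FALSE)
  }
  x <- structure(
    list(gene = gene, consensus = consensus, reads = reads,
         expected_length = expected_length),
    class = "amplicon_set"
  )
  if (!is.null(meta)) attr(x, "meta") <- meta
  validate_amplicon_set(x)
}

#' @rdname amplicon_set
#' @param x an `amplicon_set`.
#' @export
validate_amplicon_set <- function(x) {
  stopifnot(inherits(x, "amplicon_set"))
  lens <- nchar(x$reads)
  bad <- names(x$reads)[lens != x$expected_length]
  if (nchar(x$consensus) != x$expected_length) {
    bad <- c("<consensus>", bad)
  }
  if (length(bad)) {
    stop("length mismatch (expected ", x$expected_length, " bp) for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  chars <- unique(unlist(strsplit(c(x$consensus, unname(x$reads)), "",
                                  fixed = TRUE)))
  illegal <- setdiff(chars, IUPAC_CODES)
  if (length(illegal)) {
    stop("illegal characters in sequences: ", paste(illegal, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' @export
print.amplicon_set <- function(x, ...) {
  cat("<amplicon_set> gene:", x$gene, "|", length(x$reads), "clone reads x",
      x$expected_length, "bp\n")
  invisible(x)
}

#' Read cloned amplicon reads from FASTA
#'
#' The first record is taken as the strain consensus unless a separate
#' `consensus_path` is given, in which case all records are clone reads.
#' Reads that fail the fixed-length check are reported by clone id in the
#' error, never silently dropped.
#'
#' @param path FASTA file of clone reads.
#' @param gene locus name (`"gatB"`, `"coxA"`, `"ftsZ"`, `"wsp"`).
#' @param expected_length expected fragment length (bp); defaults per gene.
#' @param consensus_path optional FASTA holding the consensus as its first
#'   record.
#' @param meta optional metadata data frame to attach.
#' @return an [amplicon_set()].
#' @export
read_amplicon_fasta <- function(path, gene, expected_length = NULL,
                                consensus_path = NULL, meta = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  recs <- Biostrings::readDNAStringSet(path)
  if (length(recs) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  seqs <- setNames(as.character(recs), sub("\\s.*$", "", names(recs)))
  if (is.null(consensus_path)) {
    if (length(seqs) < 2L) {
      stop("FASTA must hold a consensus plus at least one clone read: ", path,
           call. = FALSE)
    }
    consensus <- seqs[[1L]]
    reads <- seqs[-1L]
  } else {
    cons <- Biostrings::readDNAStringSet(consensus_path)
    if (length(cons) == 0L) stop("empty consensus FASTA: ", consensus_path,
                                 call. = FALSE)
    consensus <- as.character(cons[[1L]])
    reads <- seqs
  }
  amplicon_set(gene, consensus, reads, expected_length, meta = meta)
}

#' Write an amplicon set to FASTA
#'
#' The consensus is written as the first record (named `consensus`), followed
#' by the clone reads, so the file round-trips through
#' [read_amplicon_fasta()].
#'
#' @param x an `amplicon_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_amplicon_fasta <- function(x, path) {
  stopifnot(inherits(x, "amplicon_set"))
  out <- Biostrings::DNAStringSet(c(consensus = x$consensus, x$reads))
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' Derive a majority-rule consensus from reads
#'
#' Helper for synthetic data; real analyses compare against a published
#' strain consensus instead. Ties are broken in A < C < G < T order.
#'
#' @param reads named character vector of equal-length reads.
#' @return consensus string.
#' @export
majority_consensus <- function(reads) {
  m <- seq_matrix(reads)
  apply(m, 2L, function(col) {
    col <- col[col %in% ACGT]
    if (!length(col)) return("N")
    tab <- table(factor(col, levels = ACGT))
    ACGT[which.max(tab)]
  }) |> paste(collapse = "")
}

#' Read a sample metadata table
#'
#' Tab-delimited with columns `clone_id`, `line`, `host_species`,
#' `generation`, `gene`, `strain_label`. `generation` may be NA (unknown);
#' `strain_label` is `wCer1`, `wCer2` or `unknown`.
#'
#' @param path TSV file.
#' @return data frame with validated columns.
#' @export
read_sample_meta <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("clone_id", "line", "host_species", "generation", "gene",
              "strain_label")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("metadata is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$clone_id)) {
    stop("duplicated clone_id in metadata: ",
         paste(unique(df$clone_id[duplicated(df$clone_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$gene %in% SUPPORTED_GENES)) {
    stop("unsupported gene in metadata: ",
         paste(setdiff(unique(df$gene), SUPPORTED_GENES), collapse = ", "),
         call. = FALSE)
  }
  df$generation <- suppressWarnings(as.integer(df$generation))
  if (any(df$generation < 0, na.rm = TRUE)) {
    stop("generation must be >= 0 or NA", call. = FALSE)
  }
  df
}

#' Write and read variant-call tables
#'
#' Stable tab-delimited format with columns `clone_id`, `line`, `gene`,
#' `position`, `ref`, `alt`, `recurrence_class`; the round trip
#' write -> read is lossless.
#'
#' @param calls data frame of variant calls as produced by [call_snps()]
#'   (the `recurrence_class` column is optional and written as NA when
#'   absent).
#' @param path output/input file.
#' @param allow_empty write a header-only file when `calls` has zero rows.
#' @return `write_variant_table()` returns `path` invisibly;
#'   `read_variant_table()` returns the calls data frame.
#' @export
write_variant_table <- function(calls, path, allow_empty = FALSE) {
  cols <- c("clone_id", "line", "gene", "position", "ref", "alt",
            "recurrence_class")
  if (nrow(calls) == 0L && !allow_empty) {
    stop("refusing to write an empty variant table; set allow_empty = TRUE",
         call. = FALSE)
  }
  if (!"recurrence_class" %in% names(calls)) {
    calls$recurrence_class <- NA_character_
  }
  missing <- setdiff(setdiff(cols, "recurrence_class"), names(calls))
  if (length(missing)) {
    stop("calls are missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  write.table(calls[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(position = "integer"))
  df$recurrence_class <- as.character(df$recurrence_class)
  df
}
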