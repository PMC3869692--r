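# Shared constants and small helpers.

# Default amplicon fragment lengths (bp) per supported locus. wsp amplicons
# vary by primer set, so no fixed default is imposed for it.
GENE_LENGTHS <- c(gatB = 404L, coxA = 444L, ftsZ = 478L, wsp = NA_integer_)

SUPPORTED_GENES <- names(GENE_LENGTHS)

ACGT <- c("A", "C", "G", "T")

# IUPAC nucleotide alphabet; anything outside ACGT is treated as an ambiguity
# code and excluded from variant calling.
IUPAC_CODES <- c(ACGT, "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

STOP_CODONS <- c(TAA = "ochre", TAG = "amber", TGA = "opal")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Fixed-point rounding where .5 always rounds up in magnitude (the convention
#' used for all displayed per-kb frequencies), unlike [round()]'s banker's
#' rounding. Raw values are kept alongside displayed ones throughout the
#' package; this function only affects display columns.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up (away from zero).
#' @export
#' @examples
#' round_half_up(0.145, 2) # 0.15
#' round_half_up(2.675, 2) # 2.68
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# Lightweight logging: levels debug < info < warn. Controlled by
# options(symbiopoly.log_level = "info"); "quiet" silences everything.
sp_log <- function(level = c("info", "debug", "warn"), ...) {
  level <- match.arg(level)
  threshold <- getOption("symbiopoly.log_level", "warn")
  ranks <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  if (ranks[[level]] >= ranks[[threshold]]) {
    message("[symbiopoly ", level, "] ", ...)
  }
  invisible(NULL)
}

# Split sequences into a character matrix (reads x positions); all sequences
# must share one length.
seq_matrix <- function(seqs) {
  stopifnot(length(unique(nchar(seqs))) == 1L)
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

assert_gene <- function(gene) {
  if (!is.character(gene) || length(gene) != 1L || !gene %in% SUPPORTED_GENES) {
    stop("`gene` must be one of: ", paste(SUPPORTED_GENES, collapse = ", "),
         call. = FALSE)
  }
  gene
}
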