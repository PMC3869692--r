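# Ovary fecundity classes and between-line comparisons. Mature (stage-14)
# egg counts map onto four classes: I = 0 eggs, II = 1-2, III = 3-9,
# IV = 10 or more. Records are per ovary; an aggregation option supports
# per-individual scoring as the larger of the two ovaries.

FECUNDITY_CLASSES <- c("I", "II", "III", "IV")

#' Classify ovaries by mature egg count
#'
#' @param count integer vector of mature (stage-14) egg counts (>= 0).
#' @return factor with levels I, II, III, IV.
#' @export
#' @examples
#' classify_ovary(c(0, 2, 9, 10)) # I II III IV
classify_ovary <- function(count) {
  if (any(count < 0) || any(count != round(count))) {
    stop("egg counts must be non-negative integers", call. = FALSE)
  }
  cls <- cut(count, breaks = c(-0.5, 0.5, 2.5, 9.5, Inf),
             labels = FECUNDITY_CLASSES)
  factor(cls, levels = FECUNDITY_CLASSES)
}

#' Build per-ovary records
#'
#' @param line line label.
#' @param individual_id individual identifiers (one per ovary record).
#' @param egg_count mature egg counts.
#' @return data frame with `line`, `individual_id`, `egg_count`, `class`.
#' @export
ovary_records <- function(line, individual_id, egg_count) {
  data.frame(line = line, individual_id = individual_id,
             egg_count = as.integer(egg_count),
             class = classify_ovary(egg_count), stringsAsFactors = FALSE)
}

#' Fecundity class distribution of a line
#'
#' @param records data frame from [ovary_records()] (possibly several
#'   lines).
#' @param line which line to tabulate.
#' @param per_individual score each individual as the class of its
#'   better ovary (max egg count over its records) instead of per ovary.
#' @return data frame with `class`, `n`, `pct`; percentages sum to 100 up
#'   to rounding. The sample size is attached as attribute `"n"`.
#' @export
class_distribution <- function(records, line, per_individual = FALSE) {
  sub <- records[records$line == line, , drop = FALSE]
  if (nrow(sub) == 0L) stop("unknown line: ", line, call. = FALSE)
  if (per_individual) {
    best <- tapply(sub$egg_count, sub$individual_id, max)
    cls <- classify_ovary(as.integer(best))
  } else {
    cls <- sub$class
  }
  tab <- table(factor(cls, levels = FECUNDITY_CLASSES))
  out <- data.frame(class = FECUNDITY_CLASSES, n = as.integer(tab),
                    pct = 100 * as.integer(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  attr(out, "n") <- sum(tab)
  out
}

#' Compare fecundity class distributions of two lines
#'
#' Two constructions are supported because published figure captions rarely
#' state theirs: `"classIV"` tests the 2x2 table (class IV vs not) and
#' `"full"` runs the exact conditional test on the complete 2x4 class table
#' by exhaustive enumeration (feasible at ~40 ovaries per line).
#'
#' @param recordsA,recordsB per-ovary records of the two lines.
#' @param mode `"classIV"` (default) or `"full"`.
#' @return a `contingency_result` (Fisher exact, two-tailed).
#' @export
compare_fecundity <- function(recordsA, recordsB,
                              mode = c("classIV", "full")) {
  mode <- match.arg(mode)
  stopifnot(nrow(recordsA) > 0L, nrow(recordsB) > 0L)
  tabA <- table(factor(recordsA$class, levels = FECUNDITY_CLASSES))
  tabB <- table(factor(recordsB$class, levels = FECUNDITY_CLASSES))
  if (mode == "classIV") {
    m <- rbind(c(tabA[["IV"]], sum(tabA) - tabA[["IV"]]),
               c(tabB[["IV"]], sum(tabB) - tabB[["IV"]]))
    fisher_exact(m)
  } else {
    m <- rbind(as.integer(tabA), as.integer(tabB))
    colnames(m) <- FECUNDITY_CLASSES
    fisher_exact_rxc(m)
  }
}
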