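# SNP calling of clone reads against the strain consensus, and
# recurrent-vs-singleton classification of variable positions.

#' Call substitutions of clone reads against the consensus
#'
#' One call is emitted per (clone, position) at which the read carries an
#' unambiguous base (`A`/`C`/`G`/`T`) different from the consensus base.
#' Positions where either the read or the consensus shows an IUPAC ambiguity
#' code produce no call and are logged — the automated analogue of excluding
#' all ambiguous SNPs after chromatogram inspection. Calling is position-wise
#' independent, so read order never affects the call set.
#'
#' @param amplicons a validated [amplicon_set()].
#' @param meta optional per-clone metadata (data frame with `clone_id` and
#'   `line`); defaults to the set's `"meta"` attribute.
#' @return data frame with columns `clone_id`, `line`, `gene`, `position`,
#'   `ref`, `alt`, ordered by clone then position.
#' @export
call_snps <- function(amplicons, meta = NULL) {
  stopifnot(inherits(amplicons, "amplicon_set"))
  validate_amplicon_set(amplicons)
  meta <- meta %||% attr(amplicons, "meta")
  cons <- strsplit(amplicons$consensus, "")[[1L]]
  cons_ok <- cons %in% ACGT
  if (!all(cons_ok)) {
    sp_log("info", "consensus has ambiguity codes at ",
           sum(!cons_ok), " position(s); excluded from calling")
  }
  m <- seq_matrix(amplicons$reads)
  out <- vector("list", nrow(m))
  n_ambig <- 0L
  for (i in seq_len(nrow(m))) {
    read <- m[i, ]
    read_ok <- read %in% ACGT
    n_ambig <- n_ambig + sum(!read_ok)
    hit <- which(read_ok & cons_ok & read != cons)
    if (length(hit)) {
      out[[i]] <- data.frame(
        clone_id = rownames(m)[i], position = hit,
        ref = cons[hit], alt = read[hit], stringsAsFactors = FALSE
      )
    }
  }
  if (n_ambig > 0L) {
    sp_log("info", n_ambig,
           " read position(s) with ambiguity codes excluded from calling")
  }
  calls <- do.call(rbind, out)
  if (is.null(calls)) {
    calls <- data.frame(clone_id = character(0), position = integer(0),
                        ref = character(0), alt = character(0),
                        stringsAsFactors = FALSE)
  }
  calls$gene <- rep(amplicons$gene, nrow(calls))
  calls$line <- if (!is.null(meta)) {
    meta$line[match(calls$clone_id, meta$clone_id)]
  } else {
    rep(NA_character_, nrow(calls))
  }
  calls <- calls[order(calls$clone_id, calls$position),
                 c("clone_id", "line", "gene", "position", "ref", "alt")]
  rownames(calls) <- NULL
  calls
}

#' Classify variable positions as recurrent or singleton
#'
#' Groups calls by (position, alternate base) — two different alternates at
#' one position are two distinct variant identities — and counts occurrences
#' over distinct clones (a clone never contributes twice to the same
#' variant). A variant seen in two or more independent clones is recurrent
#' regardless of whether the clones share a line or host system; exactly one
#' clone makes it a singleton.
#'
#' @param calls data frame from [call_snps()] (possibly pooled over several
#'   amplicon sets).
#' @return data frame with columns `gene`, `position`, `ref`, `alt`,
#'   `n_occurrences`, `contexts` (comma-collapsed contributing lines) and
#'   `class` (`"recurrent"`/`"singleton"`).
#' @export
classify_recurrence <- function(calls) {
  if (nrow(calls) == 0L) {
    return(data.frame(gene = character(0), position = integer(0),
                      ref = character(0), alt = character(0),
                      n_occurrences = integer(0), contexts = character(0),
                      class = character(0), stringsAsFactors = FALSE))
  }
  calls <- unique(calls[, c("clone_id", "line", "gene", "position", "ref",
                            "alt")])
  key <- interaction(calls$gene, calls$position, calls$alt, drop = TRUE)
  pieces <- lapply(split(calls, key), function(g) {
    data.frame(
      gene = g$gene[1L], position = g$position[1L], ref = g$ref[1L],
      alt = g$alt[1L], n_occurrences = length(unique(g$clone_id)),
      contexts = paste(sort(unique(g$line[!is.na(g$line)])), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, pieces)
  res$class <- ifelse(res$n_occurrences >= 2L, "recurrent", "singleton")
  res <- res[order(res$gene, res$position, res$alt), ]
  rownames(res) <- NULL
  res
}

#' Summarize the recurrent/singleton split
#'
#' @param classes data frame from [classify_recurrence()].
#' @return list with `n_recurrent`, `n_singleton`, `pct_recurrent`,
#'   `pct_singleton` (percentages rounded to the nearest integer).
#' @export
#' @examples
#' calls <- call_snps(load_fixtures("gatB_table1"))
#' summarize_recurrence(classify_recurrence(calls)) # 6 recurrent, 32 singleton
summarize_recurrence <- function(classes) {
  if (nrow(classes) == 0L) stop("no classified variants", call. = FALSE)
  n_rec <- sum(classes$class == "recurrent")
  n_sing <- sum(classes$class == "singleton")
  n <- n_rec + n_sing
  list(
    n_recurrent = n_rec, n_singleton = n_sing,
    pct_recurrent = as.integer(round_half_up(100 * n_rec / n)),
    pct_singleton = as.integer(round_half_up(100 * n_sing / n))
  )
}
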