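# Codon mapping, synonymous/nonsynonymous/nonsense annotation, and
# Nei-Gojobori (1986) path-counting dN/dS with Jukes-Cantor correction.
# The reading frame of each amplicon fragment is described by a frame offset:
# the number of leading bases to skip before the first complete codon
# (0 for all three MLST fragments; validated against the published paired
# nucleotide/amino-acid variant rows). The standard genetic code is used;
# its stop codons (TAA ochre, TAG amber, TGA opal) coincide with the
# bacterial code.

.codon_aa <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stop("invalid codon: ", codon, call. = FALSE)
  aa
}

#' Map a fragment position to its codon
#'
#' @param position 1-based position(s) within the fragment.
#' @param frame_offset bases to skip before the first complete codon (0-2).
#' @param fragment_length optional; when given, positions falling in a
#'   trailing incomplete codon are flagged `complete = FALSE`.
#' @return data frame with `position`, `codon_index` (1-based),
#'   `codon_pos` (1-3) and `complete`.
#' @export
#' @examples
#' map_codon(11) # codon 4, position 2
map_codon <- function(position, frame_offset = 0L, fragment_length = NULL) {
  stopifnot(frame_offset %in% 0:2)
  position <- as.integer(position)
  if (any(position <= frame_offset)) {
    stop("position must exceed frame_offset", call. = FALSE)
  }
  codon_index <- as.integer(ceiling((position - frame_offset) / 3))
  codon_pos <- ((position - frame_offset - 1L) %% 3L) + 1L
  complete <- rep(TRUE, length(position))
  if (!is.null(fragment_length)) {
    n_complete <- (fragment_length - frame_offset) %/% 3L
    complete <- codon_index <= n_complete
    if (any(!complete)) {
      sp_log("debug", sum(!complete),
             " position(s) fall in a trailing incomplete codon")
    }
  }
  data.frame(position = position, codon_index = codon_index,
             codon_pos = codon_pos, complete = complete)
}

#' Classify a codon substitution
#'
#' Annotates the change from `ref_codon` to `alt_codon` as synonymous,
#' nonsynonymous, or nonsense; nonsense changes are named by their stop
#' class (ochre TAA, amber TAG, opal TGA). A substitution is nonsense iff
#' the alternate codon is a stop and the reference codon is not.
#'
#' @param ref_codon,alt_codon 3-letter codons differing at >= 1 site.
#' @return list with `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`, `effect`
#'   (`"synonymous"`, `"nonsynonymous"`, `"nonsense"`) and `stop_class`
#'   (`"ochre"`, `"amber"`, `"opal"`, `"none"`).
#' @export
#' @examples
#' classify_substitution("CAA", "TAA")$stop_class # "ochre"
classify_substitution <- function(ref_codon, alt_codon) {
  ref_codon <- toupper(ref_codon); alt_codon <- toupper(alt_codon)
  if (identical(ref_codon, alt_codon)) {
    stop("codons are identical", call. = FALSE)
  }
  ref_aa <- .codon_aa(ref_codon)
  alt_aa <- .codon_aa(alt_codon)
  effect <- if (alt_aa == "*" && ref_aa != "*") {
    "nonsense"
  } else if (ref_aa == alt_aa) {
    "synonymous"
  } else {
    "nonsynonymous"
  }
  stop_class <- if (effect == "nonsense") {
    unname(STOP_CODONS[[alt_codon]])
  } else {
    "none"
  }
  list(ref_codon = ref_codon, alt_codon = alt_codon, ref_aa = ref_aa,
       alt_aa = alt_aa, effect = effect, stop_class = stop_class)
}

#' Scan clone reads for premature stop codons
#'
#' Emits one record per clone codon whose read codon is a stop while the
#' consensus codon is not. Codons containing ambiguity codes in the read are
#' skipped.
#'
#' @param amplicons a validated [amplicon_set()].
#' @param frame_offset reading-frame offset (default 0).
#' @param meta optional metadata (defaults to the set's `"meta"` attribute).
#' @return data frame with `clone_id`, `line`, `gene`, `position` (first
#'   mutated base within the codon), `codon_index`, `ref_codon`,
#'   `alt_codon`, `stop_class`.
#' @export
scan_premature_stops <- function(amplicons, frame_offset = 0L, meta = NULL) {
  stopifnot(inherits(amplicons, "amplicon_set"))
  validate_amplicon_set(amplicons)
  meta <- meta %||% attr(amplicons, "meta")
  len <- amplicons$expected_length
  n_codons <- (len - frame_offset) %/% 3L
  cons <- strsplit(amplicons$consensus, "")[[1L]]
  rows <- list()
  for (clone in names(amplicons$reads)) {
    read <- strsplit(amplicons$reads[[clone]], "")[[1L]]
    for (k in seq_len(n_codons)) {
      idx <- frame_offset + (k - 1L) * 3L + 1:3
      rc <- paste(cons[idx], collapse = "")
      ac <- paste(read[idx], collapse = "")
      if (!all(read[idx] %in% ACGT) || !all(cons[idx] %in% ACGT)) next
      if (ac %in% names(STOP_CODONS) && !(rc %in% names(STOP_CODONS))) {
        changed <- idx[cons[idx] != read[idx]]
        rows[[length(rows) + 1L]] <- data.frame(
          clone_id = clone, gene = amplicons$gene,
          position = changed[1L], codon_index = k, ref_codon = rc,
          alt_codon = ac, stop_class = unname(STOP_CODONS[[ac]]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    clone_id = character(0), gene = character(0), position = integer(0),
    codon_index = integer(0), ref_codon = character(0),
    alt_codon = character(0), stop_class = character(0),
    stringsAsFactors = FALSE
  )
  out$line <- if (!is.null(meta)) {
    meta$line[match(out$clone_id, meta$clone_id)]
  } else {
    rep(NA_character_, nrow(out))
  }
  out[, c("clone_id", "line", "gene", "position", "codon_index",
          "ref_codon", "alt_codon", "stop_class")]
}

# Fractional synonymous site count of one codon: at each of the 3 positions,
# the fraction of the 3 possible base changes that leave the amino acid
# unchanged. Changes to (or within) stop codons count as nonsynonymous,
# matching the equal-weighting site definition used throughout.
.codon_syn_sites <- function(codon) {
  b <- strsplit(codon, "")[[1L]]
  aa <- .codon_aa(codon)
  s <- 0
  for (p in 1:3) {
    for (alt in setdiff(ACGT, b[p])) {
      cand <- b
      cand[p] <- alt
      if (.codon_aa(paste(cand, collapse = "")) == aa) s <- s + 1 / 3
    }
  }
  s
}

# Average syn/nonsyn substitution counts between two codons over all
# equally weighted mutational paths (orderings of the differing positions).
# Paths passing through a premature stop codon are excluded when at least
# one stop-free path exists; otherwise all paths are used with a warning.
.codon_path_counts <- function(c1, c2) {
  b1 <- strsplit(c1, "")[[1L]]
  b2 <- strsplit(c2, "")[[1L]]
  diff_pos <- which(b1 != b2)
  n_diff <- length(diff_pos)
  if (n_diff == 0L) return(c(sd = 0, nd = 0))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  paths <- perms(diff_pos)
  step_counts <- lapply(paths, function(ord) {
    cur <- b1
    sd <- 0; nd <- 0; hits_stop <- FALSE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- b2[p]
      aa_cur <- .codon_aa(paste(cur, collapse = ""))
      aa_nxt <- .codon_aa(paste(nxt, collapse = ""))
      if (aa_nxt == "*" && !identical(nxt, b2)) hits_stop <- TRUE
      if (aa_cur == aa_nxt) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, hits_stop = hits_stop)
  })
  ok <- !vapply(step_counts, `[[`, logical(1), "hits_stop")
  if (!any(ok)) {
    warning("no stop-free mutational path between ", c1, " and ", c2,
            "; averaging over all paths")
    ok <- rep(TRUE, length(step_counts))
  }
  used <- step_counts[ok]
  c(sd = mean(vapply(used, `[[`, numeric(1), "sd")),
    nd = mean(vapply(used, `[[`, numeric(1), "nd")))
}

#' Nei-Gojobori dN/dS between two in-frame sequences
#'
#' Path-counting NG86: synonymous/nonsynonymous sites are counted per codon
#' as the fraction of the three possible changes at each position that are
#' synonymous (averaged between the two sequences); observed substitutions
#' in multi-hit codons are averaged over all equally weighted mutational
#' paths, excluding paths through premature stop codons when a stop-free
#' path exists. Proportions are Jukes-Cantor corrected:
#' `d = -3/4 * log(1 - 4/3 * p)`. Codons containing ambiguity codes or gaps
#' in either sequence, and any trailing incomplete codon, are skipped
#' pairwise.
#'
#' @param seqA,seqB equal-length nucleotide strings.
#' @param frame_offset reading-frame offset (default 0).
#' @return list with `S_sites`, `N_sites`, `Sd`, `Nd`, `pS`, `pN`, `dS`,
#'   `dN`, `dnds` (NA when undefined), `dnds_defined`, and
#'   `n_codons_compared`.
#' @export
ng86_dnds <- function(seqA, seqB, frame_offset = 0L) {
  seqA <- toupper(seqA); seqB <- toupper(seqB)
  if (nchar(seqA) != nchar(seqB)) {
    stop("sequences must have equal length", call. = FALSE)
  }
  stopifnot(frame_offset %in% 0:2)
  a <- strsplit(seqA, "")[[1L]]
  b <- strsplit(seqB, "")[[1L]]
  n_codons <- (length(a) - frame_offset) %/% 3L
  S <- 0; N <- 0; Sd <- 0; Nd <- 0; used <- 0L
  for (k in seq_len(n_codons)) {
    idx <- frame_offset + (k - 1L) * 3L + 1:3
    ca <- a[idx]; cb <- b[idx]
    if (!all(ca %in% ACGT) || !all(cb %in% ACGT)) next
    codA <- paste(ca, collapse = "")
    codB <- paste(cb, collapse = "")
    used <- used + 1L
    sA <- .codon_syn_sites(codA)
    sB <- .codon_syn_sites(codB)
    S <- S + (sA + sB) / 2
    N <- N + 3 - (sA + sB) / 2
    if (codA != codB) {
      counts <- .codon_path_counts(codA, codB)
      Sd <- Sd + counts[["sd"]]
      Nd <- Nd + counts[["nd"]]
    }
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  dS <- jc(pS); dN <- jc(pN)
  defined <- !is.na(dS) && !is.na(dN) && dS > 0
  list(S_sites = S, N_sites = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       dS = dS, dN = dN,
       dnds = if (defined) dN / dS else NA_real_,
       dnds_defined = defined, n_codons_compared = used)
}

#' dN/dS of each clone against the consensus
#'
#' Runs [ng86_dnds()] for every clone read against the set's consensus and
#' aggregates the ratio as the mean of pairwise ratios with undefined values
#' (dS = 0) dropped — the aggregation rule is deliberately explicit and
#' configurable since clone-library studies rarely state theirs.
#'
#' @param amplicons a validated [amplicon_set()].
#' @param frame_offset reading-frame offset.
#' @param aggregate `"mean"` (default) or `"none"` (per-clone table only).
#' @return list with `per_clone` (data frame) and `mean_dnds`.
#' @export
dnds_vs_consensus <- function(amplicons, frame_offset = 0L,
                              aggregate = c("mean", "none")) {
  stopifnot(inherits(amplicons, "amplicon_set"))
  aggregate <- match.arg(aggregate)
  rows <- lapply(names(amplicons$reads), function(clone) {
    r <- ng86_dnds(amplicons$consensus, amplicons$reads[[clone]],
                   frame_offset)
    data.frame(clone_id = clone, Sd = r$Sd, Nd = r$Nd, dS = r$dS, dN = r$dN,
               dnds = r$dnds, stringsAsFactors = FALSE)
  })
  per_clone <- do.call(rbind, rows)
  mean_dnds <- if (aggregate == "mean") {
    vals <- per_clone$dnds[!is.na(per_clone$dnds)]
    if (length(vals)) mean(vals) else NA_real_
  } else {
    NA_real_
  }
  list(per_clone = per_clone, mean_dnds = mean_dnds)
}
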