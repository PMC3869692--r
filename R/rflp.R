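# In-silico restriction fragment prediction: digest a circular or linear
# genome at an enzyme recognition site and count the fragments a probe locus
# would hybridize to. Coordinates are 1-based inclusive.

#' Digest a genome sequence at a restriction site
#'
#' Cuts at every occurrence of `site`; the cut falls after base
#' `cut_offset` of the site (default 1, mirroring HindIII's A^AGCTT).
#' For circular topology the segment past the last cut joins the segment
#' before the first cut; a circular sequence without any site yields a
#' single full-length fragment. Fragments are non-overlapping, cover the
#' genome, and their lengths always sum to the genome length.
#'
#' @param sequence genome nucleotide string.
#' @param site recognition sequence (length >= 4; default HindIII
#'   `"AAGCTT"`).
#' @param topology `"circular"` (default) or `"linear"`.
#' @param cut_offset bases of the site left of the cut (1 to
#'   `nchar(site) - 1`).
#' @return object of class `digest_result`: list with `fragments` (data
#'   frame `start`, `end`, `length`, `wraps`), `topology`, `genome_length`,
#'   `cut_positions` (position of the base just left of each cut).
#' @export
digest_genome <- function(sequence, site = "AAGCTT",
                          topology = c("circular", "linear"),
                          cut_offset = 1L) {
  topology <- match.arg(topology)
  sequence <- toupper(sequence)
  site <- toupper(site)
  L <- nchar(sequence)
  if (L == 0L) stop("empty sequence", call. = FALSE)
  if (nchar(site) < 4L) stop("site must be >= 4 bp", call. = FALSE)
  cut_offset <- as.integer(cut_offset)
  stopifnot(cut_offset >= 1L, cut_offset < nchar(site))
  # site occurrences; for circular topology also those spanning the origin
  subject <- if (topology == "circular" && L > nchar(site)) {
    paste0(sequence, substr(sequence, 1L, nchar(site) - 1L))
  } else {
    sequence
  }
  hits <- Biostrings::matchPattern(site, Biostrings::DNAString(subject))
  starts <- Biostrings::start(hits)
  starts <- starts[starts <= L]
  cuts <- sort(unique(((starts + cut_offset - 1L) - 1L) %% L + 1L))
  if (topology == "linear") {
    cuts <- cuts[cuts < L]
    bounds <- c(0L, cuts, L)
    frags <- data.frame(
      start = head(bounds, -1L) + 1L,
      end = bounds[-1L]
    )
    frags$length <- frags$end - frags$start + 1L
    frags$wraps <- FALSE
  } else if (length(cuts) == 0L) {
    frags <- data.frame(start = 1L, end = L, length = L, wraps = FALSE)
  } else {
    start <- cuts + 1L
    end <- c(cuts[-1L], cuts[1L])
    start[start > L] <- start[start > L] - L
    frags <- data.frame(start = start, end = end)
    frags$wraps <- frags$end < frags$start
    frags$length <- ifelse(frags$wraps,
                           L - frags$start + 1L + frags$end,
                           frags$end - frags$start + 1L)
    frags <- frags[, c("start", "end", "length", "wraps")]
  }
  structure(list(fragments = frags, topology = topology, genome_length = L,
                 cut_positions = cuts),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat("<digest_result>", nrow(x$fragments), "fragment(s),", x$topology,
      "genome of", x$genome_length, "bp\n")
  invisible(x)
}

# Overlap (bp) of a fragment with an interval, both 1-based inclusive;
# wrapped circular fragments are split into their two arcs.
.fragment_overlap <- function(frag_start, frag_end, wraps, L, iv_start,
                              iv_end) {
  arcs <- if (wraps) {
    list(c(frag_start, L), c(1L, frag_end))
  } else {
    list(c(frag_start, frag_end))
  }
  sum(vapply(arcs, function(a) {
    max(0L, min(a[2L], iv_end) - max(a[1L], iv_start) + 1L)
  }, numeric(1)))
}

#' Count fragments a probe locus hybridizes to
#'
#' A fragment is counted when it overlaps any probe interval by at least
#' `min_overlap` bp. The default 20 bp approximates the overlap needed for
#' detectable hybridization; it is a modelling choice, not an
#' experimentally derived constant.
#'
#' @param digest a [digest_genome()] result.
#' @param probe data frame of probe occurrence intervals with columns
#'   `start`, `end` (1-based inclusive), optionally `name`.
#' @param min_overlap minimum overlap in bp (default 20).
#' @return integer number of distinct hybridizing fragments.
#' @export
probe_fragment_count <- function(digest, probe, min_overlap = 20L) {
  stopifnot(inherits(digest, "digest_result"),
            all(c("start", "end") %in% names(probe)))
  L <- digest$genome_length
  if (any(probe$start < 1L) || any(probe$end > L) ||
      any(probe$start > probe$end)) {
    stop("probe intervals must satisfy 1 <= start <= end <= genome length",
         call. = FALSE)
  }
  frags <- digest$fragments
  hit <- vapply(seq_len(nrow(frags)), function(i) {
    any(vapply(seq_len(nrow(probe)), function(j) {
      .fragment_overlap(frags$start[i], frags$end[i], frags$wraps[i], L,
                        probe$start[j], probe$end[j]) >= min_overlap
    }, logical(1)))
  }, logical(1))
  sum(hit)
}

#' Read a BED-like probe table
#'
#' Tab-delimited columns `name`, `start`, `end` with 1-based inclusive
#' coordinates.
#'
#' @param path file path.
#' @return data frame of probe intervals.
#' @export
read_probe_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "start", "end") %in% names(df)))
  df
}
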