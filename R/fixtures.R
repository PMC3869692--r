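# Packaged fixtures reconstructed from the published variant-position,
# frequency and stop-codon tables. Full amplicon sequences are not printed in
# the source tables, so fixture sequences use a seeded synthetic background
# with the published variant positions, consensus bases and anchor codons
# applied; every downstream statistic depends only on positions and counts,
# not on the background sequence.

FIXTURE_SEED <- 20131204L

# Variable nucleotide positions of the 404-bp gatB fragment of wCer2:
# consensus base, per-line alternate (NA = line matches consensus) and the
# published recurrence annotation.
table1_variants <- function() {
  df <- read.delim(text = "position\tconsensus\tR.cerasi\tRC21\tRC20\tRC33\tRC45\tRC50\tWolMed88.6\tfreq_label
3\tT\t\t\t\t\tC\t\t\tsingleton
11\tA\t\t\t\t\t\tG\t\t2x in RC
16\tG\t\t\t\t\t\t\tA\tsingleton
31\tC\t\t\t\t\t\t\tT\tsingleton
32\tT\t\t\t\tA\t\t\t\tsingleton
36\tC\t\t\t\t\t\t\tA\tsingleton
42\tT\tC\t\tC\t\t\t\t\t3x in RC, 1x in R. cerasi
61\tA\tG\t\t\t\t\t\t\tsingleton
72\tA\tG\t\t\t\t\t\t\tsingleton
88\tT\t\t\t\t\t\tC\t\tsingleton
89\tA\t\t\t\tG\t\t\t\tsingleton
93\tT\t\t\tC\t\t\t\t\t2x in RC
102\tT\t\t\tC\t\t\t\t\tsingleton
112\tA\t\tG\t\t\t\t\t\tsingleton
121\tA\t\t\tT\t\t\t\t\tsingleton
149\tC\tT\t\t\t\t\t\t\tsingleton
186\tT\t\t\tC\t\t\t\t\t2x in RC
195\tA\tG\t\t\t\t\t\t\tsingleton
206\tA\t\t\t\t\t\t\tG\tsingleton
221\tT\tC\t\t\t\t\t\t\tsingleton
226\tC\t\t\tT\t\t\t\t\tsingleton
238\tT\t\t\t\t\tC\t\t\tsingleton
250\tA\t\t\t\tG\t\t\tG\t1x RC, 1x in WolMed88.6
253\tC\t\t\t\t\t\tT\tT\t1x RC, 1x in WolMed88.6
257\tT\t\t\t\t\tC\t\t\tsingleton
288\tT\t\t\t\t\tC\t\t\tsingleton
305\tT\t\t\tC\t\t\t\t\tsingleton
321\tA\tG\t\t\t\t\t\t\tsingleton
323\tA\t\t\tG\t\t\t\t\tsingleton
324\tA\tG\t\t\t\t\t\t\tsingleton
343\tA\t\t\tG\t\t\t\t\tsingleton
350\tA\t\t\t\t\t\t\tG\tsingleton
354\tA\t\t\t\t\tG\t\t\tsingleton
355\tA\t\t\t\t\t\tG\t\tsingleton
367\tT\t\t\t\tC\t\t\t\tsingleton
371\tT\t\t\t\t\t\tC\t\tsingleton
390\tA\t\t\t\t\tC\t\t\tsingleton
398\tA\t\t\t\t\t\t\tG\tsingleton
", stringsAsFactors = FALSE, na.strings = "")
  df
}

# Published per-clone occurrence multiplicities: the variant matrix collapses
# lines, so recurrence annotations ("2x in RC") are expanded here into clone
# multiplicities within the marked line(s). This is the only expansion
# consistent with the published RC20 per-kb rate (13 occurrences -> 2.68/kb);
# RC50 and RC21 are internally inconsistent in the source tables and are
# carried as-is (flagged by table2_discrepancies()).
.table1_multiplicity <- function(line, position) {
  if (line == "RC20" && position == 42) return(3L)
  if (line == "RC20" && position %in% c(93, 186)) return(2L)
  if (line == "RC50" && position == 11) return(2L)
  1L
}

# Published per-kb SNP frequencies for the gatB panel (donor + recipients).
table2_gatB <- function() {
  data.frame(
    no = 1:10,
    group = c("wCer1 of R. cerasi", "wCer2 of R. cerasi", "wCer1 of RC",
              "wCer2 of RC", "RC20", "RC33", "RC45", "RC50", "RC21",
              "WolMed88.6"),
    bases = c(9696L, 8888L, 1212L, 29088L, 4848L, 4848L, 4848L, 4848L,
              4848L, 4848L),
    rate_per_kb = c(0.52, 1.01, 2.48, 1.01, 2.68, 0.83, 1.24, 1.03, 0.00,
                    1.65),
    corrected_rate_per_kb = c(NA, 0.73, NA, 0.73, 2.40, 0.55, 0.96, 0.75,
                              -0.28, 1.37),
    stringsAsFactors = FALSE
  )
}

# Premature stop codons in the MLST loci of wCer1 and wCer2.
table3_stops <- function() {
  data.frame(
    line = c("RC20", "RC50", "WolMed88.6", "RC20",
             "F37 eastern Sicily", "F38 eastern Sicily",
             "F40 western Sicily", "F42 western Sicily"),
    gene = c("gatB", "gatB", "gatB", "coxA", "ftsZ", "ftsZ", "ftsZ", "ftsZ"),
    position = c(226L, 253L, 253L, 22L, 25L, 25L, 25L, 25L),
    fragment_length = c(404L, 404L, 404L, 444L, 478L, 478L, 478L, 478L),
    ref_codon = c("CAA", "CAA", "CAA", "AAA", "GGA", "GGA", "GGA", "GGA"),
    alt_codon = c("TAA", "TAA", "TAA", "TAA", "TGA", "TGA", "TGA", "TGA"),
    stop_class = c("ochre", "ochre", "ochre", "ochre", "opal", "opal",
                   "opal", "opal"),
    strain = c("wCer2", "wCer2", "wCer2", "wCer1", "wCer1", "wCer1", "wCer1",
               "wCer1"),
    stringsAsFactors = FALSE
  )
}

# Taq polymerase control re-sequencing sets used for the error baseline.
taq_controls <- function() {
  data.frame(
    gene = c("coxA", "ftsZ", "gatB"),
    n_clones = c(10L, 10L, 14L),
    length_bp = c(444L, 290L, 429L),
    n_errors = c(0L, 0L, 2L),
    stringsAsFactors = FALSE
  )
}

# Build a synthetic consensus of `len` bases under constraints:
#  - `fixed`: named vector position -> base (published consensus bases),
#  - `pinned_codons`: named list codon_index -> 3-base codon (anchor codons),
#  - no in-frame stop codon in the consensus,
#  - no variant in `variants` (position, alt) creates a stop codon unless
#    flagged `allow_stop` (the published nonsense mutations).
# Deterministic for a given seed.
.build_consensus <- function(len, fixed = integer(0), pinned_codons = list(),
                             variants = NULL, seed = FIXTURE_SEED) {
  bases <- local({
    set.seed(seed)
    sample(ACGT, len, replace = TRUE)
  })
  constrained <- logical(len)
  for (ci in names(pinned_codons)) {
    idx <- (as.integer(ci) - 1L) * 3L + 1:3
    bases[idx] <- strsplit(pinned_codons[[ci]], "")[[1L]]
    constrained[idx] <- TRUE
  }
  if (length(fixed)) {
    pos <- as.integer(names(fixed))
    conflict <- constrained[pos] & bases[pos] != unname(fixed)
    if (any(conflict)) {
      stop("fixed base conflicts with pinned codon at position ",
           paste(pos[conflict], collapse = ", "))
    }
    bases[pos] <- unname(fixed)
    constrained[pos] <- TRUE
  }
  n_codons <- len %/% 3L
  codon_ok <- function(codon_bases, vars) {
    cod <- paste(codon_bases, collapse = "")
    if (cod %in% names(STOP_CODONS)) return(FALSE)
    if (!is.null(vars) && nrow(vars)) {
      for (i in seq_len(nrow(vars))) {
        alt <- codon_bases
        alt[vars$codon_pos[i]] <- vars$alt[i]
        if (paste(alt, collapse = "") %in% names(STOP_CODONS) &&
            !vars$allow_stop[i]) {
          return(FALSE)
        }
      }
    }
    TRUE
  }
  for (k in seq_len(n_codons)) {
    idx <- (k - 1L) * 3L + 1:3
    vars <- NULL
    if (!is.null(variants)) {
      vars <- variants[variants$position %in% idx, , drop = FALSE]
      if (nrow(vars)) vars$codon_pos <- vars$position - (k - 1L) * 3L
    }
    if (codon_ok(bases[idx], vars)) next
    free <- idx[!constrained[idx]]
    if (!length(free)) {
      stop("over-constrained codon ", k, " cannot avoid stop codons")
    }
    fills <- expand.grid(rep(list(ACGT), length(free)),
                         stringsAsFactors = FALSE)
    found <- FALSE
    for (r in seq_len(nrow(fills))) {
      cand <- bases[idx]
      cand[match(free, idx)] <- unlist(fills[r, ], use.names = FALSE)
      if (codon_ok(cand, vars)) {
        bases[idx] <- cand
        found <- TRUE
        break
      }
    }
    if (!found) stop("no stop-free fill for codon ", k)
  }
  paste(bases, collapse = "")
}

.gatb_fixture_consensus <- function() {
  t1 <- table1_variants()
  fixed <- setNames(t1$consensus, t1$position)
  # Anchor codons consistent with the published paired nt/aa rows:
  # codon 1 Ala (nt 3 T->C synonymous), codon 4 Glu GAA (nt 11 A->G E->G),
  # codons 76/85 CAA Gln hit by the ochre mutations at nt 226/253,
  # codon 108 Lys AAA (nt 323 A->G K->R, nt 324 A->G synonymous).
  pinned <- list(`1` = "GCT", `4` = "GAA", `76` = "CAA", `85` = "CAA",
                 `108` = "AAA")
  lines <- c("R.cerasi", "RC21", "RC20", "RC33", "RC45", "RC50", "WolMed88.6")
  vars <- do.call(rbind, lapply(lines, function(ln) {
    alt <- t1[[ln]]
    keep <- !is.na(alt)
    if (!any(keep)) return(NULL)
    data.frame(position = t1$position[keep], alt = alt[keep],
               stringsAsFactors = FALSE)
  }))
  vars <- unique(vars)
  vars$allow_stop <- vars$position %in% c(226L, 253L)
  .build_consensus(404L, fixed = fixed, pinned_codons = pinned,
                   variants = vars)
}

# Clone layout of the gatB fixture: 22 donor clones (8,888 bp), 12 clones per
# recipient line. Occurrences are assigned to distinct clones within each
# line, cycling when a line has more occurrences than clones.
.gatb_fixture_layout <- function() {
  list(
    `R.cerasi` = list(n = 22L, host = "R. cerasi", prefix = "Rcer"),
    RC20 = list(n = 12L, host = "D. simulans", prefix = "RC20"),
    RC21 = list(n = 12L, host = "D. simulans", prefix = "RC21"),
    RC33 = list(n = 12L, host = "D. simulans", prefix = "RC33"),
    RC45 = list(n = 12L, host = "D. simulans", prefix = "RC45"),
    RC50 = list(n = 12L, host = "D. simulans", prefix = "RC50"),
    WolMed88.6 = list(n = 12L, host = "C. capitata", prefix = "WM")
  )
}

.gatb_fixture_set <- function() {
  cons <- .gatb_fixture_consensus()
  t1 <- table1_variants()
  layout <- .gatb_fixture_layout()
  reads <- character(0)
  meta <- NULL
  for (ln in names(layout)) {
    info <- layout[[ln]]
    ids <- sprintf("%s_c%02d", info$prefix, seq_len(info$n))
    seqs <- setNames(rep(cons, info$n), ids)
    col <- if (ln == "R.cerasi") "R.cerasi" else ln
    alt <- t1[[col]]
    keep <- which(!is.na(alt))
    occ_pos <- integer(0)
    occ_alt <- character(0)
    for (i in keep) {
      m <- .table1_multiplicity(ln, t1$position[i])
      occ_pos <- c(occ_pos, rep(t1$position[i], m))
      occ_alt <- c(occ_alt, rep(alt[i], m))
    }
    if (length(occ_pos)) {
      clone_idx <- ((seq_along(occ_pos) - 1L) %% info$n) + 1L
      for (j in seq_along(occ_pos)) {
        s <- strsplit(seqs[[clone_idx[j]]], "")[[1L]]
        s[occ_pos[j]] <- occ_alt[j]
        seqs[[clone_idx[j]]] <- paste(s, collapse = "")
      }
    }
    reads <- c(reads, seqs)
    meta <- rbind(meta, data.frame(
      clone_id = ids, line = ln, host_species = info$host,
      generation = NA_integer_, gene = "gatB",
      strain_label = "wCer2", stringsAsFactors = FALSE
    ))
  }
  amplicon_set("gatB", cons, reads, 404L, meta = meta)
}

# coxA fixture: wCer1 in line RC20 with one ochre singleton (AAA -> TAA at
# position 22, codon 8); five further clean clones.
.coxa_fixture_set <- function() {
  vars <- data.frame(position = 22L, alt = "T", allow_stop = TRUE,
                     stringsAsFactors = FALSE)
  cons <- .build_consensus(444L, fixed = c(`22` = "A"),
                           pinned_codons = list(`8` = "AAA"),
                           variants = vars, seed = FIXTURE_SEED + 1L)
  ids <- sprintf("RC20cox_c%02d", 1:6)
  seqs <- setNames(rep(cons, 6L), ids)
  s <- strsplit(seqs[[1L]], "")[[1L]]
  s[22L] <- "T"
  seqs[[1L]] <- paste(s, collapse = "")
  meta <- data.frame(clone_id = ids, line = "RC20",
                     host_species = "D. simulans",
                     generation = NA_integer_, gene = "coxA",
                     strain_label = "wCer1", stringsAsFactors = FALSE)
  amplicon_set("coxA", cons, seqs, 444L, meta = meta)
}

# ftsZ fixture: the recurrent (4x) opal mutation of wCer1 (GGA -> TGA at
# position 25, codon 9) in four Sicilian donor individuals, plus clean clones.
.ftsz_fixture_set <- function() {
  vars <- data.frame(position = 25L, alt = "T", allow_stop = TRUE,
                     stringsAsFactors = FALSE)
  cons <- .build_consensus(478L, fixed = c(`25` = "G"),
                           pinned_codons = list(`9` = "GGA"),
                           variants = vars, seed = FIXTURE_SEED + 2L)
  carriers <- c("F37", "F38", "F40", "F42")
  clean <- c("F30", "F31", "F33", "F35")
  ids <- c(carriers, clean)
  seqs <- setNames(rep(cons, length(ids)), ids)
  for (id in carriers) {
    s <- strsplit(seqs[[id]], "")[[1L]]
    s[25L] <- "T"
    seqs[[id]] <- paste(s, collapse = "")
  }
  meta <- data.frame(
    clone_id = ids,
    line = c("F37 eastern Sicily", "F38 eastern Sicily",
             "F40 western Sicily", "F42 western Sicily",
             rep("Rcerasi-Sicily", length(clean))),
    host_species = "R. cerasi", generation = NA_integer_,
    gene = "ftsZ", strain_label = "wCer1", stringsAsFactors = FALSE
  )
  amplicon_set("ftsZ", cons, seqs, 478L, meta = meta)
}

#' Load a packaged fixture
#'
#' Fixtures are reconstructed in code from the published variant-position,
#' frequency, stop-codon and polymerase-control tables; sequence fixtures use
#' a seeded synthetic background (see package vignette). Available names:
#'
#' * `"gatB_table1"`: the 404-bp gatB amplicon set of wCer2 (donor plus six
#'   recipient lines, clone metadata attached as attribute `"meta"`).
#' * `"coxA_table3"`, `"ftsZ_table3"`: amplicon sets carrying the published
#'   premature stop mutations.
#' * `"table1_positions"`: the 38-row variable-position table.
#' * `"table2_gatB"`: printed per-kb frequencies of the gatB panel.
#' * `"table3_stops"`: the 8 published stop-codon records.
#' * `"taq_controls"`: polymerase control re-sequencing sets.
#'
#' @param name fixture name.
#' @return an `amplicon_set` or data frame, depending on the fixture.
#' @export
#' @examples
#' nrow(load_fixtures("table1_positions")) # 38 variable positions
load_fixtures <- function(name) {
  registry <- c("gatB_table1", "coxA_table3", "ftsZ_table3",
                "table1_positions", "table2_gatB", "table3_stops",
                "taq_controls")
  if (!is.character(name) || length(name) != 1L || !name %in% registry) {
    stop("unknown fixture; available: ", paste(registry, collapse = ", "),
         call. = FALSE)
  }
  switch(name,
    gatB_table1 = .gatb_fixture_set(),
    coxA_table3 = .coxa_fixture_set(),
    ftsZ_table3 = .ftsz_fixture_set(),
    table1_positions = table1_variants(),
    table2_gatB = table2_gatB(),
    table3_stops = table3_stops(),
    taq_controls = taq_controls()
  )
}
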