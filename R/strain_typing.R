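# Strain assignment of clone reads via diagnostic sites, co-infection
# detection, prevalence-switch localization across host generations, and a
# Monte-Carlo detection-power estimator for low-titer minor strains.
#
# Real diagnostic wsp/VNTR sequences are not published; packaged profiles
# are seeded synthetic stand-ins (make_wsp_profile) and real profiles are a
# configurable input.

#' Construct a diagnostic strain profile
#'
#' A sequence-marker profile lists diagnostic sites with the expected base
#' per strain; a length-polymorphic marker (VNTR-style) lists the expected
#' amplicon length per strain instead.
#'
#' @param marker marker name, e.g. `"wsp"` or `"VNTR-141"`.
#' @param sites data frame with column `position` plus one base column per
#'   strain (for sequence markers).
#' @param lengths named numeric vector of expected amplicon length per
#'   strain (for length markers).
#' @return object of class `diagnostic_profile`.
#' @export
diagnostic_profile <- function(marker, sites = NULL, lengths = NULL) {
  if (is.null(sites) && is.null(lengths)) {
    stop("provide diagnostic sites and/or lengths", call. = FALSE)
  }
  strains <- character(0)
  if (!is.null(sites)) {
    stopifnot(is.data.frame(sites), "position" %in% names(sites))
    strains <- setdiff(names(sites), "position")
    if (length(strains) < 2L) {
      stop("a site profile must discriminate >= 2 strains", call. = FALSE)
    }
    discriminates <- apply(sites[, strains, drop = FALSE], 1L,
                           function(x) length(unique(x)) >= 2L)
    if (!all(discriminates)) {
      stop("every site must discriminate >= 2 strains; offending position(s): ",
           paste(sites$position[!discriminates], collapse = ", "),
           call. = FALSE)
    }
  }
  if (!is.null(lengths)) {
    stopifnot(!is.null(names(lengths)))
    strains <- union(strains, names(lengths))
  }
  structure(list(marker = marker, sites = sites, lengths = lengths,
                 strains = strains),
            class = "diagnostic_profile")
}

#' Generate a synthetic wsp-style diagnostic profile
#'
#' Builds a seeded random marker fragment plus per-strain reference
#' sequences differing at `n_sites` diagnostic positions. Synthetic
#' stand-in: real diagnostic haplotypes are a user input.
#'
#' @param n_sites number of diagnostic sites (default 4).
#' @param length fragment length in bp (default 36, a short informative
#'   window of the full marker amplicon).
#' @param strains strain names (default wCer1/wCer2).
#' @param seed RNG seed.
#' @return list with `profile` (a [diagnostic_profile()]) and `references`
#'   (named character vector of per-strain sequences).
#' @export
make_wsp_profile <- function(n_sites = 4L, length = 36L,
                             strains = c("wCer1", "wCer2"), seed = 1L) {
  stopifnot(n_sites >= 1L, n_sites <= length, length(strains) >= 2L)
  set.seed(seed)
  backbone <- sample(ACGT, length, replace = TRUE)
  pos <- sort(sample.int(length, n_sites))
  sites <- data.frame(position = pos)
  refs <- setNames(rep(list(backbone), length(strains)), strains)
  for (i in seq_along(pos)) {
    bases <- sample(ACGT, length(strains)) # without replacement: distinct
    for (s in seq_along(strains)) refs[[s]][pos[i]] <- bases[s]
  }
  for (s in strains) {
    sites[[s]] <- vapply(pos, function(p) refs[[s]][p], character(1))
  }
  list(profile = diagnostic_profile("wsp", sites = sites),
       references = vapply(refs, paste, character(1), collapse = ""))
}

#' Type one read against a diagnostic profile
#'
#' Scores each strain as the fraction of diagnostic sites at which the read
#' matches that strain's base, and calls the best-scoring strain when its
#' score reaches `threshold` and is unique; ties and sub-threshold matches
#' are `"unknown"` — never probabilistically assigned.
#'
#' @param read nucleotide string covering all profile sites.
#' @param profile a [diagnostic_profile()] with sites.
#' @param threshold minimum match fraction for a call (default 0.9).
#' @return object of class `strain_call`: list with `strain`, `confidence`,
#'   `scores`, `evidence` (matched positions of the called strain).
#' @export
type_clone <- function(read, profile, threshold = 0.9) {
  stopifnot(inherits(profile, "diagnostic_profile"))
  if (is.null(profile$sites)) {
    stop("profile has no sequence sites; use type_by_length()", call. = FALSE)
  }
  read <- toupper(read)
  sites <- profile$sites
  if (nchar(read) < max(sites$position)) {
    stop("read shorter than the last diagnostic site", call. = FALSE)
  }
  bases <- strsplit(read, "")[[1L]][sites$position]
  strains <- setdiff(names(sites), "position")
  scores <- vapply(strains, function(s) mean(bases == sites[[s]]), numeric(1))
  best <- max(scores)
  winners <- strains[scores == best]
  strain <- if (best >= threshold && length(winners) == 1L) {
    winners
  } else {
    "unknown"
  }
  evidence <- if (strain != "unknown") {
    sites$position[bases == sites[[strain]]]
  } else {
    integer(0)
  }
  structure(list(strain = strain, confidence = best, scores = scores,
                 evidence = evidence),
            class = "strain_call")
}

#' @export
print.strain_call <- function(x, ...) {
  cat("<strain_call>", x$strain, "(confidence", round(x$confidence, 3), ")\n")
  invisible(x)
}

#' Type an amplicon by fragment length (VNTR-style)
#'
#' Calls the strain whose expected amplicon length is within `tol` bp of the
#' observed length; ambiguous (several strains within tolerance) or
#' unmatched lengths give `"unknown"`.
#'
#' @param observed_length observed amplicon length (bp).
#' @param profile a [diagnostic_profile()] with `lengths`.
#' @param tol length tolerance in bp (default 2, approximating gel
#'   resolution).
#' @return a `strain_call`.
#' @export
type_by_length <- function(observed_length, profile, tol = 2) {
  stopifnot(inherits(profile, "diagnostic_profile"))
  if (is.null(profile$lengths)) {
    stop("profile has no length table", call. = FALSE)
  }
  d <- abs(profile$lengths - observed_length)
  hits <- names(profile$lengths)[d <= tol]
  strain <- if (length(hits) == 1L) hits else "unknown"
  structure(list(strain = strain,
                 confidence = if (length(hits) == 1L) 1 else 0,
                 scores = setNames(as.numeric(d <= tol),
                                   names(profile$lengths)),
                 evidence = observed_length),
            class = "strain_call")
}

#' Type every read of an amplicon set
#'
#' @param amplicons an [amplicon_set()] of marker reads.
#' @param profile a [diagnostic_profile()].
#' @param threshold match threshold passed to [type_clone()].
#' @return data frame with `clone_id`, `strain`, `confidence`.
#' @export
type_amplicons <- function(amplicons, profile, threshold = 0.9) {
  stopifnot(inherits(amplicons, "amplicon_set"))
  rows <- lapply(names(amplicons$reads), function(id) {
    call <- type_clone(amplicons$reads[[id]], profile, threshold)
    data.frame(clone_id = id, strain = call$strain,
               confidence = call$confidence, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Infection status from per-sample strain calls
#'
#' `multiple` iff at least two distinct non-unknown strains are each
#' supported by `min_reads` or more calls; `single` when exactly one is;
#' `none` when no strain reaches support (a strain with zero supporting
#' calls is never reported).
#'
#' @param calls character vector of strain labels, or the data frame from
#'   [type_amplicons()].
#' @param min_reads minimum supporting calls per strain (default 1).
#' @return list with `status` (`"single"`, `"multiple"`, `"none"`) and
#'   `strains` (supported strains).
#' @export
detect_coinfection <- function(calls, min_reads = 1L) {
  if (is.data.frame(calls)) calls <- calls$strain
  if (!length(calls)) stop("need >= 1 strain call", call. = FALSE)
  tab <- table(calls[calls != "unknown"])
  supported <- names(tab)[tab >= min_reads]
  status <- if (length(supported) >= 2L) {
    "multiple"
  } else if (length(supported) == 1L) {
    "single"
  } else {
    "none"
  }
  list(status = status, strains = sort(supported))
}

#' Localize a strain prevalence switch across generations
#'
#' Given per-generation detected strain sets, returns the last generation at
#' which `from_strain` was still detected and the first later generation at
#' which `to_strain` was detected without `from_strain`; `NULL` when no such
#' pattern exists.
#'
#' @param series data frame with `generation` (strictly increasing) and
#'   `strains` (list column of character vectors, or comma-separated
#'   strings).
#' @param from_strain,to_strain strain labels.
#' @return list `(g_last_from, g_first_to_only)` or `NULL`.
#' @export
locate_switch <- function(series, from_strain, to_strain) {
  stopifnot(is.data.frame(series), nrow(series) >= 2L,
            all(c("generation", "strains") %in% names(series)))
  if (is.unsorted(series$generation, strictly = TRUE)) {
    stop("generations must be strictly increasing", call. = FALSE)
  }
  sets <- if (is.list(series$strains)) {
    series$strains
  } else {
    strsplit(as.character(series$strains), "\\s*,\\s*")
  }
  has_from <- vapply(sets, function(s) from_strain %in% s, logical(1))
  has_to <- vapply(sets, function(s) to_strain %in% s, logical(1))
  if (!any(has_from)) return(NULL)
  g_last_from <- max(series$generation[has_from])
  to_only <- has_to & !has_from & series$generation > g_last_from
  if (!any(to_only)) return(NULL)
  list(g_last_from = g_last_from,
       g_first_to_only = min(series$generation[to_only]))
}

#' Monte-Carlo detection power for a low-titer minor strain
#'
#' Simulates `n_reads` clone reads per replicate: each read derives from the
#' minor strain with probability `titer_fraction` (otherwise the major
#' strain), per-base errors at rate `error_rate` are injected into the
#' reference sequences, reads are typed with [type_clone()], and the minor
#' strain counts as detected when it gains at least `min_reads` calls. With
#' no error and `min_reads = 1` the power is `1 - (1 - titer)^n` in closed
#' form, which the Monte-Carlo estimate must reproduce.
#'
#' @param titer_fraction minor-strain frequency in `[0, 1]`.
#' @param n_reads clone reads sampled per replicate.
#' @param error_rate per-base substitution error rate.
#' @param profile output of [make_wsp_profile()] (profile plus references),
#'   or a list with elements `profile` and `references`. The first strain in
#'   the profile is the major one, the second the minor.
#' @param n_reps Monte-Carlo replicates (default 500).
#' @param min_reads calls required to claim detection (default 1).
#' @param seed optional RNG seed.
#' @return list with `power`, `mc_se`, `n_reps`.
#' @export
detection_power <- function(titer_fraction, n_reads, error_rate = 0,
                            profile, n_reps = 500L, min_reads = 1L,
                            seed = NULL) {
  stopifnot(titer_fraction >= 0, titer_fraction <= 1, n_reads >= 1L)
  if (!is.null(seed)) set.seed(seed)
  prof <- profile$profile
  refs <- profile$references
  stopifnot(inherits(prof, "diagnostic_profile"), length(refs) >= 2L)
  major <- prof$strains[1L]
  minor <- prof$strains[2L]
  len <- nchar(refs[[1L]])
  detected <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    src <- ifelse(runif(n_reads) < titer_fraction, minor, major)
    n_minor_calls <- 0L
    for (i in seq_len(n_reads)) {
      read <- strsplit(refs[[src[i]]], "")[[1L]]
      if (error_rate > 0) {
        hit <- which(runif(len) < error_rate)
        for (p in hit) read[p] <- sample(setdiff(ACGT, read[p]), 1L)
      }
      call <- type_clone(paste(read, collapse = ""), prof)
      if (call$strain == minor) n_minor_calls <- n_minor_calls + 1L
    }
    detected[r] <- n_minor_calls >= min_reads
  }
  p <- mean(detected)
  list(power = p, mc_se = sqrt(p * (1 - p) / n_reps), n_reps = n_reps)
}
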