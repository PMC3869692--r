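# Forward simulator for the whole sampling process the pipeline assumes:
# a donor symbiont population of haplotypes at varying frequencies, a
# transfer bottleneck at microinjection, neutral Wright-Fisher drift with
# imperfect maternal transmission across host generations, and clone
# re-sequencing with per-base polymerase error. Every output carries a
# ground-truth ledger that fully determines the expected pipeline results.

#' Build a haplotype pool
#'
#' Haplotype 1 is the canonical consensus; each further haplotype differs
#' from it at one or more drawn variant sites (sites are assigned to
#' non-canonical haplotypes round-robin, so every site segregates in
#' exactly one haplotype).
#'
#' @param n_haplotypes number of haplotypes (>= 1).
#' @param n_variant_sites total variant sites distributed over the
#'   non-canonical haplotypes; must be 0 when `n_haplotypes` is 1 and less
#'   than the fragment length.
#' @param freq_spec haplotype frequencies: numeric vector summing to 1,
#'   `"uniform"`, or `list(dirichlet = alpha)` for a seeded Dirichlet draw.
#' @param gene locus name (sets the default fragment length).
#' @param fragment_length fragment length in bp.
#' @param consensus optional canonical sequence; generated (seeded) when
#'   absent.
#' @param seed RNG seed.
#' @return object of class `haplotype_pool`: list with `gene`, `strain`,
#'   `haplotypes` (named character vector), `frequencies`, and `sites`
#'   (ledger data frame: `position`, `ref`, `alt`, `haplotype`).
#' @export
make_pool <- function(n_haplotypes, n_variant_sites, freq_spec = "uniform",
                      gene = "gatB", fragment_length = NULL,
                      consensus = NULL, strain = "wCer2", seed = 1L) {
  assert_gene(gene)
  if (is.null(fragment_length)) {
    fragment_length <- GENE_LENGTHS[[gene]]
    if (is.na(fragment_length)) stop("fragment_length required for ", gene,
                                     call. = FALSE)
  }
  stopifnot(n_haplotypes >= 1L, n_variant_sites >= 0L,
            n_variant_sites < fragment_length)
  if (n_haplotypes == 1L && n_variant_sites > 0L) {
    stop("a single-haplotype pool cannot carry variant sites", call. = FALSE)
  }
  if (n_haplotypes > 1L && n_variant_sites < 1L) {
    stop("need >= 1 variant site to distinguish ", n_haplotypes,
         " haplotypes", call. = FALSE)
  }
  set.seed(seed)
  if (is.null(consensus)) {
    consensus <- paste(sample(ACGT, fragment_length, replace = TRUE),
                       collapse = "")
  }
  freqs <- if (identical(freq_spec, "uniform")) {
    rep(1 / n_haplotypes, n_haplotypes)
  } else if (is.list(freq_spec) && !is.null(freq_spec$dirichlet)) {
    alpha <- rep_len(freq_spec$dirichlet, n_haplotypes)
    g <- vapply(alpha, function(a) stats::rgamma(1L, a), numeric(1))
    g / sum(g)
  } else {
    as.numeric(freq_spec)
  }
  if (length(freqs) != n_haplotypes || abs(sum(freqs) - 1) > 1e-9 ||
      any(freqs < 0)) {
    stop("frequencies must be length ", n_haplotypes, " and sum to 1",
         call. = FALSE)
  }
  hap_names <- paste0("hap", seq_len(n_haplotypes))
  haps <- setNames(rep(consensus, n_haplotypes), hap_names)
  sites <- data.frame(position = integer(0), ref = character(0),
                      alt = character(0), haplotype = character(0),
                      stringsAsFactors = FALSE)
  if (n_variant_sites > 0L) {
    pos <- sort(sample.int(fragment_length, n_variant_sites))
    owner <- ((seq_along(pos) - 1L) %% (n_haplotypes - 1L)) + 2L
    cons_bases <- strsplit(consensus, "")[[1L]]
    alt <- vapply(pos, function(p) sample(setdiff(ACGT, cons_bases[p]), 1L),
                  character(1))
    for (i in seq_along(pos)) {
      s <- strsplit(haps[[owner[i]]], "")[[1L]]
      s[pos[i]] <- alt[i]
      haps[[owner[i]]] <- paste(s, collapse = "")
    }
    sites <- data.frame(position = pos, ref = cons_bases[pos], alt = alt,
                        haplotype = hap_names[owner],
                        stringsAsFactors = FALSE)
  }
  structure(list(gene = gene, strain = strain, haplotypes = haps,
                 frequencies = setNames(freqs, hap_names),
                 consensus = consensus, sites = sites),
            class = "haplotype_pool")
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat("<haplotype_pool>", x$strain, x$gene, "|", length(x$haplotypes),
      "haplotype(s),", nrow(x$sites), "variant site(s)\n")
  invisible(x)
}

#' Simulation configuration
#'
#' Defaults describe the transfer experiments the simulator emulates: a
#' predominantly wCer2 infection with a low-titer wCer1 co-infection,
#' founding bottlenecks at microinjection, and maternal transmission that
#' starts imperfect (65% prevalence shortly after transfer) and approaches
#' completeness (95%) in later generations. The per-generation effective
#' symbiont population size is not derivable from published data and is an
#' explicit free parameter.
#'
#' @param strain_titers named initial strain frequencies (sum to 1).
#' @param bottleneck_size founding symbiont sample size N_b at transfer.
#' @param generations host generations G to simulate.
#' @param effective_size per-generation symbiont effective size N_e
#'   (>= N_b).
#' @param transmission_initial,transmission_late per-generation maternal
#'   transmission probabilities before/after `transmission_switch_gen`.
#' @param transmission_switch_gen generation at which transmission improves.
#' @param condition_on_retention treat lines as selected for retained
#'   infection: transmission failures are counted in the ledger but do not
#'   extinguish the line (the selection regime of the source experiments).
#' @param error_rate per-base polymerase/cloning error rate (default
#'   1.5e-4, i.e. 0.15 SNPs/kb).
#' @param clones_per_sample clone reads sequenced per sampled line and
#'   generation.
#' @param n_lines number of independent recipient lines.
#' @param sample_generations generations at which clones are sequenced.
#' @param fitness optional per-haplotype relative fitness (default neutral).
#' @param seed RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(strain_titers = c(wCer2 = 0.98, wCer1 = 0.02),
                       bottleneck_size = 100L,
                       generations = 10L,
                       effective_size = 1000L,
                       transmission_initial = 0.65,
                       transmission_late = 0.95,
                       transmission_switch_gen = 5L,
                       condition_on_retention = TRUE,
                       error_rate = 1.5e-4,
                       clones_per_sample = 12L,
                       n_lines = 5L,
                       sample_generations = NULL,
                       fitness = NULL,
                       seed = 1L) {
  stopifnot(abs(sum(strain_titers) - 1) < 1e-9, all(strain_titers >= 0),
            bottleneck_size >= 1L, generations >= 1L,
            effective_size >= bottleneck_size,
            transmission_initial >= 0, transmission_initial <= 1,
            transmission_late >= 0, transmission_late <= 1,
            error_rate >= 0, error_rate <= 1, clones_per_sample >= 1L,
            n_lines >= 1L)
  structure(
    list(strain_titers = strain_titers, bottleneck_size = bottleneck_size,
         generations = generations, effective_size = effective_size,
         transmission_initial = transmission_initial,
         transmission_late = transmission_late,
         transmission_switch_gen = transmission_switch_gen,
         condition_on_retention = condition_on_retention,
         error_rate = error_rate, clones_per_sample = clones_per_sample,
         n_lines = n_lines,
         sample_generations = sample_generations %||% generations,
         fitness = fitness, seed = seed),
    class = "sim_config"
  )
}

#' Bottleneck and Wright-Fisher drift of a haplotype pool
#'
#' The founding population is a multinomial sample of size
#' `bottleneck_size` from the donor frequencies; each subsequent generation
#' is a multinomial sample of size `effective_size` from the previous
#' generation's (optionally fitness-weighted) frequencies. Loss and
#' fixation are absorbing. A per-generation transmission failure
#' (probability 1 - t) extinguishes the lineage's symbionts unless the
#' configuration conditions on retention, in which case failures are
#' counted but ignored.
#'
#' @param pool a [make_pool()] result.
#' @param config a [sim_config()]; its `seed` is NOT applied here so that
#'   callers control the stream (apply `set.seed()` yourself or use
#'   [simulate_study()]).
#' @return list with `trajectory` (matrix `(generations + 1) x haplotypes`
#'   of frequencies; row 1 is the founding bottleneck sample), `counts`
#'   (same shape, absolute counts), `lost` (logical: all symbionts lost),
#'   `n_transmission_failures`.
#' @export
bottleneck_and_drift <- function(pool, config) {
  stopifnot(inherits(pool, "haplotype_pool"), inherits(config, "sim_config"))
  k <- length(pool$frequencies)
  fitness <- config$fitness %||% rep(1, k)
  stopifnot(length(fitness) == k, all(fitness >= 0))
  counts <- matrix(0L, nrow = config$generations + 1L, ncol = k,
                   dimnames = list(NULL, names(pool$frequencies)))
  counts[1L, ] <- as.integer(rmultinom(1L, config$bottleneck_size,
                                       pool$frequencies))
  n_fail <- 0L
  lost <- FALSE
  for (g in seq_len(config$generations)) {
    t_g <- if (g <= config$transmission_switch_gen) {
      config$transmission_initial
    } else {
      config$transmission_late
    }
    prev <- counts[g, ]
    if (sum(prev) == 0L) {
      counts[g + 1L, ] <- 0L
      next
    }
    if (runif(1L) > t_g) {
      n_fail <- n_fail + 1L
      if (!config$condition_on_retention) {
        counts[g + 1L, ] <- 0L
        lost <- TRUE
        next
      }
    }
    w <- prev * fitness
    counts[g + 1L, ] <- as.integer(rmultinom(1L, config$effective_size,
                                             w / sum(w)))
  }
  traj <- counts / pmax(rowSums(counts), 1L)
  traj[rowSums(counts) == 0L, ] <- 0
  list(trajectory = traj, counts = counts,
       lost = lost || sum(counts[config$generations + 1L, ]) == 0L,
       n_transmission_failures = n_fail)
}

#' Re-sequence a pool state as clone reads with polymerase error
#'
#' Each clone draws a haplotype proportionally to the current frequencies,
#' then i.i.d. per-base errors are injected (uniform over the 3 alternate
#' bases). The ledger records each clone's true haplotype and error
#' positions, so downstream estimates can be checked exactly.
#'
#' @param pool a [make_pool()] result (provides the sequences).
#' @param frequencies current haplotype frequencies (default: the pool's).
#' @param n_clones number of clone reads.
#' @param error_rate per-base error probability.
#' @param clone_prefix prefix for clone ids.
#' @param line,generation metadata fields for the emitted clones.
#' @return list with `amplicons` (an [amplicon_set()] whose consensus is
#'   the pool's canonical sequence) and `ledger` (data frame per clone:
#'   `clone_id`, `haplotype`, `n_errors`, `error_positions` as
#'   comma-string).
#' @export
sequence_clones <- function(pool, frequencies = NULL, n_clones,
                            error_rate = 1.5e-4, clone_prefix = "sim",
                            line = "simline", generation = NA_integer_) {
  stopifnot(inherits(pool, "haplotype_pool"), n_clones >= 1L)
  freqs <- frequencies %||% pool$frequencies
  stopifnot(length(freqs) == length(pool$haplotypes), all(freqs >= 0),
            sum(freqs) > 0)
  freqs <- freqs / sum(freqs)
  len <- nchar(pool$consensus)
  ids <- sprintf("%s_c%03d", clone_prefix, seq_len(n_clones))
  hap_idx <- sample.int(length(freqs), n_clones, replace = TRUE,
                        prob = freqs)
  reads <- character(n_clones)
  err_n <- integer(n_clones)
  err_pos <- character(n_clones)
  for (i in seq_len(n_clones)) {
    s <- strsplit(pool$haplotypes[[hap_idx[i]]], "")[[1L]]
    hits <- which(runif(len) < error_rate)
    for (p in hits) s[p] <- sample(setdiff(ACGT, s[p]), 1L)
    reads[i] <- paste(s, collapse = "")
    err_n[i] <- length(hits)
    err_pos[i] <- paste(hits, collapse = ",")
  }
  meta <- data.frame(clone_id = ids, line = line,
                     host_species = "simulated",
                     generation = as.integer(generation), gene = pool$gene,
                     strain_label = pool$strain, stringsAsFactors = FALSE)
  ledger <- data.frame(clone_id = ids,
                       haplotype = names(pool$haplotypes)[hap_idx],
                       n_errors = err_n, error_positions = err_pos,
                       stringsAsFactors = FALSE)
  list(
    amplicons = amplicon_set(pool$gene, pool$consensus,
                             setNames(reads, ids), len, meta = meta),
    ledger = ledger
  )
}

# Planted prevalence time course for a switch line: the major strain alone
# up to the start of the switch window, the minor strain alone from its
# end; the transition period itself is unobserved (non-consecutive
# sampling), so locate_switch() recovers exactly the planted window.
.switch_series <- function(generations_observed, window,
                           from_strain = "wCer2", to_strain = "wCer1") {
  generations_observed <- generations_observed[
    generations_observed <= window[1L] | generations_observed >= window[2L]]
  sets <- lapply(generations_observed, function(g) {
    if (g <= window[1L]) from_strain else to_strain
  })
  data.frame(generation = generations_observed,
             strains = I(sets))
}

#' Simulate a complete transfer study
#'
#' End-to-end synthetic data set: a donor haplotype pool per strain, donor
#' clone samples, `n_lines` recipient lines each founded through an
#' independent bottleneck and drifted for `generations`, clone re-sequencing
#' at the configured sampling generations, and (optionally) a planted
#' strain-prevalence switch line with its observation time course. The
#' ground-truth ledger fully determines the expected pipeline outputs;
#' identical seeds give identical outputs.
#'
#' @param config a [sim_config()].
#' @param pool optional donor [make_pool()] (default: a 5-haplotype wCer2
#'   gatB pool with 10 variant sites, canonical haplotype at 0.95-ish
#'   Dirichlet-free frequencies: canonical 0.92, four rare at 0.02).
#' @param switch_window optional numeric `c(g_last_major, g_first_minor)`;
#'   when given, a switch line observation series over seven non-consecutive
#'   generations is planted, emulating a major-to-minor prevalence
#'   replacement.
#' @return list of class `sim_output` with `donor` (clones + ledger),
#'   `lines` (per line: `drift`, `samples` per sampled generation),
#'   `meta` (combined metadata), `switch_series` (or NULL), `config`,
#'   `pool`.
#' @export
simulate_study <- function(config = sim_config(), pool = NULL,
                           switch_window = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (is.null(pool)) {
    pool <- make_pool(5L, 10L, freq_spec = c(0.92, 0.02, 0.02, 0.02, 0.02),
                      gene = "gatB", seed = config$seed)
  }
  donor <- sequence_clones(pool, n_clones = config$clones_per_sample,
                           error_rate = config$error_rate,
                           clone_prefix = "donor", line = "donor",
                           generation = 0L)
  lines <- list()
  for (l in seq_len(config$n_lines)) {
    ln <- sprintf("SL%02d", l)
    drift <- bottleneck_and_drift(pool, config)
    samples <- list()
    for (g in config$sample_generations) {
      stopifnot(g >= 1L, g <= config$generations)
      samples[[as.character(g)]] <- sequence_clones(
        pool, frequencies = drift$trajectory[g + 1L, ],
        n_clones = config$clones_per_sample,
        error_rate = config$error_rate,
        clone_prefix = sprintf("%s_g%03d", ln, g), line = ln,
        generation = g
      )
    }
    lines[[ln]] <- list(drift = drift, samples = samples)
  }
  switch_series <- NULL
  if (!is.null(switch_window)) {
    stopifnot(length(switch_window) == 2L,
              switch_window[1L] < switch_window[2L])
    obs <- sort(unique(c(
      round(seq(max(1, switch_window[1L] - 10), switch_window[1L],
                length.out = 5)),
      switch_window[2L], switch_window[2L] + 1
    )))
    switch_series <- .switch_series(obs, switch_window)
  }
  meta <- do.call(rbind, c(
    list(attr(donor$amplicons, "meta")),
    lapply(lines, function(li) {
      do.call(rbind, lapply(li$samples,
                            function(s) attr(s$amplicons, "meta")))
    })
  ))
  rownames(meta) <- NULL
  structure(list(donor = donor, lines = lines, meta = meta,
                 switch_series = switch_series, config = config,
                 pool = pool),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat("<sim_output>", length(x$lines), "recipient line(s),",
      nrow(x$meta), "clones total\n")
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Emits one FASTA per sampled amplicon set, a combined metadata TSV, and a
#' JSON ground-truth ledger.
#'
#' @param sim a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_output <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_output"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("write_sim_output() needs the jsonlite package", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_amplicon_fasta(sim$donor$amplicons, file.path(dir, "donor.fasta"))
  ledgers <- list(donor = sim$donor$ledger)
  for (ln in names(sim$lines)) {
    for (g in names(sim$lines[[ln]]$samples)) {
      s <- sim$lines[[ln]]$samples[[g]]
      write_amplicon_fasta(s$amplicons,
                           file.path(dir, sprintf("%s_g%s.fasta", ln, g)))
      ledgers[[sprintf("%s_g%s", ln, g)]] <- s$ledger
    }
    ledgers[[paste0(ln, "_trajectory")]] <-
      as.data.frame(sim$lines[[ln]]$drift$trajectory)
  }
  write.table(sim$meta, file.path(dir, "meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(ledgers, file.path(dir, "ledger.json"),
                       dataframe = "columns", digits = NA)
  invisible(dir)
}
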