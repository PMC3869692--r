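# Polymerase/cloning error baseline estimated from control re-sequencing of
# known fragments. Errors are modelled as independent per-base events
# (binomial), which is also the model the simulator injects.

#' Construct a control re-sequencing set
#'
#' One control set records the outcome of re-PCR and re-sequencing a known
#' fragment: how many clones, their fragment length, and how many erroneous
#' substitutions were observed in total.
#'
#' @param gene locus name.
#' @param n_clones number of control clones sequenced.
#' @param length_bp clone fragment length (bp).
#' @param n_errors total erroneous substitutions observed across clones.
#' @return data frame row of class-free control data (columns `gene`,
#'   `n_clones`, `length_bp`, `n_errors`).
#' @export
control_set <- function(gene, n_clones, length_bp, n_errors) {
  assert_gene(gene)
  stopifnot(n_clones >= 1L, length_bp >= 1L, n_errors >= 0L)
  if (n_errors > n_clones * length_bp) {
    stop("n_errors exceeds total sequenced bases", call. = FALSE)
  }
  data.frame(gene = gene, n_clones = as.integer(n_clones),
             length_bp = as.integer(length_bp),
             n_errors = as.integer(n_errors), stringsAsFactors = FALSE)
}

#' Pooled polymerase error rate from control sets
#'
#' Pools errors and bases over all control sets and returns the per-kb error
#' rate: `1000 * sum(errors) / sum(n_clones * length_bp)`. Pooling is
#' exchangeable — the estimate depends only on the totals. On the published
#' control counts (0 errors in 10x444 bp of coxA, 0 in 10x290 bp of ftsZ,
#' 2 in 14x429 bp of gatB) this gives 0.15 SNPs/kb.
#'
#' @param controls data frame with columns `gene`, `n_clones`, `length_bp`,
#'   `n_errors` (rows may come from [control_set()] or
#'   `load_fixtures("taq_controls")`).
#' @return object of class `error_baseline`: list with `rate_per_kb` (raw),
#'   `rate_display` (half-up, 2 decimals), `n_errors`, `n_bases`, `source`.
#' @export
#' @examples
#' pooled_error_rate(load_fixtures("taq_controls"))$rate_display # 0.15
pooled_error_rate <- function(controls) {
  needed <- c("n_clones", "length_bp", "n_errors")
  if (!all(needed %in% names(controls))) {
    stop("controls need columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  n_bases <- sum(as.numeric(controls$n_clones) * controls$length_bp)
  if (n_bases <= 0) stop("zero total bases in controls", call. = FALSE)
  n_err <- sum(controls$n_errors)
  rate <- 1000 * n_err / n_bases
  structure(
    list(rate_per_kb = rate, rate_display = round_half_up(rate, 2),
         n_errors = n_err, n_bases = n_bases, source = "estimated"),
    class = "error_baseline"
  )
}

#' @export
print.error_baseline <- function(x, ...) {
  cat("<error_baseline>", x$rate_display, "SNPs/kb (", x$n_errors,
      "errors in", x$n_bases, "bases;", x$source, ")\n")
  invisible(x)
}

# Baselines quoted by the source study rather than estimated here: the
# published mean for non-proof-reading Taq (0.21/kb) and the constant used
# for the corrected frequency columns (0.28/kb).
#' Reference error baselines
#'
#' `published_taq_baseline()` returns the literature mean error rate for
#' standard non-proof-reading Taq polymerases (0.21 SNPs/kb);
#' `table2_baseline()` returns the 0.28 SNPs/kb constant used to produce
#' baseline-corrected frequency columns. The two coexist deliberately: the
#' frequency correction takes its baseline as an explicit argument,
#' defaulting to 0.28 (see [corrected_frequency()]).
#'
#' @return an `error_baseline` object with the quoted constant.
#' @export
published_taq_baseline <- function() {
  structure(list(rate_per_kb = 0.21, rate_display = 0.21, n_errors = NA,
                 n_bases = NA, source = "published(0.21)"),
            class = "error_baseline")
}

#' @rdname published_taq_baseline
#' @export
table2_baseline <- function() {
  structure(list(rate_per_kb = 0.28, rate_display = 0.28, n_errors = NA,
                 n_bases = NA, source = "table2_footnote(0.28)"),
            class = "error_baseline")
}

#' Exact binomial confidence interval on the error rate
#'
#' Clopper-Pearson interval on the per-base error probability from the pooled
#' control counts, scaled to SNPs/kb. The lower bound is 0 when no errors
#' were observed.
#'
#' @param controls control sets as for [pooled_error_rate()].
#' @param level confidence level in (0, 1); default 0.95.
#' @return named numeric vector `c(lower, upper)` in SNPs/kb.
#' @export
error_ci <- function(controls, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("level must be in (0, 1)", call. = FALSE)
  }
  est <- pooled_error_rate(controls)
  x <- est$n_errors
  n <- est$n_bases
  alpha <- 1 - level
  lower <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = 1000 * lower, upper = 1000 * upper)
}
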