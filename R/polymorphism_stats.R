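# Per-group SNP frequencies, baseline correction and 2x2 contingency tests.
# Contingency tables count bases: SNP occurrences vs non-variant bases —
# the construction that reproduces the published P values.

#' Per-kilobase SNP frequency of a group
#'
#' @param n number of SNP occurrences in the group (integer >= 0).
#' @param L number of sequenced bases (> 0).
#' @param group_label optional label.
#' @return object of class `frequency_record`: list with `group_label`,
#'   `n_snp_occurrences`, `n_bases`, `rate_per_kb` (raw) and `rate_display`
#'   (half-up to 2 decimals).
#' @export
#' @examples
#' snp_frequency(9, 8888)$rate_display # 1.01
snp_frequency <- function(n, L, group_label = NA_character_) {
  if (!is.numeric(L) || L <= 0) stop("L must be > 0", call. = FALSE)
  if (!is.numeric(n) || n < 0) stop("n must be >= 0", call. = FALSE)
  rate <- 1000 * n / L
  structure(
    list(group_label = group_label, n_snp_occurrences = as.integer(n),
         n_bases = as.integer(L), rate_per_kb = rate,
         rate_display = round_half_up(rate, 2)),
    class = "frequency_record"
  )
}

#' @export
print.frequency_record <- function(x, ...) {
  cat("<frequency_record>", x$group_label %||% "", x$n_snp_occurrences,
      "SNPs in", x$n_bases, "bases =", x$rate_display, "/kb\n")
  invisible(x)
}

#' Baseline-corrected frequency
#'
#' Subtracts the polymerase error baseline from a per-kb rate. The result is
#' deliberately unclamped: a group whose observed rate is below the baseline
#' gets a negative corrected value (e.g. 0.00 - 0.28 = -0.28).
#'
#' @param rate per-kb SNP frequency (raw or displayed).
#' @param baseline error baseline in SNPs/kb (>= 0); default 0.28, the
#'   constant behind the published corrected columns (see
#'   [table2_baseline()]).
#' @return corrected per-kb rate.
#' @export
corrected_frequency <- function(rate, baseline = 0.28) {
  if (inherits(baseline, "error_baseline")) baseline <- baseline$rate_per_kb
  if (baseline < 0) stop("baseline must be >= 0", call. = FALSE)
  rate - baseline
}

#' Fold change of a rate over the error baseline
#'
#' @param rate per-kb SNP frequency.
#' @param baseline error baseline in SNPs/kb (> 0).
#' @return `rate / baseline`.
#' @export
fold_over_baseline <- function(rate, baseline) {
  if (inherits(baseline, "error_baseline")) baseline <- baseline$rate_per_kb
  if (baseline <= 0) stop("baseline must be > 0", call. = FALSE)
  rate / baseline
}

.as_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (any(m < 0) || any(m != round(m))) {
    stop("table must hold non-negative integers", call. = FALSE)
  }
  storage.mode(m) <- "double"
  m
}

contingency_result <- function(table, statistic, p, method) {
  structure(
    list(table = table, statistic = statistic,
         p_two_tailed = min(max(p, 0), 1), method = method),
    class = "contingency_result"
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("<contingency_result>", x$method, "p =", format(x$p_two_tailed), "\n")
  invisible(x)
}

#' Chi-squared test with Yates continuity correction
#'
#' Classic 2x2 chi-squared with the Yates correction: the statistic is
#' `sum((|O - E| - 0.5)^2 / E)`, with the continuity term floored at zero
#' when `|O - E| < 0.5`; the P value is the upper tail of chi-squared with
#' 1 df (two-tailed by construction). A zero row or column margin yields
#' p = 1 with a warning.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return a `contingency_result` (`statistic`, `p_two_tailed`, `method`).
#' @export
chi2_yates <- function(table) {
  m <- .as_2x2(table)
  if (sum(m) == 0 || any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warning("zero margin: chi-squared undefined, returning p = 1")
    return(contingency_result(m, 0, 1, "chi2_yates"))
  }
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  dev <- pmax(abs(m - E) - 0.5, 0)
  stat <- sum(dev^2 / E)
  contingency_result(m, stat, pchisq(stat, df = 1, lower.tail = FALSE),
                     "chi2_yates")
}

#' Fisher's exact test (two-tailed) for a 2x2 table
#'
#' Exact two-tailed P value by full enumeration of the hypergeometric
#' support with fixed margins: the probabilities of all tables no more
#' probable than the observed one (with a 1e-7 relative slack for ties) are
#' summed.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return a `contingency_result`.
#' @export
fisher_exact <- function(table) {
  m <- .as_2x2(table)
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  if (n == 0) return(contingency_result(m, NA_real_, 1, "fisher_exact"))
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(m[1, 1], c1, n - c1, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  contingency_result(m, p_obs, p, "fisher_exact")
}

# Exact conditional test for an r x c table: enumerates every table with the
# observed margins, accumulating the probability of tables no more probable
# than the observed one. Probability under fixed margins is
# prod(row!)*prod(col!)/(N! * prod(cell!)). Feasible for the small ovary
# tables this package meets (2 x 4 at ~40 per row).
fisher_exact_rxc <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0) || any(m != round(m))) {
    stop("table must hold non-negative integers", call. = FALSE)
  }
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  if (n == 0) return(contingency_result(m, NA_real_, 1, "fisher_exact"))
  log_const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1)
  tab_logp <- function(x) log_const - sum(lgamma(x + 1))
  logp_obs <- tab_logp(m)
  nr <- nrow(m); nc <- ncol(m)
  total <- 0
  # Fill rows recursively; the final row is forced by the column margins.
  recurse <- function(rows_done, col_left) {
    if (nrow(rows_done) == nr - 1L) {
      if (any(col_left < 0)) return(invisible(NULL))
      x <- rbind(rows_done, col_left)
      lp <- tab_logp(x)
      if (lp <= logp_obs + log(1 + 1e-7)) total <<- total + exp(lp)
      return(invisible(NULL))
    }
    target <- rs[nrow(rows_done) + 1L]
    cells <- function(ci, row_acc) {
      filled <- sum(row_acc)
      if (ci == nc) {
        last <- target - filled
        if (last >= 0 && last <= col_left[nc]) {
          row <- c(row_acc, last)
          recurse(rbind(rows_done, row), col_left - row)
        }
        return(invisible(NULL))
      }
      upper <- min(col_left[ci], target - filled)
      if (upper < 0) return(invisible(NULL))
      for (v in 0:upper) cells(ci + 1L, c(row_acc, v))
    }
    cells(1L, numeric(0))
  }
  recurse(m[0, , drop = FALSE], cs)
  contingency_result(m, exp(logp_obs), total, "fisher_exact")
}

#' Compare the SNP frequencies of two groups
#'
#' Builds the base-count contingency table
#' `rbind(c(n_A, L_A - n_A), c(n_B, L_B - n_B))` and applies the chosen
#' test. Symmetric in its arguments.
#'
#' @param recA,recB [snp_frequency()] records.
#' @param method `"chi2_yates"` (default) or `"fisher_exact"`.
#' @return a `contingency_result`.
#' @export
#' @examples
#' a <- snp_frequency(5, 9696, "wCer1 of R. cerasi")
#' b <- snp_frequency(9, 8888, "wCer2 of R. cerasi")
#' compare_groups(a, b)$p_two_tailed # ~0.334
compare_groups <- function(recA, recB,
                           method = c("chi2_yates", "fisher_exact")) {
  stopifnot(inherits(recA, "frequency_record"),
            inherits(recB, "frequency_record"))
  method <- match.arg(method)
  tab <- rbind(c(recA$n_snp_occurrences, recA$n_bases - recA$n_snp_occurrences),
               c(recB$n_snp_occurrences, recB$n_bases - recB$n_snp_occurrences))
  rownames(tab) <- c(recA$group_label, recB$group_label)
  switch(method, chi2_yates = chi2_yates(tab), fisher_exact = fisher_exact(tab))
}

#' Infer an integer SNP count from a printed per-kb rate
#'
#' Published tables print rounded per-kb rates but not the underlying
#' occurrence counts. This inverts the rounding: the unique integer `n` with
#' `round(1000 * n / L, 2)` equal to the printed rate. No unique `n` is a
#' hard error rather than a guess.
#'
#' @param rate_display printed per-kb rate (2 decimals).
#' @param L sequenced bases.
#' @param n_max upper bound of the search (default `ceiling(L/100)`, far
#'   above any plausible clone-library SNP count).
#' @return the integer count.
#' @export
infer_count_from_rate <- function(rate_display, L, n_max = ceiling(L / 100)) {
  cand <- 0:n_max
  hit <- cand[round_half_up(1000 * cand / L, 2) == rate_display]
  if (length(hit) != 1L) {
    stop("no unique integer count reproduces ", rate_display, "/kb on ", L,
         " bases (candidates: ", paste(hit, collapse = ", "), ")",
         call. = FALSE)
  }
  hit
}

#' Per-line frequency table from variant calls
#'
#' Counts SNP occurrences per line from a call set, divides by the bases
#' sequenced per line, and appends the baseline-corrected column.
#'
#' @param calls data frame from [call_snps()].
#' @param bases_by_line named vector of sequenced bases per line (e.g.
#'   clones x fragment length).
#' @param baseline per-kb error baseline for the corrected column
#'   (default 0.28).
#' @return data frame with one row per line: `line`, `n_snp_occurrences`,
#'   `n_bases`, `rate_per_kb`, `rate_display`, `corrected_display`.
#' @export
snp_frequency_table <- function(calls, bases_by_line, baseline = 0.28) {
  lines <- names(bases_by_line)
  if (is.null(lines)) stop("bases_by_line must be named by line", call. = FALSE)
  rows <- lapply(lines, function(ln) {
    n <- sum(calls$line == ln, na.rm = TRUE)
    rec <- snp_frequency(n, bases_by_line[[ln]], ln)
    data.frame(line = ln, n_snp_occurrences = rec$n_snp_occurrences,
               n_bases = rec$n_bases, rate_per_kb = rec$rate_per_kb,
               rate_display = rec$rate_display,
               corrected_display = round_half_up(
                 corrected_frequency(rec$rate_per_kb, baseline), 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Flag disagreements between recomputed and printed frequencies
#'
#' The published variant matrix and frequency table are not perfectly
#' consistent with each other (e.g. one line shows a variant but prints a
#' rate of 0.00/kb). This reports, per line, the recomputed and printed
#' displayed rates and whether they differ; the pipeline reports what it
#' counts and flags such fixture inconsistencies rather than resolving them.
#'
#' @param freq_table output of [snp_frequency_table()].
#' @param printed data frame with columns `group` (or `line`) and
#'   `rate_per_kb` of printed values, e.g. `load_fixtures("table2_gatB")`.
#' @return `freq_table` with appended `printed_display` and `consistent`.
#' @export
table2_discrepancies <- function(freq_table, printed) {
  key <- if ("group" %in% names(printed)) printed$group else printed$line
  idx <- match(freq_table$line, key)
  freq_table$printed_display <- printed$rate_per_kb[idx]
  freq_table$consistent <- !is.na(freq_table$printed_display) &
    freq_table$rate_display == freq_table$printed_display
  for (i in which(!freq_table$consistent)) {
    sp_log("info", "line ", freq_table$line[i], ": recomputed ",
           freq_table$rate_display[i], "/kb vs printed ",
           freq_table$printed_display[i], "/kb")
  }
  freq_table
}
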