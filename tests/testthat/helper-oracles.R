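# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: translation uses a local codon table and path
# enumeration is a plain recursive search.

oracle_aa <- local({
  tab <- Biostrings::GENETIC_CODE
  function(codon) unname(tab[codon])
})

# Exhaustive NG86 path oracle: enumerate all orderings of differing codon
# positions, drop paths through intermediate stop codons when a stop-free
# path exists, and average syn/nonsyn step counts.
oracle_path_counts <- function(c1, c2) {
  b1 <- strsplit(c1, "")[[1]]
  b2 <- strsplit(c2, "")[[1]]
  d <- which(b1 != b2)
  if (!length(d)) return(c(sd = 0, nd = 0))
  orders <- if (length(d) == 1) {
    list(d)
  } else {
    # all permutations by brute force
    res <- list()
    gen <- function(prefix, rest) {
      if (!length(rest)) {
        res[[length(res) + 1]] <<- prefix
        return(invisible(NULL))
      }
      for (i in seq_along(rest)) gen(c(prefix, rest[i]), rest[-i])
    }
    gen(integer(0), d)
    res
  }
  paths <- lapply(orders, function(ord) {
    cur <- b1
    sd <- 0; nd <- 0; stopped <- FALSE
    for (k in seq_along(ord)) {
      nxt <- cur
      nxt[ord[k]] <- b2[ord[k]]
      aa1 <- oracle_aa(paste(cur, collapse = ""))
      aa2 <- oracle_aa(paste(nxt, collapse = ""))
      if (aa2 == "*" && k < length(ord)) stopped <- TRUE
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, stopped = stopped)
  })
  ok <- !vapply(paths, `[[`, logical(1), "stopped")
  if (!any(ok)) ok <- rep(TRUE, length(paths))
  c(sd = mean(vapply(paths[ok], `[[`, numeric(1), "sd")),
    nd = mean(vapply(paths[ok], `[[`, numeric(1), "nd")))
}

# Two-tailed Fisher P for a 2x2 table by direct hypergeometric enumeration.
oracle_fisher_2x2 <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  supp <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- dhyper(supp, c1, n - c1, r1)
  sum(pr[pr <= dhyper(m[1, 1], c1, n - c1, r1) * (1 + 1e-7)])
}

# Random small amplicon set with known injected variants (no ambiguity
# codes): returns the set plus the exact expected call table.
random_amplicons_with_truth <- function(n_reads = 6, len = 60, n_vars = 8,
                                        seed = 1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  cons <- paste(sample(bases, len, replace = TRUE), collapse = "")
  reads <- character(n_reads)
  truth <- NULL
  for (i in seq_len(n_reads)) {
    s <- strsplit(cons, "")[[1]]
    pos <- sort(sample.int(len, sample(0:n_vars, 1)))
    for (p in pos) {
      alt <- sample(setdiff(bases, s[p]), 1)
      truth <- rbind(truth, data.frame(
        clone_id = sprintf("r%02d", i), position = p, ref = s[p], alt = alt,
        stringsAsFactors = FALSE
      ))
      s[p] <- alt
    }
    reads[i] <- paste(s, collapse = "")
  }
  names(reads) <- sprintf("r%02d", seq_len(n_reads))
  list(amplicons = amplicon_set("wsp", cons, reads, len), truth = truth)
}
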