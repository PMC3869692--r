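test_that("codon mapping follows the offset-0 frame of the fragments", {
  expect_identical(map_codon(11)$codon_index, 4L)
  expect_identical(map_codon(11)$codon_pos, 2L)
  expect_identical(map_codon(3)$codon_index, 1L)
  expect_identical(map_codon(3)$codon_pos, 3L)
  expect_identical(map_codon(1)$codon_index, 1L)
  expect_identical(map_codon(1)$codon_pos, 1L)
  # published stop positions land on first codon positions
  expect_identical(map_codon(226)$codon_pos, 1L)
  expect_identical(map_codon(253)$codon_pos, 1L)
  expect_identical(map_codon(226)$codon_index, 76L)
  expect_identical(map_codon(253)$codon_index, 85L)
  # trailing incomplete codon of the 404-bp fragment is flagged
  mc <- map_codon(c(402, 403, 404), fragment_length = 404)
  expect_identical(mc$complete, c(TRUE, FALSE, FALSE))
  expect_error(map_codon(1, frame_offset = 1), "exceed")
})

test_that("substitutions classify by the genetic code with named stops", {
  ochre <- classify_substitution("CAA", "TAA")
  expect_identical(ochre$effect, "nonsense")
  expect_identical(ochre$stop_class, "ochre")
  opal <- classify_substitution("GGA", "TGA")
  expect_identical(opal$effect, "nonsense")
  expect_identical(opal$stop_class, "opal")
  amber <- classify_substitution("TGG", "TAG")
  expect_identical(amber$stop_class, "amber")
  syn <- classify_substitution("GCT", "GCC")
  expect_identical(syn$effect, "synonymous")
  expect_identical(syn$stop_class, "none")
  non <- classify_substitution("GAA", "GGA")
  expect_identical(non$effect, "nonsynonymous")
  expect_identical(c(non$ref_aa, non$alt_aa), c("E", "G"))
  expect_error(classify_substitution("AAA", "AAA"), "identical")
})

test_that("stop scan recovers exactly the published stop records", {
  stops3 <- load_fixtures("table3_stops")

  g <- scan_premature_stops(load_fixtures("gatB_table1"))
  expect_identical(nrow(g), 3L)
  expect_setequal(g$position, c(226L, 253L, 253L))
  expect_true(all(g$stop_class == "ochre"))
  expect_setequal(g$line, stops3$line[stops3$gene == "gatB"])

  f <- scan_premature_stops(load_fixtures("ftsZ_table3"))
  expect_identical(nrow(f), 4L)
  expect_true(all(f$stop_class == "opal"))
  expect_true(all(f$position == 25L))
  expect_setequal(f$clone_id, c("F37", "F38", "F40", "F42"))

  cx <- scan_premature_stops(load_fixtures("coxA_table3"))
  expect_identical(nrow(cx), 1L)
  expect_identical(cx$stop_class, "ochre")
  expect_identical(cx$position, 22L)

  # a consensus-identical clone contributes nothing
  amp <- load_fixtures("ftsZ_table3")
  clean <- amplicon_set("ftsZ", amp$consensus, c(w = amp$consensus))
  expect_identical(nrow(scan_premature_stops(clean)), 0L)
})

test_that("NG86 site counts always sum to 3 per codon", {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste,
                  collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  for (cod in sample(codons, 12)) {
    s <- symbiopoly:::.codon_syn_sites(cod)
    expect_gte(s, 0)
    expect_lte(s, 3)
  }
  # per-pair totals: S + N = 3 * codons compared
  r <- ng86_dnds("GCTAAATTT", "GCCAAGTTA")
  expect_equal(r$S_sites + r$N_sites, 3 * r$n_codons_compared,
               tolerance = 1e-9)
})

test_that("NG86 path counting matches the exhaustive oracle", {
  # identical sequences
  r0 <- ng86_dnds("GCTGCT", "GCTGCT")
  expect_equal(r0$Sd + r0$Nd, 0)
  expect_false(r0$dnds_defined)

  # single synonymous difference
  r1 <- ng86_dnds("GCT", "GCC")
  expect_equal(r1$Sd, 1)
  expect_equal(r1$Nd, 0)

  # two-hit codon: average over enumerated paths
  r2 <- ng86_dnds("TTT", "GTA")
  want <- oracle_path_counts("TTT", "GTA")
  expect_equal(r2$Sd, want[["sd"]], tolerance = 1e-9)
  expect_equal(r2$Nd, want[["nd"]], tolerance = 1e-9)

  # random codon pairs: Sd + Nd equals the nucleotide differences and the
  # path averages agree with the oracle
  set.seed(77)
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste,
                  collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  for (i in 1:20) {
    pair <- sample(sense, 2)
    nd <- sum(strsplit(pair[1], "")[[1]] != strsplit(pair[2], "")[[1]])
    if (nd == 0) next
    got <- suppressWarnings(symbiopoly:::.codon_path_counts(pair[1], pair[2]))
    want <- oracle_path_counts(pair[1], pair[2])
    expect_equal(got[["sd"]], want[["sd"]], tolerance = 1e-9)
    expect_equal(got[["nd"]], want[["nd"]], tolerance = 1e-9)
    expect_equal(got[["sd"]] + got[["nd"]], nd, tolerance = 1e-9)
  }
})

test_that("Jukes-Cantor correction is monotone and dS=0 flags the ratio", {
  p <- seq(0, 0.74, by = 0.02)
  d <- -0.75 * log(1 - 4 * p / 3)
  expect_true(all(diff(d) > 0))

  # nonsynonymous-only divergence: ratio undefined
  r <- ng86_dnds("AAA", "GAA") # K -> E, nonsynonymous
  expect_equal(r$Sd, 0)
  expect_false(r$dnds_defined)
  expect_true(is.na(r$dnds))

  expect_error(ng86_dnds("AAA", "AAAA"), "equal length")
})

test_that("ambiguous codons are skipped pairwise", {
  r <- ng86_dnds("GCTNAA", "GCCAAA")
  expect_identical(r$n_codons_compared, 1L)
  expect_equal(r$Sd, 1)
})

test_that("clone-vs-consensus aggregation drops undefined ratios", {
  amp <- load_fixtures("gatB_table1")
  res <- dnds_vs_consensus(amp)
  expect_identical(nrow(res$per_clone), length(amp$reads))
  defined <- res$per_clone$dnds[!is.na(res$per_clone$dnds)]
  if (length(defined)) {
    expect_equal(res$mean_dnds, mean(defined))
  } else {
    expect_true(is.na(res$mean_dnds))
  }
})
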