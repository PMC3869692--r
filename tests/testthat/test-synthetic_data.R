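test_that("haplotype pools encode their stated structure", {
  p1 <- make_pool(1, 0, gene = "gatB", seed = 4)
  expect_identical(p1$haplotypes[[1]], p1$consensus)
  expect_identical(nrow(p1$sites), 0L)

  p2 <- make_pool(2, 1, freq_spec = c(0.9, 0.1), seed = 5)
  expect_equal(unname(p2$frequencies), c(0.9, 0.1))
  expect_identical(nrow(p2$sites), 1L)
  # the biallelic site distinguishes hap2 from the consensus
  s <- p2$sites
  expect_identical(substr(p2$haplotypes[["hap2"]], s$position, s$position),
                   s$alt)

  p5 <- make_pool(5, 10, freq_spec = list(dirichlet = 2), seed = 6)
  expect_equal(sum(p5$frequencies), 1, tolerance = 1e-9)
  expect_identical(nrow(p5$sites), 10L)
  # realized site spectrum matches the ledger exactly
  for (i in seq_len(nrow(p5$sites))) {
    hap <- p5$haplotypes[[p5$sites$haplotype[i]]]
    expect_identical(substr(hap, p5$sites$position[i],
                            p5$sites$position[i]), p5$sites$alt[i])
  }
  expect_error(make_pool(1, 3), "single-haplotype")
  expect_error(make_pool(3, 0), ">= 1 variant site")
  expect_error(make_pool(2, 1, freq_spec = c(0.5, 0.4)), "sum to 1")
})

test_that("drift conserves frequency mass and respects absorbing states", {
  pool <- make_pool(4, 6, freq_spec = c(0.7, 0.1, 0.1, 0.1), seed = 8)
  cfg <- sim_config(bottleneck_size = 50, generations = 30,
                    effective_size = 200, seed = 1)
  set.seed(1)
  res <- bottleneck_and_drift(pool, cfg)
  expect_identical(dim(res$trajectory), c(31L, 4L))
  live <- rowSums(res$counts) > 0
  expect_true(all(abs(rowSums(res$trajectory[live, , drop = FALSE]) - 1)
                  < 1e-9))
  # lost haplotypes never return
  for (h in 1:4) {
    z <- which(res$counts[, h] == 0)
    if (length(z)) expect_true(all(res$counts[z[1]:31, h] == 0))
  }
  # single-haplotype pool: constant trajectory
  p1 <- make_pool(1, 0, seed = 2)
  set.seed(3)
  r1 <- bottleneck_and_drift(p1, cfg)
  expect_true(all(r1$trajectory[, 1] == 1))
})

test_that("large populations barely drift (law of large numbers)", {
  pool <- make_pool(3, 4, freq_spec = c(0.5, 0.3, 0.2), seed = 10)
  cfg <- sim_config(bottleneck_size = 1e6, generations = 5,
                    effective_size = 1e6,
                    transmission_initial = 1, transmission_late = 1)
  set.seed(11)
  res <- bottleneck_and_drift(pool, cfg)
  final <- res$trajectory[6, ]
  expect_true(all(abs(final - c(0.5, 0.3, 0.2)) < 0.01))
})

test_that("founding loss of a minor strain matches the closed form", {
  # minor haplotype at 0.02, bottleneck 20: loss-by-founding prob 0.98^20
  pool <- make_pool(2, 1, freq_spec = c(0.98, 0.02), seed = 12)
  cfg <- sim_config(bottleneck_size = 20, generations = 1,
                    effective_size = 100,
                    transmission_initial = 1, transmission_late = 1)
  set.seed(13)
  n_rep <- 500
  lost <- 0L
  for (i in seq_len(n_rep)) {
    res <- bottleneck_and_drift(pool, cfg)
    if (res$counts[1, 2] == 0L) lost <- lost + 1L
  }
  p_closed <- 0.98^20
  se <- sqrt(p_closed * (1 - p_closed) / n_rep)
  expect_lt(abs(lost / n_rep - p_closed), 3 * se)
})

test_that("clone re-sequencing draws haplotypes and errors as stated", {
  pool <- make_pool(2, 1, freq_spec = c(0.5, 0.5), seed = 14)
  set.seed(15)
  out <- sequence_clones(pool, n_clones = 4000, error_rate = 0)
  counts <- table(out$ledger$haplotype)
  se <- sqrt(4000 * 0.25)
  expect_lt(abs(counts[["hap1"]] - 2000), 3 * se)
  expect_true(all(out$ledger$n_errors == 0))

  # error-free single haplotype: clones identical to consensus
  p1 <- make_pool(1, 0, seed = 16)
  set.seed(17)
  o1 <- sequence_clones(p1, n_clones = 5, error_rate = 0)
  expect_true(all(o1$amplicons$reads == p1$consensus))

  # injected error rate recovered through the pipeline's own estimator
  set.seed(18)
  n_clones <- 250 # ~1e5 bases of gatB
  o2 <- sequence_clones(p1, n_clones = n_clones, error_rate = 1.5e-4)
  calls <- call_snps(o2$amplicons)
  expect_identical(nrow(calls), sum(o2$ledger$n_errors))
  est <- pooled_error_rate(data.frame(gene = "gatB", n_clones = n_clones,
                                      length_bp = 404,
                                      n_errors = nrow(calls)))
  ci <- error_ci(data.frame(gene = "gatB", n_clones = n_clones,
                            length_bp = 404, n_errors = nrow(calls)))
  expect_true(ci["lower"] <= 0.15 && 0.15 <= ci["upper"])
})

test_that("a fixed seed reproduces the study byte for byte", {
  cfg <- sim_config(generations = 4, n_lines = 2, clones_per_sample = 6,
                    seed = 99)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$donor$amplicons$reads, s2$donor$amplicons$reads)
  expect_identical(s1$donor$ledger, s2$donor$ledger)
  expect_identical(
    s1$lines$SL01$samples[["4"]]$amplicons$reads,
    s2$lines$SL01$samples[["4"]]$amplicons$reads)
  expect_identical(s1$lines$SL02$drift$counts, s2$lines$SL02$drift$counts)
})

test_that("planted switches and recurrent rare haplotypes are recovered", {
  cfg <- sim_config(generations = 4, n_lines = 5, clones_per_sample = 12,
                    seed = 7)
  sim <- simulate_study(cfg, switch_window = c(150, 167))
  sw <- locate_switch(sim$switch_series, "wCer2", "wCer1")
  expect_equal(sw$g_last_from, 150)
  expect_equal(sw$g_first_to_only, 167)

  # a rare donor haplotype surviving the bottleneck in >= 2 lines makes its
  # site recurrent across independently founded systems
  pool <- make_pool(2, 1, freq_spec = c(0.8, 0.2), seed = 20)
  cfg2 <- sim_config(strain_titers = c(wCer2 = 1), bottleneck_size = 200,
                     generations = 2, effective_size = 1000,
                     transmission_initial = 1, transmission_late = 1,
                     error_rate = 0, clones_per_sample = 12, n_lines = 5,
                     seed = 21)
  sim2 <- simulate_study(cfg2, pool = pool)
  calls <- do.call(rbind, lapply(names(sim2$lines), function(ln) {
    call_snps(sim2$lines[[ln]]$samples[["2"]]$amplicons)
  }))
  cls <- classify_recurrence(calls)
  site <- pool$sites
  hit <- cls[cls$position == site$position & cls$alt == site$alt, ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$class, "recurrent")
  expect_gte(length(strsplit(hit$contexts, ",")[[1]]), 2L)
})

test_that("simulated studies round-trip to disk with their ledger", {
  skip_if_not_installed("jsonlite")
  cfg <- sim_config(generations = 2, n_lines = 1, clones_per_sample = 4,
                    seed = 5)
  sim <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_sim_output(sim, dir)
  expect_true(file.exists(file.path(dir, "donor.fasta")))
  expect_true(file.exists(file.path(dir, "meta.tsv")))
  back <- read_amplicon_fasta(file.path(dir, "donor.fasta"), "gatB")
  expect_identical(back$reads, sim$donor$amplicons$reads)
  ledger <- jsonlite::read_json(file.path(dir, "ledger.json"),
                                simplifyVector = TRUE)
  expect_identical(ledger$donor$clone_id, sim$donor$ledger$clone_id)
})
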