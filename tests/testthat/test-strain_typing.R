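test_that("profiles validate their diagnostic sites", {
  sites <- data.frame(position = c(3, 9), wCer1 = c("A", "G"),
                      wCer2 = c("C", "T"))
  p <- diagnostic_profile("wsp", sites = sites)
  expect_s3_class(p, "diagnostic_profile")
  bad <- data.frame(position = 3, wCer1 = "A", wCer2 = "A")
  expect_error(diagnostic_profile("wsp", sites = bad), "discriminate")
  expect_error(diagnostic_profile("wsp"), "sites and/or lengths")
})

test_that("clones type by best matching strain with ties -> unknown", {
  wp <- make_wsp_profile(n_sites = 4, length = 36, seed = 7)
  call1 <- type_clone(wp$references[["wCer1"]], wp$profile)
  expect_identical(call1$strain, "wCer1")
  expect_equal(call1$confidence, 1)
  call2 <- type_clone(wp$references[["wCer2"]], wp$profile)
  expect_identical(call2$strain, "wCer2")

  # a half-and-half chimera ties -> unknown
  sites <- wp$profile$sites
  chim <- strsplit(wp$references[["wCer1"]], "")[[1]]
  swap <- sites$position[1:2]
  chim[swap] <- sites$wCer2[1:2]
  tie <- type_clone(paste(chim, collapse = ""), wp$profile)
  expect_identical(tie$strain, "unknown")

  expect_error(type_clone("ACGT", wp$profile), "shorter")
})

test_that("typing is robust to sequencing error at realistic rates", {
  wp <- make_wsp_profile(n_sites = 4, length = 36, seed = 21)
  set.seed(42)
  n_per_strain <- 100
  correct <- 0L
  for (strain in c("wCer1", "wCer2")) {
    for (i in seq_len(n_per_strain)) {
      read <- strsplit(wp$references[[strain]], "")[[1]]
      err <- which(runif(36) < 0.002)
      for (p in err) read[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                               read[p]), 1)
      if (type_clone(paste(read, collapse = ""),
                     wp$profile)$strain == strain) {
        correct <- correct + 1L
      }
    }
  }
  expect_gte(correct / (2 * n_per_strain), 0.99)
})

test_that("length-polymorphic typing respects the tolerance window", {
  p <- diagnostic_profile("VNTR-141",
                          lengths = c(wCer1 = 420, wCer2 = 561,
                                      wCer4 = 700))
  expect_identical(type_by_length(421, p)$strain, "wCer1")
  expect_identical(type_by_length(561, p)$strain, "wCer2")
  expect_identical(type_by_length(500, p)$strain, "unknown")
  close_p <- diagnostic_profile("VNTR", lengths = c(a = 100, b = 103))
  expect_identical(type_by_length(101.5, close_p)$strain, "unknown")
})

test_that("co-infection status counts supported strains only", {
  expect_identical(
    detect_coinfection(c(rep("wCer1", 3), rep("wCer2", 5)))$status,
    "multiple")
  expect_identical(detect_coinfection(rep("wCer2", 8)),
                   list(status = "single", strains = "wCer2"))
  expect_identical(detect_coinfection(rep("unknown", 4))$status, "none")
  # min_reads filters weakly supported strains
  r <- detect_coinfection(c("wCer1", rep("wCer2", 6)), min_reads = 2)
  expect_identical(r$status, "single")
  expect_identical(r$strains, "wCer2")
  expect_error(detect_coinfection(character(0)), ">= 1")
})

test_that("prevalence switches localize to the observed window", {
  series <- data.frame(
    generation = c(140, 150, 167, 168),
    strains = I(list("wCer2", "wCer2", "wCer1", "wCer1"))
  )
  sw <- locate_switch(series, "wCer2", "wCer1")
  expect_equal(sw$g_last_from, 150)
  expect_equal(sw$g_first_to_only, 167)

  flat <- data.frame(generation = c(1, 5, 9),
                     strains = I(list("wCer2", "wCer2", "wCer2")))
  expect_null(locate_switch(flat, "wCer2", "wCer1"))

  unsorted <- series[c(2, 1, 3, 4), ]
  expect_error(locate_switch(unsorted, "wCer2", "wCer1"), "increasing")

  # comma-string input form
  s2 <- data.frame(generation = c(1, 2, 3),
                   strains = c("wCer2", "wCer1,wCer2", "wCer1"))
  sw2 <- locate_switch(s2, "wCer2", "wCer1")
  expect_equal(unlist(sw2), c(g_last_from = 2, g_first_to_only = 3))
})

test_that("planted random switches are recovered", {
  set.seed(31)
  for (i in 1:5) {
    gens <- sort(sample(100:200, 8))
    cut <- sample(2:6, 1)
    w <- c(gens[cut], gens[cut + 1])
    series <- symbiopoly:::.switch_series(gens, w)
    sw <- locate_switch(series, "wCer2", "wCer1")
    expect_equal(sw$g_last_from, w[1])
    expect_equal(sw$g_first_to_only, w[2])
  }
})

test_that("detection power matches the closed form and is monotone", {
  wp <- make_wsp_profile(n_sites = 4, length = 36, seed = 5)
  expect_equal(detection_power(0, 10, 0, wp, n_reps = 50,
                               seed = 1)$power, 0)
  expect_equal(detection_power(1, 10, 0, wp, n_reps = 50,
                               seed = 1)$power, 1)

  pw <- detection_power(0.05, 12, 0, wp, n_reps = 600, seed = 9)
  closed <- 1 - 0.95^12
  se <- sqrt(closed * (1 - closed) / 600)
  expect_lt(abs(pw$power - closed), 3 * se)

  # monotone in titer (allowing MC noise via a generous margin)
  p_lo <- detection_power(0.02, 12, 0, wp, n_reps = 400, seed = 2)$power
  p_hi <- detection_power(0.30, 12, 0, wp, n_reps = 400, seed = 2)$power
  expect_gt(p_hi, p_lo)
  # monotone in read depth
  n_lo <- detection_power(0.10, 3, 0, wp, n_reps = 400, seed = 3)$power
  n_hi <- detection_power(0.10, 30, 0, wp, n_reps = 400, seed = 3)$power
  expect_gt(n_hi, n_lo)
})
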