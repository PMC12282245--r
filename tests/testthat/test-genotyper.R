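test_that("ratio measurement follows the peak heights", {
  mkb <- function(h) {
    s <- simulate_peak_table(gt("aa", "aa"), test_panel, zero_noise,
                             seed = 1)
    pk <- s$peak_table$peaks
    tg <- test_panel$targets
    for (t in names(h)) {
      i <- which(pk$dye == tg$dye[tg$name == t] &
                   abs(pk$size - tg$expected_size[tg$name == t]) < 1)
      if (h[[t]] == 0) pk$height[i] <- NA else pk$height[i] <- h[[t]]
    }
    pk <- pk[!is.na(pk$height), ]
    bind_peaks(pk, test_panel)
  }
  m <- compute_ratios(mkb(c(alpha1 = 1000, alpha2 = 962, Y1 = 940,
                            Y2 = 1020)))
  expect_equal(m$a_ratio, 1.04, tolerance = 0.005)
  expect_equal(m$y_ratio, 0.92, tolerance = 0.005)

  m0 <- compute_ratios(mkb(c(alpha1 = 1000, alpha2 = 0, Y1 = 1000,
                             Y2 = 1000)))
  expect_true(is.na(m0$a_ratio))
  expect_true("alpha2" %in% m0$absent)

  meq <- compute_ratios(mkb(c(alpha1 = 800, alpha2 = 800, Y1 = 800,
                              Y2 = 800)))
  expect_identical(meq$a_ratio, 1)
  expect_identical(meq$y_ratio, 1)
})

test_that("classification reproduces the published class means and refuses junk", {
  cc <- classify_cnv(ratio_m(2.02, 0.48), test_panel)
  expect_identical(cc$label, "-a3.7/aa")
  expect_identical(classify_cnv(ratio_m(1.0, 1.0), test_panel)$label,
                   "aa/aa")
  expect_identical(classify_cnv(ratio_m(1.88, 2.05), test_panel)$label,
                   "-a4.2/aa")
  expect_identical(classify_cnv(ratio_m(0.97, 0.35), test_panel)$label,
                   "HKaa/aa")
  far <- classify_cnv(ratio_m(5.0, 5.0), test_panel)
  expect_identical(far$no_call_reason, "SCORE_EXCEEDS_MAX_Z")
  # absence pattern that no catalog pair produces
  odd <- ratio_m(NA_real_, 1,
                 heights = c(alpha1 = 0, alpha2 = 1000, Y1 = 1000,
                             Y2 = 1000))
  expect_identical(classify_cnv(odd, test_panel)$no_call_reason,
                   "ABSENCE_PATTERN_UNMATCHED")
})

test_that("classification is invariant to a global amplification scale", {
  set.seed(31)
  for (rep in 1:20) {
    pair <- sample(c("aa", "-a3.7", "-a4.2", "aaa_anti3.7", "HKaa"), 2,
                   replace = TRUE)
    s <- simulate_peak_table(list(alpha = pair, beta = c("bN", "bN")),
                             test_panel, sim_params(noise_cv = 0.07),
                             seed = sample.int(2^31 - 2, 1))
    b <- bind_peaks(s$peak_table$peaks, test_panel)
    base <- classify_cnv(compute_ratios(b), test_panel)
    for (c_scale in c(0.3, 2.5)) {
      pk <- s$peak_table$peaks
      pk$height <- pk$height * c_scale
      b2 <- bind_peaks(pk, test_panel)
      cc <- classify_cnv(compute_ratios(b2), test_panel)
      expect_identical(cc$label, base$label)
    }
  }
})

test_that("mutation zygosity follows the mutation/wild-type channel rule", {
  zyg <- function(genotype) {
    s <- simulate_peak_table(genotype, test_panel, zero_noise, seed = 2)
    b <- bind_peaks(s$peak_table$peaks, test_panel)
    call_mutations(b, test_panel)
  }
  het <- zyg(gt("aa", "aa", "bCD17", "bN"))
  expect_identical(het$zygosity[het$site == "bCD17"], "HET")
  hom <- zyg(gt("aa", "aa", "bCD17", "bCD17"))
  expect_identical(hom$zygosity[hom$site == "bCD17"], "HOM")
  nc <- zyg(gt("aa", "aa", "bCD37", "bN"))
  expect_identical(nc$zygosity[nc$site == "bCD37"], "HET_OR_HOM")
  ws <- zyg(gt("aWSa", "--SEA"))
  expect_identical(ws$zygosity[ws$site == "aWSa"], "HOM")
  none <- zyg(gt("aa", "aa"))
  expect_identical(nrow(none), 0L)
})

test_that("missing internal controls always yield UNINTERPRETABLE", {
  for (ctrl in c("GAPDH", "AMEL")) {
    s <- simulate_peak_table(gt("-a3.7", "aa", "bCD17", "bN"), test_panel,
                             zero_noise, seed = 3)
    pk <- s$peak_table$peaks
    tg <- test_panel$targets
    i <- which(pk$dye == tg$dye[tg$name == ctrl] &
                 abs(pk$size - tg$expected_size[tg$name == ctrl]) < 1)
    pk <- pk[-i, ]
    call <- call_sample(peak_table("x", pk), test_panel)
    expect_identical(call$status, "UNINTERPRETABLE")
    expect_true(paste0("CONTROL_", ctrl, "_MISSING") %in% call$qc_flags)
    expect_length(call$genotypes, 0L)
  }
  # global dropout below the analytical threshold: both controls flagged
  s <- simulate_peak_table(gt("aa", "aa"), test_panel, zero_noise, seed = 4)
  pk <- s$peak_table$peaks
  pk$height <- pk$height * 0.01
  call <- call_sample(peak_table("y", pk), test_panel)
  expect_identical(call$status, "UNINTERPRETABLE")
  expect_setequal(call$qc_flags, c("CONTROL_GAPDH_MISSING",
                                   "CONTROL_AMEL_MISSING"))
})

test_that("compound genotype with dosage, mutation and control evidence is unique", {
  call <- sim_call(gt("aCD74a", "-a4.2", "bCD17", "bN"))
  expect_identical(call$status, "OK")
  expect_identical(format_genotype(call$genotypes[[1]]),
                   "aCD74a/-a4.2; bCD17/bN")
  expect_identical(call$ratios$a_ratio, 2)
  expect_identical(call$ratios$y_ratio, 2)
})

test_that("missing wild-type control leaves exactly the two-genotype ambiguity", {
  call <- sim_call(gt("aWSa", "--SEA", "bCD37", "bN"))
  expect_identical(call$status, "AMBIGUOUS")
  labels <- vapply(call$genotypes, format_genotype, character(1))
  expect_setequal(labels, c("aWSa/--SEA; bCD37/bN",
                            "aWSa/--SEA; bCD37/bCD37"))
  expect_true("ZYGOSITY_UNRESOLVED" %in% call$qc_flags)
  expect_identical(call$ratios$a_ratio, 1)
  expect_identical(call$ratios$y_ratio, 1)
})

test_that("wild-type evidence lists the wild type first among dosage-equivalent configurations", {
  call <- sim_call(gt("aa", "aa"))
  expect_identical(call$status, "AMBIGUOUS")
  expect_identical(format_genotype(call$genotypes[[1]]), "aa/aa; bN/bN")
  labels <- vapply(call$genotypes, format_genotype, character(1))
  expect_true("-a3.7/aaa_anti3.7; bN/bN" %in% labels)
  expect_true("CNV_COMPENSATED_ALTERNATES" %in% call$qc_flags)
  expect_true(call_contains_truth(call, gt("aa", "aa")))
})

test_that("no candidate genotype ever conflicts with observed variant peaks", {
  set.seed(55)
  alpha <- c(genotype_catalog(test_panel)$alpha, "aa")
  beta <- c(genotype_catalog(test_panel)$beta, "bN")
  for (rep in 1:40) {
    truth <- list(alpha = sample(alpha, 2, replace = TRUE),
                  beta = sample(beta, 2, replace = TRUE))
    call <- sim_call(truth, seed = sample.int(2^31 - 2, 1))
    if (!(call$status %in% c("OK", "AMBIGUOUS"))) next
    s <- simulate_peak_table(truth, test_panel, zero_noise, seed = 1)
    observed <- bound_targets(bind_peaks(s$peak_table$peaks, test_panel))
    for (g in call$genotypes) {
      predicted <- expected_peak_set(g, test_panel)
      variant <- grep("^(mut_|gap_|wt_)", union(predicted, observed),
                      value = TRUE)
      expect_identical(sort(intersect(predicted, variant)),
                       sort(intersect(observed, variant)),
                       info = format_genotype(g))
    }
  }
})

test_that("cnv call conflicting with marker evidence is an explicit NO_CALL", {
  # SEA breakpoint present but dosage says -a3.7/aa: no pair explains both
  s <- simulate_peak_table(gt("-a3.7", "aa"), test_panel, zero_noise,
                           seed = 8)
  pk <- s$peak_table$peaks
  sea <- test_panel$targets[test_panel$targets$name == "gap_SEA", ]
  pk <- rbind(pk, data.frame(dye = sea$dye, size = sea$expected_size,
                             height = 2000, area = NA_real_,
                             scan_position = NA_integer_))
  call <- call_sample(peak_table("conflict", pk), test_panel)
  expect_identical(call$status, "NO_CALL")
  expect_identical(call$qc_flags, "EVIDENCE_CONFLICT")
})

test_that("cohort calling and concordance bookkeeping agree with the manifest", {
  spec <- list(
    list(genotype = gt("aa", "aa"), n = 4),
    list(genotype = gt("-a3.7", "aa"), n = 3),
    list(genotype = gt("aa", "--SEA", "bCD41/42", "bN"), n = 3))
  ch <- simulate_cohort(spec, test_panel, sim_params(noise_cv = 0.05),
                        seed = 21)
  res <- call_cohort(ch$samples, test_panel)
  expect_identical(nrow(res$records), 10L)
  cs <- concordance_summary(res$calls, ch$manifest)
  expect_identical(cs$n_negative, 4L)
  expect_identical(cs$n_positive, 6L)
  expect_identical(cs$negative_concordance, 1)
  expect_identical(cs$positive_concordance, 1)
  expect_identical(cs$overall_accuracy, 1)
})
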