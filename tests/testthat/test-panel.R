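test_that("shipped default panel satisfies all design rules", {
  report <- validate_panel(test_panel)
  expect_identical(nrow(report), 0L)
  # programmatic re-check of the two headline constraints
  tg <- test_panel$targets
  expect_true(all(tg$expected_size >= 80 & tg$expected_size <= 600))
  for (dye in unique(tg$dye))
    expect_true(all(diff(sort(tg$expected_size[tg$dye == dye])) >= 3))
})

test_that("each seeded single defect triggers exactly one violation", {
  mutate_and_check <- function(mutator, rule) {
    p <- test_panel
    p <- mutator(p)
    report <- validate_panel(p)
    expect_identical(nrow(report), 1L, info = rule)
    expect_identical(report$rule, rule)
  }
  mutate_and_check(function(p) {
    p$targets$expected_size[p$targets$name == "GAPDH"] <- 79
    p
  }, "size_range")
  mutate_and_check(function(p) {
    i <- which(p$targets$name == "alpha2")
    p$targets$expected_size[i] <-
      p$targets$expected_size[p$targets$name == "alpha1"] + 2
    p
  }, "same_dye_spacing")
  mutate_and_check(function(p) {
    p$targets <- p$targets[p$targets$name != "GAPDH", ]
    p
  }, "internal_controls")
  mutate_and_check(function(p) {
    i <- which(p$targets$name == "mut_bCD17")
    p$targets <- p$targets[-i, ]
    p
  }, "wt_control_link")
  mutate_and_check(function(p) {
    p$targets$dye[p$targets$name == "gap_SEA"] <- "LIZ"
    p
  }, "liz_reserved")
})

test_that("unparseable panel files raise a structural error, not violations", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("just: a\nscalar: doc", f)
  expect_error(read_panel(f), class = "thal_panel_structure_error")
  expect_error(read_panel(file.path(tempdir(), "nope.yaml")), "not found")
})

test_that("copy sums reproduce the per-allele dosage model", {
  expect_identical(expected_copy_numbers(c("aa", "aa"), test_panel),
                   c(alpha1 = 2L, alpha2 = 2L, Y1 = 2L, Y2 = 2L))
  expect_identical(expected_copy_numbers(c("-a3.7", "aa"), test_panel),
                   c(alpha1 = 2L, alpha2 = 1L, Y1 = 1L, Y2 = 2L))
  expect_identical(expected_copy_numbers(c("-a3.7", "-a4.2"), test_panel),
                   c(alpha1 = 2L, alpha2 = 0L, Y1 = 1L, Y2 = 1L))
  expect_error(expected_copy_numbers(c("aa", "bN"), test_panel),
               "alpha alleles")
  expect_error(expected_copy_numbers(c("aa", "nonesuch"), test_panel),
               "unknown allele")
})

test_that("theoretical ratios are exact rationals for the validated classes", {
  cases <- list(
    list(pair = c("aa", "aa"),          a = c(1L, 1L), y = c(1L, 1L)),
    list(pair = c("-a3.7", "aa"),       a = c(2L, 1L), y = c(1L, 2L)),
    list(pair = c("-a4.2", "aa"),       a = c(2L, 1L), y = c(2L, 1L)),
    list(pair = c("aaa_anti3.7", "aa"), a = c(2L, 3L), y = c(3L, 2L)),
    list(pair = c("aaa_anti4.2", "aa"), a = c(2L, 3L), y = c(2L, 3L)),
    list(pair = c("HKaa", "aa"),        a = c(1L, 1L), y = c(1L, 3L)))
  for (cs in cases) {
    r <- expected_ratio(cs$pair, test_panel)
    expect_identical(r$a, cs$a, info = paste(cs$pair, collapse = "/"))
    expect_identical(r$y, cs$y, info = paste(cs$pair, collapse = "/"))
  }
})

test_that("undefined and fully absent ratios are flagged", {
  r <- expect_silent(expected_ratio(c("-a3.7", "-a3.7"), test_panel))
  expect_null(r$a)
  expect_identical(r$y, c(0L, 1L))
  expect_false(r$total_absence)
  r2 <- expected_ratio(c("--SEA", "--SEA"), test_panel)
  expect_null(r2$a)
  expect_null(r2$y)
  expect_true(r2$total_absence)
  r3 <- expected_ratio(c("aWSa", "--SEA"), test_panel)
  expect_identical(r3$a, c(1L, 1L))
  expect_identical(r3$y, c(1L, 1L))
})

test_that("copy sums are exchange-symmetric over the whole alpha catalog", {
  alpha <- c(genotype_catalog(test_panel)$alpha, "aa")
  for (pair in all_unordered_pairs(alpha))
    expect_identical(expected_copy_numbers(pair, test_panel),
                     expected_copy_numbers(rev(pair), test_panel))
})

test_that("recombination conserves segment copies for each deletion/triplication pair", {
  al <- test_panel$alleles
  two_aa <- 2L * al[["aa"]]$copies
  expect_identical(al[["-a3.7"]]$copies + al[["aaa_anti3.7"]]$copies, two_aa)
  expect_identical(al[["-a4.2"]]$copies + al[["aaa_anti4.2"]]$copies, two_aa)
})

test_that("expected peak sets follow the channel rules", {
  wt <- expected_peak_set(gt("aa", "aa"), test_panel)
  expect_true(all(c("alpha1", "alpha2", "Y1", "Y2", "GAPDH", "AMEL") %in% wt))
  expect_true(all(paste0("wt_", c("aCSa", "bCD17", "bCD41/42")) %in% wt))
  expect_false(any(grepl("^(mut_|gap_)", wt)))

  sea <- expected_peak_set(gt("aa", "--SEA"), test_panel)
  expect_identical(sort(setdiff(sea, wt)), "gap_SEA")

  hom17 <- expected_peak_set(gt("aa", "aa", "bCD17", "bCD17"), test_panel)
  expect_true("mut_bCD17" %in% hom17)
  expect_false("wt_bCD17" %in% hom17)
  het17 <- expected_peak_set(gt("aa", "aa", "bCD17", "bN"), test_panel)
  expect_true(all(c("mut_bCD17", "wt_bCD17") %in% het17))
})

test_that("catalog holds exactly 16 alpha and 24 beta variant labels", {
  cat_v <- genotype_catalog(test_panel)
  expect_length(cat_v$alpha, 16L)
  expect_length(cat_v$beta, 24L)
})

test_that("panel YAML round trip preserves the model", {
  f <- withr::local_tempfile(fileext = ".yaml")
  write_panel(test_panel, f)
  p2 <- read_panel(f)
  expect_identical(p2$targets, test_panel$targets)
  expect_identical(p2$ratio_classes, test_panel$ratio_classes)
  expect_identical(p2$alpha_pairs$sig, test_panel$alpha_pairs$sig)
  expect_identical(p2$beta_pairs$sig, test_panel$beta_pairs$sig)
  expect_identical(p2$analytical_min_height,
                   test_panel$analytical_min_height)
})

test_that("shipped extdata panel matches the built-in default", {
  shipped <- system.file("extdata", "default_panel.yaml",
                         package = "thalcefa")
  expect_true(nzchar(shipped))
  p2 <- read_panel(shipped)
  expect_identical(nrow(validate_panel(p2)), 0L)
  expect_identical(p2$ratio_classes, test_panel$ratio_classes)
})
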