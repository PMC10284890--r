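test_that("library sampling honours the class mix", {
  ali <- generator_config(seed = 2, library_size = 500,
                          class_mix = c(CA = 0, Pol = 0, Uns = 0, Ali = 1,
                                        Other = 0))
  lib <- build_formula_library(ali)
  expect_true(all(lib$hc >= 1.5 & lib$hc <= 2.0))
  expect_true(all(lib$class == "Ali"))

  cfg <- generator_config(seed = 2, library_size = 10000)
  lib <- build_formula_library(cfg)
  got <- table(lib$class) / nrow(lib)
  for (cl in names(cfg$class_mix))
    expect_lt(abs(got[[cl]] - cfg$class_mix[[cl]]), 0.02)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- generator_config(seed = 77, formulas_per_lake = 100,
                          library_size = 800, n_lakes = 2)
  expect_identical(build_formula_library(cfg), build_formula_library(cfg))

  p1 <- synthesize_lake_pair(1, cfg, z = 0.5)
  p2 <- synthesize_lake_pair(1, cfg, z = 0.5)
  expect_identical(p1$dark$peaks, p2$dark$peaks)
  expect_identical(p1$truth, p2$truth)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  synthesize_study(cfg, dir = d1)
  synthesize_study(cfg, dir = d2)
  for (f in c("samples.csv", "peaks/MQ_light.csv", "spectra/GL_dark_r2.csv",
              "eems/MQ_light.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("adding lakes does not perturb earlier lakes' draws", {
  cfg3 <- generator_config(seed = 31, n_lakes = 3, formulas_per_lake = 80,
                           library_size = 600)
  cfg5 <- generator_config(seed = 31, n_lakes = 5, formulas_per_lake = 80,
                           library_size = 600)
  a <- synthesize_lake_pair(1, cfg3, z = 0.2)
  b <- synthesize_lake_pair(1, cfg5, z = 0.2)
  expect_identical(a$dark$peaks, b$dark$peaks)
  expect_identical(a$truth$produced, b$truth$produced)
})

test_that("peak emission respects the configured noise and S/N model", {
  cfg0 <- generator_config(seed = 3, ppm_noise_sd = 0, library_size = 500)
  lib <- build_formula_library(cfg0)
  pl <- synthesize_peaklist(lib[1:50, ], cfg0, "exact")
  truth <- attr(pl, "truth")
  want <- lib$mass[match(truth$formula, lib$formula)] -
    ATOMIC_MASS[["proton"]]
  expect_equal(truth$mz, want, tolerance = 1e-12)

  all_low <- generator_config(seed = 3, snr_below4_frac = 1,
                              library_size = 500)
  pl2 <- synthesize_peaklist(lib[1:50, ], all_low, "low")
  a <- assign_peaklist(pl2)
  expect_equal(nrow(a$formulas), 0)
  expect_true(all(a$assignments$rejection_reason == "low_snr"))
})

test_that("a null photo effect leaves the light sample equal to dark", {
  cfg <- generator_config(
    seed = 4, formulas_per_lake = 100, library_size = 800,
    photo_effect = list(
      produce_base = c(CA = 0, Pol = 0, Uns = 0, Ali = 0, Other = 0),
      produce_slope = c(CA = 0, Pol = 0, Uns = 0, Ali = 0, Other = 0),
      remove = c(CA = 0, Pol = 0, Uns = 0, Ali = 0, Other = 0)))
  lk <- synthesize_lake_pair(1, cfg, z = 1)
  expect_setequal(lk$truth$light_formulas, lk$truth$dark_formulas)
  expect_length(lk$truth$produced, 0)
  expect_length(lk$truth$removed, 0)
})

test_that("injection rates scale with the DOM score as configured", {
  cfg <- generator_config(seed = 6, formulas_per_lake = 2000,
                          library_size = 12000)
  lk_hi <- synthesize_lake_pair(1, cfg, z = 1.5)
  lib <- build_formula_library(cfg)
  prod_class <- lib$class[match(lk_hi$truth$produced, lib$formula)]
  dark_class <- lib$class[match(lk_hi$truth$dark_formulas, lib$formula)]
  p_ca_expected <- cfg$photo_effect$produce_base[["CA"]] +
    cfg$photo_effect$produce_slope[["CA"]] * 1.5
  p_ca_realised <- sum(prod_class == "CA") / sum(dark_class == "CA")
  expect_equal(p_ca_realised, p_ca_expected, tolerance = 0.02)

  # produced sets are CA/Pol-enriched at high z relative to low z
  lk_lo <- synthesize_lake_pair(2, cfg, z = -1.5)
  lo_class <- lib$class[match(lk_lo$truth$produced, lib$formula)]
  share <- function(cls) mean(cls %in% c("CA", "Pol"))
  expect_gt(share(prod_class), share(lo_class))
})

test_that("the study bundle matches the factorial design arithmetic", {
  cfg <- generator_config(seed = 8, n_lakes = 10, formulas_per_lake = 60,
                          library_size = 600)
  st <- synthesize_study(cfg)
  nb <- st$samples[!st$samples$is_blank, ]
  expect_equal(nrow(nb), 10 * 2 * 2 * 3)
  expect_true(any(st$samples$is_blank))
  expect_equal(length(st$lakes), 10)
  expect_equal(sort(unique(nb$treatment)), c("dark", "light"))
  expect_setequal(unique(nb$temperature_C), c(10, 20))
  expect_true(all(nb$doc_mgC_L >= cfg$doc_range[1] - 1e-9))
  # DOC within the configured span (small lognormal jitter allowed above)
  expect_true(all(nb$doc_mgC_L <= cfg$doc_range[2] * 1.15))
  # truth is sufficient to score the pipeline
  expect_true(all(is.finite(st$truth$x_true)))
  expect_true(all(is.finite(st$truth$rr_true)))
})

test_that("study files round-trip through read_study", {
  cfg <- generator_config(seed = 9, n_lakes = 2, formulas_per_lake = 60,
                          library_size = 600)
  d <- withr::local_tempdir()
  st <- synthesize_study(cfg, dir = d)
  back <- read_study(d)
  expect_equal(back$samples$co2_d28, st$samples$co2_d28, tolerance = 0)
  expect_equal(back$lakes[[1]]$dark$peaks, st$lakes[[1]]$dark$peaks,
               tolerance = 0)
  expect_equal(back$spectra[["MQ_dark_r1"]]$absorbance,
               st$spectra[["MQ_dark_r1"]]$absorbance, tolerance = 0)
  expect_equal(back$eems[["GL_light"]]$intensity,
               st$eems[["GL_light"]]$intensity, tolerance = 0)
})

test_that("synthetic optical inputs land in the study's reported ranges", {
  cfg <- generator_config(seed = 10, n_lakes = 10, formulas_per_lake = 60,
                          library_size = 600)
  st <- synthesize_study(cfg)
  dark <- grep("_dark_r", names(st$spectra), value = TRUE)
  a300 <- vapply(dark, function(s) napierian_a(st$spectra[[s]], 300),
                 numeric(1))
  expect_true(all(a300 > 5 & a300 < 80))
  bixv <- vapply(grep("dark", names(st$eems), value = TRUE),
                 function(e) bix(st$eems[[e]]), numeric(1))
  expect_true(all(bixv > 0.3 & bixv < 1.1))
  srv <- vapply(dark, function(s) slope_ratio(st$spectra[[s]]), numeric(1))
  expect_true(all(srv > 0.8 & srv < 1.6))
})
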