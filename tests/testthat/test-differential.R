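two_formula_pair <- function(i_ref, i_trt) {
  comps <- data.frame(c = c(10, 12), h = c(12, 16), o = c(4, 5), n = 0,
                      s = 0)
  list(ref = make_annotated("dark", comps, i_ref),
       trt = make_annotated("light", comps, i_trt))
}

test_that("dual-threshold rule needs both raw and relative change", {
  # equal totals: +30% raw is also +30% relative
  p <- two_formula_pair(c(100, 100), c(130, 70))
  d <- compare_threshold(p$ref, p$trt)
  expect_identical(d$produced, "C10H12O4")
  expect_identical(d$degraded, "C12H16O5")

  # identical samples: everything unchanged
  q <- two_formula_pair(c(100, 50), c(100, 50))
  dq <- compare_threshold(q$ref, q$trt)
  expect_length(dq$produced, 0)
  expect_length(dq$degraded, 0)
  expect_length(dq$unchanged, 2)

  # raw change above threshold but relative change below: not produced.
  # both intensities rise 30% so relative intensities are unchanged.
  r <- two_formula_pair(c(100, 100), c(130, 130))
  dr <- compare_threshold(r$ref, r$trt)
  expect_length(dr$produced, 0)

  expect_error(compare_threshold(p$ref, p$ref), "different samples")
})

test_that("formulas present in only one sample are classed by presence", {
  ref <- make_annotated("dark", data.frame(c = c(10, 12), h = c(12, 16),
                                           o = c(4, 5), n = 0, s = 0),
                        c(100, 100))
  trt <- make_annotated("light", data.frame(c = c(10, 14), h = c(12, 18),
                                            o = c(4, 6), n = 0, s = 0),
                        c(100, 1))
  d <- compare_threshold(ref, trt)
  expect_true("C14H18O6" %in% d$produced)  # tiny but newly present
  expect_true("C12H16O5" %in% d$degraded)
})

test_that("presence/absence comparison is plain set algebra", {
  comps <- data.frame(c = 10:13, h = c(12, 14, 16, 18), o = 4:7, n = 0,
                      s = 0)
  a <- make_annotated("a", comps[1:3, ], c(1, 2, 3))       # A B C
  b <- make_annotated("b", comps[2:4, ], c(2, 3, 4))       # B C D
  d <- compare_presence_absence(a, b)
  expect_identical(d$produced, "C13H18O7")
  expect_identical(d$degraded, "C10H12O4")
  expect_setequal(d$unchanged, c("C11H14O5", "C12H16O6"))

  disj <- compare_presence_absence(make_annotated("a", comps[1:2, ], 1:2),
                                   make_annotated("b", comps[3:4, ], 1:2))
  expect_length(disj$unchanged, 0)
  expect_length(disj$produced, 2)
  expect_length(disj$degraded, 2)

  same <- compare_presence_absence(a, make_annotated("b", comps[1:3, ],
                                                     c(9, 9, 9)))
  expect_length(same$produced, 0)
  expect_length(same$degraded, 0)
})

test_that("swapping reference and treated swaps produced and degraded", {
  cfg <- generator_config(seed = 13, formulas_per_lake = 150,
                          library_size = 1200)
  lk <- synthesize_lake_pair(1, cfg, z = 1)
  a1 <- assign_peaklist(lk$dark)
  a2 <- assign_peaklist(lk$light)
  d12 <- compare_threshold(a1, a2)
  d21 <- compare_threshold(a2, a1)
  expect_setequal(d12$produced, d21$degraded)
  expect_setequal(d12$degraded, d21$produced)
  expect_setequal(d12$unchanged, d21$unchanged)
  expect_length(intersect(d12$produced, d12$degraded), 0)

  pa12 <- compare_presence_absence(a1, a2)
  pa21 <- compare_presence_absence(a2, a1)
  expect_setequal(pa12$produced, pa21$degraded)
})

test_that("an extreme threshold reduces to presence/absence", {
  p <- two_formula_pair(c(100, 100), c(160, 40))
  d <- compare_threshold(p$ref, p$trt, frac = 99)
  expect_length(d$produced, 0)   # shared formulas all unchanged
  expect_length(d$degraded, 0)
})

test_that("threshold detection recovers generator truth at 5% intensity CV", {
  set.seed(17)
  cfg <- generator_config(seed = 17, formulas_per_lake = 400,
                          library_size = 3000)
  lk <- synthesize_lake_pair(2, cfg, z = 1.2)
  # annotated samples straight from the truth tables with 5% CV noise
  lib <- build_formula_library(cfg)
  f_dark <- lib[match(lk$truth$dark_formulas, lib$formula), ]
  f_light <- lib[match(lk$truth$light_formulas, lib$formula), ]
  base <- setNames(rlnorm(length(union(f_dark$formula, f_light$formula)),
                          14, 1),
                   union(f_dark$formula, f_light$formula))
  ref <- annotated_sample("d", f_dark,
                          base[f_dark$formula] * rlnorm(nrow(f_dark), 0,
                                                        0.05))
  trt <- annotated_sample("l", f_light,
                          base[f_light$formula] * rlnorm(nrow(f_light), 0,
                                                         0.05))
  d <- compare_threshold(ref, trt)
  sens_p <- length(intersect(d$produced, lk$truth$produced)) /
    length(lk$truth$produced)
  sens_d <- length(intersect(d$degraded, lk$truth$removed)) /
    length(lk$truth$removed)
  truly_unchanged <- setdiff(intersect(f_dark$formula, f_light$formula),
                             c(lk$truth$produced, lk$truth$removed))
  spec <- mean(truly_unchanged %in% d$unchanged)
  expect_gte(sens_p, 0.95)
  expect_gte(sens_d, 0.95)
  expect_gte(spec, 0.95)
})

test_that("method concordance reports Jaccard 1 / correlation 1 on itself", {
  cfg <- generator_config(seed = 19, formulas_per_lake = 120,
                          library_size = 1000)
  sets <- lapply(1:3, function(i) {
    lk <- synthesize_lake_pair(i, cfg, z = i - 2)
    compare_threshold(assign_peaklist(lk$dark), assign_peaklist(lk$light))
  })
  conc <- method_concordance(sets, sets)
  expect_equal(unname(conc$mean_jaccard), rep(1, 3))
  expect_equal(unname(conc$correlation), rep(1, 3), tolerance = 1e-9)

  # disjoint produced sets -> Jaccard 0 for that label
  comps <- data.frame(c = 10:13, h = c(12, 14, 16, 18), o = 4:7, n = 0,
                      s = 0)
  a <- compare_presence_absence(make_annotated("a", comps[1, ], 1),
                                make_annotated("b", comps[2, ], 1))
  b <- compare_presence_absence(make_annotated("a", comps[3, ], 1),
                                make_annotated("b", comps[4, ], 1))
  c0 <- method_concordance(a, b)
  expect_equal(unname(c0$jaccard["produced", 1]), 0)
  expect_true(is.na(c0$correlation[["produced"]]))  # < 3 pairs

  # hand-enumerated oracle on one pair: threshold vs presence/absence
  p <- two_formula_pair(c(100, 100), c(130, 70))
  thr <- compare_threshold(p$ref, p$trt)
  pa <- compare_presence_absence(p$ref, p$trt)
  cc <- method_concordance(thr, pa)
  # threshold: one produced, one degraded; presence/absence: both unchanged
  expect_equal(unname(cc$jaccard[, 1]), c(0, 0, 0))
})

test_that("aromaticity overlap diagnostic flags the closer set pair", {
  pp <- list(L1 = c(0.2, 0.3, 0.4), L2 = c(0.6, 0.7))
  pd <- list(L1 = c(0.6, 0.7, 0.8), L2 = c(0.1, 0.2))
  bd <- list(L1 = c(0.25, 0.35, 0.30), L2 = c(0.15, 0.22))
  out <- set_overlap_analysis(pp, pd, bd)
  expect_identical(out$overlaps_with, c("PP", "PD"))
  expect_equal(out$median_pp[1], 0.3)

  ident <- set_overlap_analysis(list(L = c(0.3, 0.4)), list(L = c(0.3, 0.4)),
                                list(L = c(0.3, 0.4)))
  expect_equal(ident$gap_pp_bd, 0)
  expect_equal(ident$gap_pd_bd, 0)

  # single-value sets: medians reported, rank-sum omitted
  deg <- set_overlap_analysis(list(L = 0.3), list(L = 0.5), list(L = 0.35))
  expect_true(is.na(deg$p_pp_bd))
  expect_identical(deg$overlaps_with, "PP")

  expect_warning(
    set_overlap_analysis(list(L = numeric(0)), list(L = 0.5),
                         list(L = 0.35)),
    "skipped")
})

test_that("rank-sum overlap calls match the generating distributions", {
  set.seed(23)
  n_sim <- 200
  flagged_pp <- logical(n_sim)
  p_ppbd <- numeric(n_sim)
  for (k in seq_len(n_sim)) {
    pp <- rnorm(500, 0.3, 0.08)
    bd <- rnorm(500, 0.3, 0.08)
    pd <- rnorm(500, 0.6, 0.08)
    out <- set_overlap_analysis(list(L = pp), list(L = pd), list(L = bd))
    flagged_pp[k] <- out$overlaps_with == "PP"
    p_ppbd[k] <- out$p_pp_bd
  }
  expect_gte(mean(flagged_pp), 0.9)
  expect_gte(mean(p_ppbd > 0.05), 0.9)
})
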