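test_that("CO2 production is the day-0-referenced, blank-corrected rise", {
  rec <- list(co2_d0 = 5, co2_d7 = 14, co2_d28 = 25)
  blank <- list(co2_d0 = 1, co2_d7 = 2, co2_d28 = 3)
  expect_equal(co2_production(rec, blank, day = 28), (25 - 5) - (3 - 1))
  expect_equal(co2_production(rec, blank, day = 7), (14 - 5) - (2 - 1))

  same <- co2_production(blank, blank, day = 28)
  expect_equal(same, 0)

  expect_warning(un <- co2_production(rec, NULL, day = 28), "uncorrected")
  expect_equal(un, 20)

  neg <- co2_production(list(co2_d0 = 5, co2_d28 = 6),
                        list(co2_d0 = 1, co2_d28 = 4), day = 28)
  expect_equal(as.numeric(neg), -2)
  expect_true(isTRUE(attr(neg, "negative")))

  expect_error(co2_production(list(co2_d0 = 5, co2_d28 = NA), blank, 28),
               "required")
})

test_that("response ratios are log ratios with sign antisymmetry", {
  expect_equal(response_ratio(10, 10), 0)
  expect_equal(response_ratio(20, 10), log(2), tolerance = 1e-12)
  expect_equal(response_ratio(0.565, 1), -0.571, tolerance = 1e-3)
  expect_equal(response_ratio(3, 7), -response_ratio(7, 3),
               tolerance = 1e-12)
  expect_equal(response_ratio(20, 10, log = FALSE), 2)
  expect_warning(v <- response_ratio(-1, 5), "non-positive")
  expect_true(is.na(v))
})

test_that("DOM PC1 follows the two-variable closed form", {
  doc <- c(6, 9, 12, 15)
  pc <- dom_pc1(doc, doc * 0.1)          # perfectly correlated
  expect_equal(pc$var_explained, 1, tolerance = 1e-12)
  expect_equal(pc$scores, as.vector(scale(doc)) * sqrt(2),
               tolerance = 1e-9)

  # independent columns by construction (empirical r = 0)
  x <- c(-1, 1, -1, 1); y <- c(-1, -1, 1, 1)
  pc0 <- dom_pc1(x, y)
  expect_equal(pc0$var_explained, 0.5, tolerance = 1e-12)

  # general case: (1 + r) / 2
  set.seed(41)
  for (k in 1:5) {
    doc <- rnorm(12); don <- 0.6 * doc + rnorm(12, 0, 0.8)
    pc <- dom_pc1(doc, don)
    expect_equal(pc$var_explained, (1 + abs(cor(doc, don))) / 2,
                 tolerance = 1e-12)
    expect_gt(pc$loadings[["doc"]], 0)
  }

  # invariant to affine unit changes
  set.seed(42)
  doc <- runif(8, 5, 17); don <- runif(8, 0.3, 1.4)
  expect_equal(dom_pc1(doc, don)$scores,
               dom_pc1(doc * 1000 + 3, don / 14 - 2)$scores,
               tolerance = 1e-9)

  expect_error(dom_pc1(rep(1, 5), rnorm(5)), "variance")
})

test_that("standardized coefficient equals the Pearson correlation", {
  x <- c(1, 2, 4, 7, 11)
  expect_equal(standardized_coef(x, x)$coef, 1)
  expect_equal(standardized_coef(x, x)$r2, 1)
  expect_equal(standardized_coef(x, -x)$coef, -1)

  set.seed(43)
  y <- 2 * x + rnorm(5)
  sc <- standardized_coef(x, y)
  expect_equal(sc$coef, cor(x, y), tolerance = 1e-12)
  expect_equal(sc$p_value, cor.test(x, y)$p.value, tolerance = 1e-9)
  expect_equal(abs(standardized_coef(y, x)$coef), abs(sc$coef),
               tolerance = 1e-12)

  # sampling distribution around a true r = 0.86 (R^2 = 0.74)
  r2s <- replicate(300, {
    x <- rnorm(10)
    y <- 0.86 * x + sqrt(1 - 0.86^2) * rnorm(10)
    standardized_coef(x, y)$r2
  })
  expect_lt(abs(median(r2s) - 0.74), 0.15)

  expect_error(standardized_coef(rep(1, 5), rnorm(5)), "variance")
})

test_that("factorial ANOVA reproduces aov on a balanced design and flags
           degenerate input", {
  set.seed(44)
  d <- expand.grid(treatment = c("dark", "light"), temperature = c(10, 20),
                   lake = LETTERS[1:4], rep = 1:3)
  d$response <- rnorm(nrow(d)) +
    0.8 * (d$treatment == "light") * (d$lake == "A")
  out <- factorial_anova(d, c("treatment", "temperature", "lake"))
  ref <- summary(stats::aov(response ~ treatment * temperature * lake,
                            data = d))[[1]]
  m <- match(paste0(out$term), trimws(rownames(ref)))
  expect_equal(out$sumsq, ref[m, "Sum Sq"], tolerance = 1e-9)
  expect_equal(out$p_value, ref[m, "Pr(>F)"], tolerance = 1e-9)
  expect_true("treatment:temperature" %in% out$term)
  expect_true("treatment:lake" %in% out$term)

  flat <- d; flat$response <- 1
  out0 <- factorial_anova(flat, c("treatment", "temperature", "lake"))
  expect_true(attr(out0, "degenerate"))
  expect_true(all(is.na(out0$p_value)))

  one <- d; one$treatment <- "dark"
  expect_error(factorial_anova(one, c("treatment", "lake")), "2 levels")
})

test_that("a strong sunlight-by-lake interaction is detected", {
  set.seed(45)
  hits <- replicate(20, {
    rr <- rnorm(10, 0, 0.5)   # per-lake sunlight effect
    st <- synthesize_co2(generator_config(seed = sample.int(1e6, 1)),
                         sprintf("L%02d", 1:10), rr,
                         dark_base = runif(10, 10, 25),
                         doc = runif(10, 6, 16), don = runif(10, 0.3, 1.3))
    st <- st[!st$is_blank, ]
    st$response <- log(st$co2_d28 - st$co2_d0)
    names(st)[names(st) == "lake_id"] <- "lake"
    names(st)[names(st) == "temperature_C"] <- "temperature"
    a <- factorial_anova(st, c("treatment", "temperature", "lake"))
    a$p_value[a$term == "treatment:lake"] < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("rank-sum test gives exact small-sample p-values", {
  same <- group_rank_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  ext <- group_rank_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(ext$p_value, 0.1, tolerance = 1e-12)  # 2/20 arrangements

  expect_error(group_rank_test(1, c(1, 2)), "at least 2")

  # power is monotone in the shift alternative
  set.seed(46)
  pow <- vapply(c(0, 1, 2.5), function(shift) {
    mean(replicate(200, {
      group_rank_test(rnorm(8), rnorm(8, shift))$p_value < 0.05
    }))
  }, numeric(1))
  expect_true(all(diff(pow) > 0))
})
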