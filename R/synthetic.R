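# Synthetic study generator with ground truth.
#
# Emulates the field design: 10 lakes spanning a DOM-content gradient, paired
# light/dark treatments, two incubation temperatures, three replicates.
# Light exposure removes a fixed per-class fraction of each lake's formulas
# and injects new ones, with the injection rates for polycyclic aromatics and
# polyphenols rising linearly along the DOM gradient; microbial incubation
# then removes a class-biased fraction of the light-exposed pool. Respiration
# response ratios are generated from a stated linear model on the true mean
# aromaticity of the photo-produced set. Every draw runs on a per-lake
# substream derived from the master seed, so adding lakes does not perturb
# existing lakes.

.substream_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  h <- 0
  for (k in utf8ToInt(key)) h <- (h * 31 + k) %% 2147480009
  as.integer((as.numeric(seed) * 7919 + h) %% 2147480009)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for the synthetic study generator
#'
#' Defaults reproduce the study conditions the package is designed around:
#' 10 lakes, paired light/dark treatments, 10 and 20 degree incubations,
#' three replicates, DOC 5.69-16.76 mg C/L, DON 0.33-1.35 mg/L, CDOM a300
#' 8.44-65.87 1/m, and a respiration response ratio generated as
#' `rr = rr_center + beta_co2 * (x - x_center) + noise`, where `x` is the
#' true mean AImod of the lake's photo-produced formulas.
#'
#' @param n_lakes Number of lakes (site codes are recycled beyond 10).
#' @param formulas_per_lake Formulas in each lake's dark sample.
#' @param library_size Size of the shared formula library the lakes draw
#'   from.
#' @param mass_range_Da Neutral-mass window for the formula space.
#' @param ppm_noise_sd Gaussian m/z error (ppm) applied to synthetic peaks.
#' @param intensity_lognormal `c(meanlog, sdlog)` of the lake-level base
#'   intensity each formula carries (drawn once per lake, shared by the
#'   paired samples).
#' @param intensity_cv Analytical (between-acquisition) lognormal CV applied
#'   to base intensities when a peak list is emitted.
#' @param snr_below4_frac Fraction of peaks drawn with S/N below 4.
#' @param class_mix Named probabilities (CA, Pol, Uns, Ali, Other) summing
#'   to 1.
#' @param photo_effect List with named per-class vectors `produce_base`,
#'   `produce_slope` (injection fraction `base + slope * z`, clamped to
#'   \[0, 1\], `z` the standardized DOM score) and `remove` (removal
#'   fraction).
#' @param bio_effect List with named per-class vector `remove`: fraction of
#'   the light-exposed pool removed by 28 days of microbial incubation.
#' @param beta_co2 Coupling of the respiration response ratio to the true
#'   mean AImod of photo-produced formulas.
#' @param x_center,rr_center Centering constants of the respiration model.
#' @param noise_sd_co2 SD of the lake-level noise on the response ratio.
#' @param co2_per_doc Dark day-28 CO2 production (umol) per mg C/L of DOC.
#' @param co2_day7_frac Day-7 production as a fraction of day-28.
#' @param temp_q10 Multiplier on production at 20 vs 10 degrees.
#' @param co2_rep_cv Replicate-level lognormal CV of production.
#' @param dic0_umol Day-0 background DIC measurement (umol).
#' @param blank_drift_umol `c(day7, day28)` residual headspace CO2 drift
#'   shared by all microcosms and captured by the blanks.
#' @param doc_range,don_range,a300_range Lake-level ranges.
#' @param tol_ppm,snr_min,diff_frac Downstream pipeline settings carried in
#'   the config (assignment tolerance, S/N gate, differential threshold).
#' @param guard_ppm The library samples only formulas that win the
#'   least-heteroatom rule outright: no competing formula with an equal or
#'   smaller heteroatom count within this window. Real assigned-formula
#'   tables have this property by construction, since they are themselves
#'   the output of the assignment rule; without it a truth formula such as
#'   C17H19NOS could never be recovered, because C10H21O9 sits 0.18 mDa away
#'   and legitimately wins the rule.
#' @param seed Master seed; fixes all randomness end-to-end.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(
    n_lakes = 10,
    formulas_per_lake = 1000,
    library_size = 5000,
    mass_range_Da = c(100, 800),
    ppm_noise_sd = 0.3,
    intensity_lognormal = c(meanlog = 14, sdlog = 1),
    intensity_cv = 0.05,
    snr_below4_frac = 0.05,
    class_mix = c(CA = 0.04, Pol = 0.08, Uns = 0.62, Ali = 0.22,
                  Other = 0.04),
    photo_effect = list(
      produce_base = c(CA = 0.08, Pol = 0.08, Uns = 0.10, Ali = 0.10,
                       Other = 0.05),
      produce_slope = c(CA = 0.045, Pol = 0.04, Uns = 0, Ali = -0.03,
                        Other = 0),
      remove = c(CA = 0.20, Pol = 0.15, Uns = 0.12, Ali = 0.10,
                 Other = 0.10)),
    bio_effect = list(
      remove = c(CA = 0.30, Pol = 0.10, Uns = 0.08, Ali = 0.25,
                 Other = 0.10)),
    beta_co2 = 14,
    x_center = 0.28,
    rr_center = 0.21,
    noise_sd_co2 = 0.15,
    co2_per_doc = 1.5,
    co2_day7_frac = 0.55,
    temp_q10 = 1.8,
    co2_rep_cv = 0.05,
    dic0_umol = 20,
    blank_drift_umol = c(0.2, 0.5),
    doc_range = c(5.69, 16.76),
    don_range = c(0.33, 1.35),
    a300_range = c(8.44, 65.87),
    tol_ppm = 1.0,
    snr_min = 4.0,
    diff_frac = 0.20,
    guard_ppm = 2.5,
    seed = 1L) {
  stopifnot(abs(sum(class_mix) - 1) < 1e-9,
            all(names(class_mix) %in% compound_classes()),
            all(photo_effect$remove >= 0 & photo_effect$remove <= 1),
            all(bio_effect$remove >= 0 & bio_effect$remove <= 1),
            snr_below4_frac >= 0, snr_below4_frac <= 1,
            ppm_noise_sd >= 0, n_lakes >= 1,
            abs(seed) < 2^31)
  structure(as.list(environment()), class = "generator_config")
}

.lake_codes <- c("MQ", "GL", "NR", "SN", "MD", "NQ", "GM", "AD", "YS", "HH")

.lake_ids <- function(n) {
  if (n <= length(.lake_codes)) .lake_codes[seq_len(n)]
  else c(.lake_codes, sprintf("L%02d", seq_len(n - length(.lake_codes)) + 10))
}

.identifiable <- function(mass, het, guard_ppm) {
  # TRUE where no other formula with an equal or smaller heteroatom count
  # lies within guard_ppm; `mass` must be sorted ascending
  n <- length(mass)
  excl <- logical(n)
  k <- 1L
  repeat {
    i <- seq_len(n - k)
    j <- i + k
    close <- (mass[j] - mass[i]) / mass[i] * 1e6 <= guard_ppm
    if (!any(close)) break
    ii <- i[close]; jj <- j[close]
    excl[ii] <- excl[ii] | het[jj] <= het[ii]
    excl[jj] <- excl[jj] | het[ii] <= het[jj]
    k <- k + 1L
  }
  !excl
}

#' Build the shared formula library
#'
#' Exhaustively enumerates the CHONS formula space passing the assignment
#' filters inside the configured mass window, classifies every formula,
#' drops formulas that could not win the least-heteroatom rule against a
#' neighbour within `cfg$guard_ppm` (see [generator_config()]), and samples
#' (without replacement) per class to match `class_mix`. The result is
#' deterministic given `cfg$seed`.
#'
#' @param cfg A [generator_config()].
#' @return Formula table with molecular indices and a `class` column.
#' @export
build_formula_library <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  space <- enumerate_formula_space(
    filter_rules(mass_min = cfg$mass_range_Da[1],
                 mass_max = cfg$mass_range_Da[2]))
  space <- formula_indices(space)
  key <- paste("identifiable", cfg$mass_range_Da[1], cfg$mass_range_Da[2],
               cfg$guard_ppm, sep = "|")
  idf <- .domphoto_cache[[key]]
  if (is.null(idf)) {
    idf <- .identifiable(space$mass, space$heteroatoms, cfg$guard_ppm)
    .domphoto_cache[[key]] <- idf
  }
  space <- space[idf, , drop = FALSE]
  counts <- round(cfg$class_mix * cfg$library_size)
  .with_seed(.substream_seed(cfg$seed, "library"), {
    picks <- lapply(names(counts), function(cl) {
      idx <- which(space$class == cl)
      if (length(idx) == 0 && counts[[cl]] > 0)
        stop(sprintf("no formulas available for class '%s'", cl))
      k <- counts[[cl]]
      if (k > length(idx)) {
        warning(sprintf("class '%s': only %d formulas available (%d asked)",
                        cl, length(idx), k))
        k <- length(idx)
      }
      sample(idx, k)
    })
    lib <- space[sort(unlist(picks)), , drop = FALSE]
    rownames(lib) <- NULL
    lib
  })
}

#' Emit a peak list for a set of formulas
#'
#' Each formula becomes one [M-H]- peak: m/z is the neutral mass minus the
#' proton mass, perturbed by Gaussian relative error of `cfg$ppm_noise_sd`
#' ppm; intensities come from the table's `base_intensity` column times a
#' lognormal analytical factor of CV `cfg$intensity_cv` (or are drawn fresh
#' from the lognormal population when the column is absent); a configured
#' fraction of peaks receives
#' S/N below 4 (uniform on \[1, 4\]), the rest above (4 + lognormal). The
#' rare pair of peaks colliding within 0.1 ppm is resolved by dropping the
#' less intense peak (recorded in the truth table).
#'
#' @param formulas Formula table (rows of the library).
#' @param cfg A [generator_config()].
#' @param sample_id Identifier; also selects the random substream.
#' @return A [peaklist()] with attribute `truth`: data frame of `formula`,
#'   `mz`, `snr`, `kept`.
#' @export
synthesize_peaklist <- function(formulas, cfg, sample_id) {
  stopifnot(inherits(cfg, "generator_config"), nrow(formulas) > 0)
  .with_seed(.substream_seed(cfg$seed, "peaks", sample_id), {
    n <- nrow(formulas)
    mz <- (formulas$mass - ATOMIC_MASS[["proton"]]) *
      (1 + stats::rnorm(n, 0, cfg$ppm_noise_sd) * 1e-6)
    intensity <- if (!is.null(formulas$base_intensity)) {
      formulas$base_intensity * stats::rlnorm(n, 0, cfg$intensity_cv)
    } else {
      stats::rlnorm(n, cfg$intensity_lognormal[[1]],
                    cfg$intensity_lognormal[[2]])
    }
    low <- stats::runif(n) < cfg$snr_below4_frac
    snr <- ifelse(low, stats::runif(n, 1, 4),
                  4 + stats::rlnorm(n, 2, 0.8))
    truth <- data.frame(formula = formulas$formula, mz = mz,
                        intensity = intensity, snr = snr, kept = TRUE,
                        stringsAsFactors = FALSE)
    o <- order(mz)
    truth <- truth[o, , drop = FALSE]
    repeat {
      rel <- diff(truth$mz[truth$kept]) /
        truth$mz[truth$kept][-sum(truth$kept)]
      clash <- which(rel < 1e-7)
      if (length(clash) == 0) break
      kept_idx <- which(truth$kept)
      i1 <- kept_idx[clash[1]]; i2 <- kept_idx[clash[1] + 1]
      drop <- if (truth$intensity[i1] < truth$intensity[i2]) i1 else i2
      truth$kept[drop] <- FALSE
    }
    pk <- truth[truth$kept, c("mz", "intensity", "snr"), drop = FALSE]
    pl <- peaklist(sample_id, pk)
    attr(pl, "truth") <- truth
    pl
  })
}

.clamp01 <- function(x) pmin(pmax(x, 0), 1)

.sample_frac_by_class <- function(tab, frac_by_class) {
  picks <- unlist(lapply(names(frac_by_class), function(cl) {
    idx <- which(tab$class == cl)
    k <- round(frac_by_class[[cl]] * length(idx))
    if (k > 0) sample(idx, k) else integer(0)
  }))
  sort(picks)
}

#' Generate one lake's dark/light/post-incubation formula sets and peak lists
#'
#' The dark pool is a class-stratified draw from the library; the light pool
#' removes `photo_effect$remove` of each class and injects
#' `produce_base + produce_slope * z` new formulas per class; microbial
#' incubation then removes `bio_effect$remove` of the light pool.
#'
#' @param lake_index Lake number (selects the substream).
#' @param cfg A [generator_config()].
#' @param library Optional precomputed [build_formula_library()] result.
#' @param z Standardized DOM-content score of the lake.
#' @return A list: `dark`, `light`, `bio` ([peaklist()]s with truth
#'   attributes) and `truth` (formula sets, the true produced/removed and
#'   bio-degraded sets, and `x_true`, the mean AImod of the produced set).
#' @export
synthesize_lake_pair <- function(lake_index, cfg, library = NULL, z = 0) {
  stopifnot(inherits(cfg, "generator_config"))
  if (is.null(library)) library <- build_formula_library(cfg)
  lake_id <- .lake_ids(max(lake_index, cfg$n_lakes))[lake_index]
  sets <- .with_seed(.substream_seed(cfg$seed, "lake", lake_index), {
    mix <- cfg$class_mix
    dark_idx <- unlist(lapply(names(mix), function(cl) {
      idx <- which(library$class == cl)
      k <- min(round(mix[[cl]] * cfg$formulas_per_lake), length(idx))
      sample(idx, k)
    }))
    dark <- library[sort(dark_idx), , drop = FALSE]
    rem_frac <- cfg$photo_effect$remove
    removed_i <- .sample_frac_by_class(dark, rem_frac)
    prod_frac <- .clamp01(cfg$photo_effect$produce_base +
                            cfg$photo_effect$produce_slope * z)
    pool <- library[-sort(dark_idx), , drop = FALSE]
    n_class_dark <- table(factor(dark$class, levels = names(prod_frac)))
    inject_n <- round(prod_frac * as.numeric(n_class_dark[names(prod_frac)]))
    injected_i <- unlist(lapply(names(prod_frac), function(cl) {
      idx <- which(pool$class == cl)
      k <- min(inject_n[[cl]], length(idx))
      if (k > 0) sample(idx, k) else integer(0)
    }))
    light <- rbind(
      if (length(removed_i) > 0) dark[-removed_i, , drop = FALSE] else dark,
      pool[sort(injected_i), , drop = FALSE])
    light <- light[order(light$mass), , drop = FALSE]
    bio_removed_i <- .sample_frac_by_class(light, cfg$bio_effect$remove)
    bio <- if (length(bio_removed_i) > 0)
      light[-bio_removed_i, , drop = FALSE] else light
    # one base intensity per formula and lake, shared by the paired samples
    base <- stats::setNames(
      stats::rlnorm(length(unique(c(dark$formula, light$formula))),
                    cfg$intensity_lognormal[[1]],
                    cfg$intensity_lognormal[[2]]),
      unique(c(dark$formula, light$formula)))
    dark$base_intensity <- base[dark$formula]
    light$base_intensity <- base[light$formula]
    bio$base_intensity <- base[bio$formula]
    list(dark = dark, light = light, bio = bio,
         removed = dark$formula[removed_i],
         produced = pool$formula[sort(injected_i)],
         bio_degraded = light$formula[bio_removed_i],
         produced_ai = pool$ai_mod[sort(injected_i)])
  })
  dark_pl <- synthesize_peaklist(sets$dark, cfg,
                                 paste0(lake_id, "_dark"))
  light_pl <- synthesize_peaklist(sets$light, cfg,
                                  paste0(lake_id, "_light"))
  bio_pl <- synthesize_peaklist(sets$bio, cfg,
                                paste0(lake_id, "_bio"))
  list(lake_id = lake_id, dark = dark_pl, light = light_pl, bio = bio_pl,
       truth = list(
         dark_formulas = sets$dark$formula,
         light_formulas = sets$light$formula,
         bio_formulas = sets$bio$formula,
         produced = sets$produced,
         removed = sets$removed,
         bio_degraded = sets$bio_degraded,
         x_true = if (length(sets$produced_ai) > 0)
           mean(sets$produced_ai) else NA_real_,
         z = z))
}

.synth_spectrum <- function(sample_id, a300, s275, s350, path_m = 0.01) {
  wl <- 250:450
  knee <- 322.5
  a <- ifelse(wl <= knee,
              a300 * exp(-s275 * (wl - 300)),
              a300 * exp(-s275 * (knee - 300)) * exp(-s350 * (wl - knee)))
  absorbance_spectrum(sample_id, wl, a * path_m / 2.303, path_m)
}

.synth_eem <- function(sample_id, humic_amp, fresh_amp) {
  ex <- seq(240, 450, by = 5)
  em <- seq(280, 520, by = 4)
  g <- function(x, mu, sd) exp(-0.5 * ((x - mu) / sd)^2)
  m <- humic_amp * outer(g(ex, 255, 30), g(em, 450, 45)) +
    0.6 * humic_amp * outer(g(ex, 330, 35), g(em, 440, 40)) +
    fresh_amp * outer(g(ex, 305, 20), g(em, 382, 28)) +
    0.02
  eem(sample_id, ex, em, m)
}

#' CO2 incubation records for the factorial design
#'
#' Builds the long sample table (lakes x light/dark x 10/20 degrees x 3
#' replicates, plus sterile blanks per temperature) with cumulative headspace
#' CO2 at days 0, 7 and 28. The light/dark production ratio equals
#' `exp(rr_lake)` at both temperatures, so the sunlight-by-temperature
#' interaction is exactly null on the log scale; temperature multiplies
#' production by `temp_q10`; replicate noise is lognormal.
#'
#' @param cfg A [generator_config()].
#' @param lake_ids Lake identifiers.
#' @param rr_lake True respiration response ratio per lake.
#' @param dark_base Dark day-28 production (umol) per lake at 10 degrees.
#' @param doc,don Per-lake concentrations copied into the records.
#' @return A [sample_table()].
#' @export
synthesize_co2 <- function(cfg, lake_ids, rr_lake, dark_base, doc, don) {
  stopifnot(length(lake_ids) == length(rr_lake),
            length(lake_ids) == length(dark_base))
  .with_seed(.substream_seed(cfg$seed, "co2"), {
    rows <- list()
    for (i in seq_along(lake_ids)) {
      for (trt in c("dark", "light")) for (tmp in c(10, 20)) {
        for (rep in 1:3) {
          mu <- dark_base[i] *
            (if (trt == "light") exp(rr_lake[i]) else 1) *
            (if (tmp == 20) cfg$temp_q10 else 1)
          prod28 <- mu * stats::rlnorm(1, 0, cfg$co2_rep_cv)
          prod7 <- prod28 * cfg$co2_day7_frac
          d0 <- cfg$dic0_umol * stats::rlnorm(1, 0, 0.05)
          rows[[length(rows) + 1]] <- data.frame(
            lake_id = lake_ids[i], treatment = trt, temperature_C = tmp,
            replicate = rep,
            doc_mgC_L = doc[i], don_mg_L = don[i],
            co2_d0 = d0,
            co2_d7 = d0 + cfg$blank_drift_umol[1] + prod7,
            co2_d28 = d0 + cfg$blank_drift_umol[2] + prod28,
            is_blank = FALSE, stringsAsFactors = FALSE)
        }
      }
    }
    for (tmp in c(10, 20)) for (rep in 1:3) {
      d0 <- 2 * stats::rlnorm(1, 0, 0.05)
      rows[[length(rows) + 1]] <- data.frame(
        lake_id = "BLK", treatment = "dark", temperature_C = tmp,
        replicate = rep, doc_mgC_L = NA_real_, don_mg_L = NA_real_,
        co2_d0 = d0,
        co2_d7 = d0 + cfg$blank_drift_umol[1],
        co2_d28 = d0 + cfg$blank_drift_umol[2],
        is_blank = TRUE, stringsAsFactors = FALSE)
    }
    sample_table(do.call(rbind, rows))
  })
}

#' Generate a complete synthetic study with ground truth
#'
#' Produces every input the analysis pipeline consumes: per-lake dark, light
#' and post-incubation peak lists (composited over replicates, as FT-ICR MS
#' data are), per-replicate absorbance spectra, per-treatment EEMs, the CO2
#' incubation sample table, and a truth record sufficient to score
#' assignment, classification, differential detection and coefficient
#' recovery.
#'
#' @param cfg A [generator_config()].
#' @param dir Optional directory; when given, all inputs are written as CSV
#'   files in the package's exchange schemas (`samples.csv`, `peaks/`,
#'   `spectra/`, `eems/`).
#' @return A list: `cfg`, `samples`, `lakes` (per-lake list with peak lists
#'   and truth), `spectra` (named list), `eems` (named list), `truth`
#'   (per-lake data frame with `doc`, `don`, `z`, `x_true`, `rr_true`).
#' @export
synthesize_study <- function(cfg = generator_config(), dir = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  library <- build_formula_library(cfg)
  n <- cfg$n_lakes
  ids <- .lake_ids(n)
  chem <- .with_seed(.substream_seed(cfg$seed, "chem"), {
    u <- (seq_len(n) - 0.5) / n
    u <- sample(u)           # lake order decoupled from the DOM gradient
    doc <- cfg$doc_range[1] + diff(cfg$doc_range) * u *
      stats::rlnorm(n, 0, 0.03)
    don <- cfg$don_range[1] + diff(cfg$don_range) * u *
      stats::rlnorm(n, 0, 0.08)
    list(doc = doc, don = don)
  })
  z <- if (n >= 3) {
    pc <- dom_pc1(chem$doc, chem$don)
    pc$scores / stats::sd(pc$scores)
  } else if (n == 2) {
    as.vector(scale(chem$doc))
  } else {
    0
  }
  lakes <- lapply(seq_len(n), function(i)
    synthesize_lake_pair(i, cfg, library, z[i]))
  x_true <- vapply(lakes, function(lk) lk$truth$x_true, numeric(1))
  rr_true <- .with_seed(.substream_seed(cfg$seed, "rr"), {
    cfg$rr_center + cfg$beta_co2 * (x_true - cfg$x_center) +
      stats::rnorm(n, 0, cfg$noise_sd_co2)
  })
  samples <- synthesize_co2(cfg, ids, rr_true,
                            dark_base = cfg$co2_per_doc * chem$doc,
                            doc = chem$doc, don = chem$don)
  rank01 <- (rank(z) - 0.5) / n
  spectra <- list(); eems <- list()
  for (i in seq_len(n)) {
    a300 <- cfg$a300_range[1] + diff(cfg$a300_range) * rank01[i]
    s275_dark <- 0.0175 - 0.0025 * rank01[i]
    s350_dark <- 0.0168 - 0.0012 * rank01[i]
    .with_seed(.substream_seed(cfg$seed, "optics", i), {
      for (trt in c("dark", "light")) {
        fade <- if (trt == "light") exp(-0.25 + 0.00) else 1
        steep <- if (trt == "light") 1.12 else 1
        for (rep in 1:3) {
          sid <- sprintf("%s_%s_r%d", ids[i], trt, rep)
          spectra[[sid]] <- .synth_spectrum(
            sid,
            a300 * fade * stats::rlnorm(1, 0, 0.02),
            s275_dark * steep * stats::rlnorm(1, 0, 0.01),
            s350_dark * stats::rlnorm(1, 0, 0.01))
        }
        eid <- sprintf("%s_%s", ids[i], trt)
        eems[[eid]] <- .synth_eem(
          eid,
          humic_amp = (2 + 8 * rank01[i]) * fade,
          fresh_amp = 0.9 + 0.4 * (1 - rank01[i]))
      }
    })
  }
  truth <- data.frame(lake_id = ids, doc = chem$doc, don = chem$don,
                      z = z, x_true = x_true, rr_true = rr_true)
  study <- list(cfg = cfg, samples = samples, lakes = lakes,
                spectra = spectra, eems = eems, truth = truth)
  if (!is.null(dir)) write_study(study, dir)
  study
}

#' Read a study directory written by [write_study()]
#'
#' Rebuilds the in-memory bundle (sample table, per-lake dark/light/bio peak
#' lists, spectra, EEMs) from the CSV layout. Ground-truth records are not
#' stored on disk, so the returned bundle carries sample identities only --
#' enough to run [run_pipeline()] on real or synthetic data alike.
#'
#' @param dir Directory containing `samples.csv`, `peaks/`, `spectra/`,
#'   `eems/`.
#' @return A study bundle as from [synthesize_study()], without truth
#'   columns (`x_true`, `rr_true`, `z` are `NA`).
#' @export
read_study <- function(dir) {
  samples <- read_samples(file.path(dir, "samples.csv"))
  ids <- unique(samples$lake_id[!samples$is_blank])
  lakes <- lapply(ids, function(id) {
    out <- list(lake_id = id)
    for (kind in c("dark", "light", "bio")) {
      f <- file.path(dir, "peaks", sprintf("%s_%s.csv", id, kind))
      if (!file.exists(f))
        stop(sprintf("stage 'assign' input missing: %s", f))
      out[[kind]] <- read_peaklist(f, sprintf("%s_%s", id, kind))
    }
    out
  })
  spectra <- list()
  for (f in list.files(file.path(dir, "spectra"), full.names = TRUE)) {
    sid <- sub("\\.csv$", "", basename(f))
    spectra[[sid]] <- read_spectrum(f, sid)
  }
  eems <- list()
  for (f in list.files(file.path(dir, "eems"), full.names = TRUE)) {
    eid <- sub("\\.csv$", "", basename(f))
    eems[[eid]] <- read_eem(f, eid)
  }
  truth <- data.frame(lake_id = ids, doc = NA_real_, don = NA_real_,
                      z = NA_real_, x_true = NA_real_, rr_true = NA_real_)
  for (id in ids) {
    sub <- samples[samples$lake_id == id, ]
    truth$doc[truth$lake_id == id] <- sub$doc_mgC_L[1]
    truth$don[truth$lake_id == id] <- sub$don_mg_L[1]
  }
  list(cfg = NULL, samples = samples, lakes = lakes, spectra = spectra,
       eems = eems, truth = truth)
}

#' Write a synthetic study bundle to disk
#'
#' @param study Result of [synthesize_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(file.path(dir, "peaks"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "spectra"), showWarnings = FALSE)
  dir.create(file.path(dir, "eems"), showWarnings = FALSE)
  write_table(as.data.frame(study$samples), file.path(dir, "samples.csv"))
  for (lk in study$lakes) {
    for (kind in c("dark", "light", "bio"))
      write_table(lk[[kind]],
                  file.path(dir, "peaks",
                            sprintf("%s_%s.csv", lk$lake_id, kind)))
  }
  for (sid in names(study$spectra))
    write_table(study$spectra[[sid]],
                file.path(dir, "spectra", paste0(sid, ".csv")))
  for (eid in names(study$eems))
    write_table(study$eems[[eid]],
                file.path(dir, "eems", paste0(eid, ".csv")))
  invisible(dir)
}
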