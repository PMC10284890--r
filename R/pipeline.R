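# End-to-end orchestration: simulate -> assign -> indices -> optics -> diff
# -> respond. Stage outputs are pure functions of (inputs, config); rerunning
# with the same config reproduces identical tables.

.mean_or_na <- function(x) if (length(x) == 0) NA_real_ else mean(x)

#' Run the full photo-bio degradation analysis pipeline
#'
#' Takes a synthetic study bundle (or generates one from `cfg`), assigns
#' molecular formulas to every peak list, computes molecular and optical
#' indices, partitions formulas into photo-produced/photo-degraded (dark vs
#' light) and bio-degraded (light vs post-incubation) sets by both the
#' dual-threshold and presence/absence methods, computes blank-corrected CO2
#' production, response ratios, the DOM-content PC1, and the standardized
#' regression coefficients linking the respiration response ratio to DOM
#' content and to the aromaticity of photo-produced compounds.
#'
#' @param cfg A [generator_config()] (also carries `tol_ppm`, `snr_min`,
#'   `diff_frac`).
#' @param study Optional pre-built [synthesize_study()] bundle; generated
#'   from `cfg` when `NULL`.
#' @param out_dir Optional directory: per-stage CSV tables and a plain-text
#'   run log are written there.
#' @param day Incubation day used for respiration (default 28).
#' @return A list with elements `lake_summary` (per-lake data frame:
#'   DOM score, optical indices and their response ratios, CO2 production
#'   means, `co2_rr`, mean AImod/H-C of the photo-produced set, truth
#'   columns), `coefficients` (standardized coefficients of `co2_rr` on the
#'   main drivers), `anova` (three-way factorial table on log CO2
#'   production), `overlap` (PP/PD/BD aromaticity overlap per lake),
#'   `concordance` (threshold vs presence/absence), `dom_pca`, `assignment`
#'   (per-sample assignment counters) and `study`.
#' @export
run_pipeline <- function(cfg = generator_config(), study = NULL,
                         out_dir = NULL, day = 28) {
  if (is.null(study)) study <- synthesize_study(cfg)
  samples <- study$samples
  ids <- study$truth$lake_id

  ann <- list()
  counters <- list()
  for (lk in study$lakes) {
    for (kind in c("dark", "light", "bio")) {
      key <- paste0(lk$lake_id, "_", kind)
      a <- assign_peaklist(lk[[kind]], tol_ppm = cfg$tol_ppm,
                           snr_min = cfg$snr_min)
      ann[[key]] <- a
      rr <- a$assignments$rejection_reason
      counters[[key]] <- data.frame(
        sample = key, peaks = nrow(a$assignments),
        assigned = sum(is.na(rr)),
        low_snr = sum(rr == "low_snr", na.rm = TRUE),
        no_candidate = sum(rr == "no_candidate", na.rm = TRUE),
        ambiguous = sum(rr == "ambiguous", na.rm = TRUE))
    }
  }
  counters <- do.call(rbind, counters)
  rownames(counters) <- NULL

  photo_thr <- list(); photo_pa <- list(); bio_thr <- list()
  pp_ai <- list(); pd_ai <- list(); bd_ai <- list()
  for (id in ids) {
    dk <- ann[[paste0(id, "_dark")]]
    lt <- ann[[paste0(id, "_light")]]
    bo <- ann[[paste0(id, "_bio")]]
    photo_thr[[id]] <- compare_threshold(dk, lt, frac = cfg$diff_frac)
    photo_pa[[id]] <- compare_presence_absence(dk, lt)
    bio_thr[[id]] <- compare_threshold(lt, bo, frac = cfg$diff_frac)
    tab <- photo_thr[[id]]$table
    pp_ai[[id]] <- tab$ai_mod[tab$status == "produced"]
    pd_ai[[id]] <- tab$ai_mod[tab$status == "degraded"]
    btab <- bio_thr[[id]]$table
    bd_ai[[id]] <- btab$ai_mod[btab$status == "degraded"]
  }
  overlap <- set_overlap_analysis(pp_ai, pd_ai, bd_ai)
  concordance <- method_concordance(photo_thr, photo_pa)

  # optical indices: per lake x treatment means over replicate spectra
  opt <- list()
  for (id in ids) {
    doc <- samples$doc_mgC_L[samples$lake_id == id][1]
    for (trt in c("dark", "light")) {
      reps <- grep(sprintf("^%s_%s_r", id, trt), names(study$spectra),
                   value = TRUE)
      rows <- do.call(rbind, lapply(reps, function(sid)
        optical_summary(study$spectra[[sid]], doc,
                        study$eems[[sprintf("%s_%s", id, trt)]])))
      opt[[paste0(id, "_", trt)]] <-
        cbind(data.frame(lake_id = id, treatment = trt),
              as.data.frame(t(colMeans(rows))))
    }
  }
  opt <- do.call(rbind, opt)
  rownames(opt) <- NULL

  # respiration: blank-corrected production, treatment means pooled over
  # temperatures (the sunlight x temperature interaction is treated as null)
  blanks <- samples[samples$is_blank, , drop = FALSE]
  nonblank <- samples[!samples$is_blank, , drop = FALSE]
  prod <- vapply(seq_len(nrow(nonblank)), function(i) {
    rec <- nonblank[i, ]
    bl <- blanks[blanks$temperature_C == rec$temperature_C, , drop = FALSE]
    blm <- as.list(colMeans(bl[, c("co2_d0", "co2_d7", "co2_d28")]))
    co2_production(rec, blm, day = day)
  }, numeric(1))
  nonblank$production <- prod

  lake_rows <- lapply(ids, function(id) {
    sub <- nonblank[nonblank$lake_id == id, ]
    m_light <- mean(sub$production[sub$treatment == "light"])
    m_dark <- mean(sub$production[sub$treatment == "dark"])
    tabp <- photo_thr[[id]]$table
    pp <- tabp[tabp$status == "produced", , drop = FALSE]
    g <- function(trt, var) opt[[var]][opt$lake_id == id &
                                         opt$treatment == trt]
    data.frame(
      lake_id = id,
      doc_mgC_L = sub$doc_mgC_L[1], don_mg_L = sub$don_mg_L[1],
      co2_light = m_light, co2_dark = m_dark,
      co2_rr = response_ratio(m_light, m_dark),
      a300_dark = g("dark", "a300_per_m"),
      sr_dark = g("dark", "sr"),
      a300_rr = response_ratio(g("light", "a300_per_m"),
                               g("dark", "a300_per_m")),
      suva254_rr = response_ratio(g("light", "suva254"),
                                  g("dark", "suva254")),
      sr_rr = response_ratio(g("light", "sr"), g("dark", "sr")),
      aimod_pp = .mean_or_na(pp$ai_mod),
      hc_pp = .mean_or_na(pp$hc),
      dbe_pp = .mean_or_na(pp$dbe),
      nosc_pp = .mean_or_na(pp$nosc),
      n_produced = nrow(pp),
      n_degraded = sum(tabp$status == "degraded"))
  })
  lake_summary <- do.call(rbind, lake_rows)
  pc <- dom_pc1(lake_summary$doc_mgC_L, lake_summary$don_mg_L)
  lake_summary$dom_pc1 <- pc$scores
  lake_summary <- merge(lake_summary, study$truth[, c("lake_id", "x_true",
                                                      "rr_true", "z")],
                        by = "lake_id", sort = FALSE)

  drivers <- c(dom_pc1 = "dom_pc1", aimod_pp = "aimod_pp", hc_pp = "hc_pp",
               dbe_pp = "dbe_pp", nosc_pp = "nosc_pp",
               a300_dark = "a300_dark", sr_rr = "sr_rr")
  coefficients <- do.call(rbind, lapply(names(drivers), function(nm) {
    x <- lake_summary[[drivers[[nm]]]]
    y <- lake_summary$co2_rr
    if (sum(is.finite(x) & is.finite(y)) < 3 ||
        stats::sd(x, na.rm = TRUE) == 0)
      return(data.frame(driver = nm, coef = NA_real_, p_value = NA_real_,
                        r2 = NA_real_, n = sum(is.finite(x))))
    sc <- standardized_coef(x, y)
    data.frame(driver = nm, coef = sc$coef, p_value = sc$p_value,
               r2 = sc$r2, n = sc$n)
  }))

  anova_tab <- nonblank
  anova_tab$response <- log(pmax(anova_tab$production, 1e-6))
  names(anova_tab)[names(anova_tab) == "lake_id"] <- "lake"
  names(anova_tab)[names(anova_tab) == "temperature_C"] <- "temperature"
  anova_res <- factorial_anova(anova_tab,
                               c("treatment", "temperature", "lake"))

  result <- list(lake_summary = lake_summary, coefficients = coefficients,
                 anova = anova_res, overlap = overlap,
                 concordance = concordance, dom_pca = pc,
                 optical = opt, assignment = counters,
                 differential = list(photo = photo_thr,
                                     photo_presence = photo_pa,
                                     bio = bio_thr),
                 study = study)
  if (!is.null(out_dir)) .write_pipeline(result, cfg, out_dir)
  result
}

.write_pipeline <- function(result, cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table(result$lake_summary, file.path(out_dir, "lake_summary.csv"))
  write_table(result$coefficients, file.path(out_dir, "coefficients.csv"))
  write_table(result$anova, file.path(out_dir, "anova.csv"))
  write_table(result$overlap, file.path(out_dir, "overlap.csv"))
  write_table(result$optical, file.path(out_dir, "optical.csv"))
  write_table(result$assignment, file.path(out_dir, "assignment.csv"))
  diffs <- do.call(rbind, lapply(names(result$differential$photo),
    function(id) {
      tab <- result$differential$photo[[id]]$table
      cbind(data.frame(lake_id = id), tab)
    }))
  write_table(diffs, file.path(out_dir, "photodiff.csv"))
  log_lines <- c(
    sprintf("domphoto pipeline run %s", format(Sys.time(), "%Y-%m-%dT%H:%M")),
    sprintf("package version: %s",
            as.character(utils::packageVersion("domphoto"))),
    sprintf("seed: %d", cfg$seed),
    sprintf("n_lakes: %d  formulas_per_lake: %d", cfg$n_lakes,
            cfg$formulas_per_lake),
    sprintf("tol_ppm: %g  snr_min: %g  diff_frac: %g", cfg$tol_ppm,
            cfg$snr_min, cfg$diff_frac))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
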