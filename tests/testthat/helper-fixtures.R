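# Small in-code fixtures shared across test files.

write_csv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# a tiny annotated sample built directly from formulas and intensities
make_annotated <- function(id, comps, intensity) {
  f <- do.call(molecular_formula, as.list(as.data.frame(comps)))
  annotated_sample(id, f, intensity)
}

# fixture panel of well-known compositions (c, h, o, n, s)
panel_comps <- data.frame(
  c = c(1, 1, 6, 6, 16, 16, 8, 10),
  h = c(4, 0, 6, 12, 10, 32, 8, 8),
  o = c(0, 2, 0, 6, 0, 2, 3, 0),
  n = 0, s = 0
)
# CH4, CO2, benzene, glucose, pyrene, palmitic acid, vanillin-like, C10H8

small_sample_table <- function() {
  data.frame(
    lake_id = rep(c("A", "B"), each = 6),
    treatment = rep(rep(c("light", "dark"), each = 3), 2),
    temperature_C = 10,
    replicate = rep(1:3, 4),
    doc_mgC_L = 8, don_mg_L = 0.5,
    co2_d0 = 5, co2_d7 = 12, co2_d28 = 25,
    is_blank = FALSE
  )
}
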