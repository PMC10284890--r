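Package: domphoto
Title: Coupled Photochemical and Biological Degradation Analysis of
    Dissolved Organic Matter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the coupled photochemical and microbial
    degradation of dissolved organic carbon (DOC) in lake water. Assigns
    CHONS molecular formulas to negative-mode FT-ICR MS peak lists under
    elemental-ratio constraints with least-heteroatom disambiguation,
    computes per-formula molecular indices (double bond equivalence, nominal
    oxidation state of carbon, modified aromaticity index) and the four-class
    compound taxonomy (polycyclic aromatics, polyphenols, highly unsaturated
    and phenolic, aliphatic), derives CDOM absorption indices (Napierian
    absorption coefficient, SUVA254, spectral slopes and their ratio) and
    FDOM fluorescence indices (BIX, HIX) from spectra and excitation-emission
    matrices, partitions formulas into photo-produced, photo-degraded and
    bio-degraded sets from paired light/dark comparisons, and links
    photochemical shifts to microbial respiration through log response
    ratios, DOM-content principal components, standardized regression
    coefficients and factorial ANOVA. Includes a fully seeded synthetic-study
    generator with ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
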