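Package: nacdyn
Title: Mechanically Coupled Tumor Growth Modeling of Breast Cancer Response
    to Neoadjuvant Chemotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates triple-negative breast cancer response to neoadjuvant
    chemotherapy with a mechanically coupled reaction-diffusion model of tumor
    cell density. Tumor cell mobility is inhibited by growth-induced mechanical
    stress (quasistatic linear elasticity with Winkler-type boundary support),
    and net proliferation is modulated by a normalized two-drug MuSyC
    pharmacodynamic surface driven by perfusion-weighted exponential
    pharmacokinetics. Includes generators for synthetic tissue-box scenarios,
    standard two-drug regimen calendars, quantities of interest (tumor volume,
    cell count, mean relative difference), a Saltelli/Jansen variance-based
    global sensitivity analysis with Latin hypercube sampling and bootstrap
    confidence intervals, and original-versus-reduced-model comparison
    machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    RNifti,
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
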