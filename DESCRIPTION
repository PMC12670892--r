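Package: ancreach
Title: Gestational-Age Window Reachability from Sparse Antenatal-Care Registers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the proportion of pregnant women reachable for maternal
    vaccination inside candidate gestational-age (GA) windows when antenatal-care
    (ANC) registers record only each woman's total contact count and the GA at her
    first and last contact. Implements exclusion filtering with data accounting,
    three interpolation strategies for the unobserved contacts (none, even, and
    uniform random with an exact closed-form reach probability), pooled and
    inverse-probability-normalized multi-country combination, stratified summary
    tables with weighted quantiles, and a multi-country synthetic cohort generator
    with register-truncation and data-error emulation for validating the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
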