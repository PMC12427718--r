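Package: teleaccess
Title: Spatial Healthcare Accessibility and Tele-Health Resource Allocation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements an improved two-step floating catchment area method
    with tele-health (i2SFCA-TH) for measuring spatial accessibility of
    chronic-disease care in metropolitan districts, combining community
    hospital supply, referral to tertiary-A hospitals, and distance-free
    online consultations. Includes equity statistics (accessibility gap,
    equilibrium index, population-weighted Gini), an equity-constrained
    linear program that allocates tertiary physician time to online service
    so as to maximize mean accessibility subject to a bound on the
    equilibrium index, a brute-force grid oracle for verifying the
    optimizer, and a seeded generator of synthetic center-periphery
    metropolitan instances for fully reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    boot,
    geosphere,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
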