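Package: nitrateRisk
Title: Deterministic and Probabilistic Health Risk Assessment of Nitrate in Groundwater
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-carcinogenic health risk assessment of nitrate in drinking
    water. Computes estimated daily intake (EDI = Cf*Cd/Bw) and hazard
    quotients (HQ = EDI/RFD) for configurable exposure groups (infants,
    children, teenagers, adults), propagates input uncertainty through a
    Monte-Carlo simulation engine with percentile and contribution-to-variance
    sensitivity reporting, interpolates well concentrations onto regular grids
    by inverse-distance weighting (IDW) with ESRI-ASCII and GeoJSON output,
    and generates synthetic well networks for validation. Ships the 66-sample
    Iranshahr (Iran) groundwater nitrate survey as a reference dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    fitdistrplus,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
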