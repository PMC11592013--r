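Package: osteoimpact
Title: Explicit-Dynamics Finite Elements for Craniofacial Bone Impact
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates blunt impact on layered cortical/trabecular bone with
    an explicit central-difference finite-element solver. Bone is modelled as
    rate-dependent elastoplastic material (multilinear J2 hardening with
    Cowper-Symonds strain-rate scaling), with ductile damage initiation from a
    rate-dependent onset-strain table, fracture-energy-regularised softening
    and element deletion. A rigid cylindrical impactor loads the mesh through
    an exponential pressure-overclosure contact law (a skin surrogate) with
    regularised Coulomb friction. Includes a synthetic-geometry generator for
    two-layer bone plates and arches, SAE J211 channel-class filtering of
    force histories, damage-field post-processing and VTU/CSV/JSON output.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    signal,
    igraph,
    xml2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
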