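Package: steerpmf
Title: Free-Energy and Entropy Reconstruction from Bidirectional Steered Pulling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Work accounting, potential-of-mean-force reconstruction and
    time-windowed quasiharmonic configurational entropy for constant-velocity
    harmonic pulling ("steered") simulations run in both the unbinding and
    binding directions.  Implements the nonequilibrium estimator ladder
    (Jarzynski forward/reverse, Bennett acceptance ratio, Minh-Adib and
    Chelli-Procacci style bidirectional free-energy curves, Hummer-Szabo and
    bidirectional WHAM-type unbiasing to G(xi)), basin/barrier analysis of the
    resulting profiles, Schlitter and quantum quasiharmonic entropies from
    mass-weighted coordinate covariances with a sliding-window scheme, and
    geometric interaction profiles (hydrogen bonds, water bridges, hydrophobic
    pairs, radius of gyration, torsions).  A self-contained overdamped
    Langevin pulling simulator with analytically known free-energy profiles
    provides ground-truth validation data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    bio3d,
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
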