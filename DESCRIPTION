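Package: ctxnet
Title: Context-Integrating Convolutional Classifiers for Ambiguous Stimuli
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for studying how surrounding context resolves
    ambiguous visual stimuli in a convolutional classifier. Binary letter glyphs
    and hand-designed ambiguous hybrids (e.g. a glyph readable as either A or H)
    are stacked together with weighted, optionally noisy flanking context letters
    into multi-channel cuboid inputs. A convolutional network with cuboid filters
    spanning all channels extracts coupled target-context features; a literal
    equation-by-equation reference forward pass verifies the fast trainable
    implementation. Experiment drivers reproduce context-shift-decrement and
    context-reinstatement phenomena: congruent, attenuated, noisy and flipped
    context conditions over a grid of stimulus noise levels, with Monte Carlo
    averaging over network initialisations and noise draws.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
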