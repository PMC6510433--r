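Package: catmetric
Title: Categorical Colour Metrics from Colour-Naming Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving a Riemannian "categorical" metric on colour
    space from population colour-naming data. Fits penalized unimodal
    response-rate functions for each colour name, turns the fitted naming
    distributions into a metric tensor field via the information geometry of
    square-rooted distributions (Bhattacharyya angles), and analyses the
    resulting geometry: path lengths and capacities in natural categorical
    units (grains), distortion against standard colour-difference formulas
    (CIE76, CIE94, CIEDE2000), plane restrictions, and isometric embeddings.
    Includes readers and descriptive statistics for colour-naming response
    tables and synthetic-data generators so the full pipeline can be
    exercised without access to a naming survey.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
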