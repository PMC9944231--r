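Package: regenworm
Title: Self-Repairing In Silico Worm with Perceptron Damage Detection
    and an Associative Bioelectric Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale simulator of a planarian-like synthetic worm
    that autonomously restores both its anatomy and its body-wide
    bioelectric pattern after arbitrary damage.  The worm is a 2D lattice
    of 3750 somatic cells organised in 5x5 blocks, each anchored by one
    of 150 stem cells.  Three trained perceptron communication motifs
    (corner, border, interior) let every cell detect missing neighbours
    from binarised membrane-voltage presence; an organism-wide stem-cell
    network classifies damage with three pattern primitives; and a
    13-node associative memory network (a sparsified Hopfield variant
    with head-to-tail activation and tail-to-head inhibition) stores the
    homeostatic voltage gradient as an attractor and restores it after
    perturbation or repair.  Deterministic damage operators (voltage
    perturbation, cell ablation, region kills, cut planes) and a
    five-stage control loop reproduce recovery from single-cell loss up
    to full head/body/tail amputation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
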