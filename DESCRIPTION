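Package: specbind
Title: Multispectroscopic Analysis of Small-Molecule Binding to Serum Albumin
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates protein-ligand binding parameters from titration
    spectroscopy. Implements Stern-Volmer fluorescence quenching analysis
    with mechanism classification, the double-logarithmic binding isotherm
    (binding constant and site number), Van't Hoff thermodynamics with
    Ross-Subramanian interaction-force classification, competitive
    site-marker displacement calls, Benesi-Hildebrand double-reciprocal
    fitting of UV absorbance titrations, and alpha-helix content from
    circular-dichroism mean residue ellipticity. Includes peak and shift
    extraction for emission series, synchronous-fluorescence slices and
    excitation-emission matrices, forward-model generators for every input
    so each estimator is testable by parameter recovery, and a study
    orchestrator that produces a structured result bundle and report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
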