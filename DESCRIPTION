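Package: quenchbind
Title: Fluorescence Quenching, Binding Thermodynamics and Site Competition for Protein-Ligand Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis of spectroscopic protein-ligand binding titrations:
    inner-filter-effect correction of fluorescence emission series,
    Stern-Volmer quenching analysis with mechanism classification,
    double-logarithm binding fits (binding constant and site number),
    van't Hoff thermodynamics with binding-force classification,
    far-UV circular dichroism helicity estimation, and site-marker
    competition analysis for serum-albumin drug sites. Includes a
    synthetic-data generator with known ground truth so every stage of
    the pipeline can be validated without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, grDevices, utils, yaml, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
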