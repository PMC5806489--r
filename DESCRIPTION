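Package: dmvscan
Title: Detection, Classification and Annotation of DNA Methylation Valleys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls DNA methylation valleys (DMVs) -- large (>= 5 kb)
    hypomethylated domains -- from per-CpG bisulfite methylation calls using
    a binned sliding-window scan, classifies them into constant (group I)
    and dynamic (group II/III) valleys from tissue-lineage methylation and
    expression, annotates them against CpG islands, histone-mark peaks and
    super-enhancers, quantifies wild-type versus knockout methylation change
    on CpG-island and non-island valley parts, and profiles transcription
    factor binding-site density against length-matched random controls.
    Includes a seeded synthetic methylome generator with known truth for
    validation, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    IRanges,
    S4Vectors,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
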