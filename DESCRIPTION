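Package: sonoAgree
Title: Inter-Rater Agreement Analysis for Multi-Annotator Ultrasound Structure Annotation
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies agreement between multiple human annotators and an AI
    annotator on anatomical-structure annotations over ultrasound scans, as used
    in evaluations of assistive AI for ultrasound-guided regional anaesthesia.
    Region structures (arteries, muscles, nerves) drawn as closed polygons are
    compared with the Dice overlap coefficient on rasterized masks; fascial and
    serosal planes drawn as open polylines are compared with an image-size
    normalized Hausdorff distance. Includes curation and grouping rules with a
    full annotation-accounting audit, pooled pairwise human-human versus
    AI-human summary tables, pixel-vote consensus maps with AI overlay export,
    aggregation of qualitative expert assessments (accuracy, risk modification,
    subjective scores), and a seeded synthetic multi-annotator study generator
    so the whole pipeline is testable without access to any study's raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, grDevices, jsonlite, yaml, png
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'geometry.R'
    'manifest.R'
    'annotations.R'
    'curation.R'
    'agreement.R'
    'consensus.R'
    'pipeline.R'
    'qualitative.R'
    'simulate.R'
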