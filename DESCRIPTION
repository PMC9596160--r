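Package: arborquant
Title: Quantification of Sensory Axon Arbors, Intracellular Transport and
    Zebrafish Behavior
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the development of zebrafish Rohon-Beard
    sensory axon arbors and the behavior of larval and adult fish.
    Provides structure-tensor orientation profiling of fluorescent arbor
    images with tubeness pre-filtering and AUC-based group comparison,
    branch density and branch-dynamics statistics (initiation rates, loss
    ratios, growth velocity, rose histograms, sister-branch angles,
    fasciculation and midline-crossing metrics), kymograph construction
    and automated particle-track extraction for EB3 comet and Rab5
    vesicle transport, photoactivation accumulation analysis, and
    operationally defined larval touch-response and adult novel-tank
    metrics. A seeded synthetic-data module generates arbor images,
    particle movies, branch-event tables and swim trajectories with known
    ground truth so that every estimator can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, CellBiology, Neuroscience, Visualization
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'arborquant-package.R'
    'behavior.R'
    'branchmetrics.R'
    'kymo.R'
    'orientation.R'
    'pipeline.R'
    'simulate-arbor.R'
    'simulate-events.R'
    'simulate-movie.R'
    'simulate-trajectory.R'
    'utils-internal.R'
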