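Package: murivfss
Title: Videofluoroscopic, Endoscopic, Histological and Home-Cage Analysis
    of Murine Feeding and Swallowing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of feeding, swallowing and upper-airway
    function in mouse models of dysphagia. Converts marker-tracked video of
    fluoroscopic drinking/eating episodes into calibrated jaw-gape traces and
    computes licking and mastication kinematics (lick rate, inter-lick
    interval, swallow rate, lick-swallow ratio, pharyngeal transit time, jaw
    opening/closing velocities). Tracks left and right glottal edges relative
    to the dorsal commissure in endoscopic video and computes laryngeal motion
    metrics (motion range ratio, open-close cycle ratio, motion correlation
    coefficient, vocal-fold angle, respiratory rate) plus laryngeal adductor
    reflex duration. Quantifies lung inflammation from H&E histology by color
    enhancement and luminance thresholding, measures mandible landmark
    distances, summarizes 72 h home-cage behavior logs in 24 h bins, and
    provides the group statistics layer (independent t-tests with mean +/- SEM,
    two-way genotype-by-side ANOVA). Includes seeded synthetic-data generators
    for every input modality so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    jsonlite,
    car,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
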