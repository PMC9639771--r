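Package: neuromech
Title: Linking Motor Unit Discharge, Muscle Fascicle Kinematics and Joint Torque
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to relate modulations in motor unit discharge to changes in
    muscle fascicle length and joint torque during isometric contractions.
    Builds cumulative spike trains from decomposed motor unit discharge times,
    conditions neural, kinematic and kinetic signals into a common fluctuation
    band with zero-phase Butterworth filtering, estimates windowed
    cross-correlation coefficients and electromechanical delays between all
    signal pairings, tracks fascicle geometry through B-mode image sequences
    with pyramidal Lucas-Kanade affine optical flow, and expresses motor unit
    recruitment and de-recruitment thresholds in both torque (%MVC) and
    fascicle-shortening coordinates. A deterministic synthetic-experiment
    generator (motoneuron pool, delayed muscle mechanics, multichannel surface
    EMG, speckle ultrasound frames and a synchronization trigger) provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'filters.R'
    'simdata-config.R'
    'simdata-pool.R'
    'simdata-mechanics.R'
    'simdata-emg.R'
    'simdata-ultrasound.R'
    'simdata-trial.R'
    'spiketools.R'
    'sil.R'
    'muap.R'
    'fastrack.R'
    'xcorrlag.R'
    'thresholds.R'
    'study.R'
    'io.R'
    'neuromech-package.R'
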