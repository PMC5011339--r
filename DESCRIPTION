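Package: mrgfus
Title: Closed-Loop MR-Guided Focused Ultrasound Thermometry, Dosimetry and Control
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Hardware-free implementation of the software stack of a
    preclinical MR-guided focused ultrasound (MRgFUS) hyperthermia system:
    proton-resonance-frequency (PRF) shift MR thermometry with ROI-based
    field-drift correction, CEM43 thermal-dose accounting with automatic
    shut-off, a clamped PID controller for closed-loop focal temperature
    control, and MR acoustic radiation force imaging (MR-ARFI) displacement
    reconstruction.  A built-in virtual rig (Pennes bioheat tissue plant,
    virtual transducer, synthetic MR scanner with noise and field drift)
    closes the loop so the whole treatment chain can be exercised, tested
    and demonstrated without a magnet.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
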