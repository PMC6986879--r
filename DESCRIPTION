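Package: prpdecode
Title: Phase-Referenced Oscillatory Power and Decoding of Odorant Identity
        from Olfactory-Bulb Local Field Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Analysis pipeline for trial-based multi-electrode local field
        potential (LFP) recordings from go/no-go odor discrimination
        sessions. Quantifies theta phase-amplitude coupling with the 51-bin
        Kullback-Leibler modulation index, extracts theta phase-referenced
        beta and high-gamma wavelet power (PRP), decodes contextual odorant
        identity per 0.1 s time bin with leave-one-out linear discriminant
        analysis against a label-shuffle control, estimates behavioral and
        neural decision times from rank-sum p-value time courses, and
        measures participation-ratio dimensionality of the electrode space.
        Includes a synthetic-session generator with configurable coupling
        strength and phase jitter, odorant- and learning-dependent power
        gains, latent-source mixing, and divergent lick trains, so the
        whole pipeline can be exercised end-to-end and validated against
        generator ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, signal, jsonlite, nortest
Suggests: testthat (>= 3.0.0), MASS, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'behavior.R'
    'decision.R'
    'decoding.R'
    'dimensionality.R'
    'filters.R'
    'inference.R'
    'morlet.R'
    'pac.R'
    'pipeline.R'
    'prp.R'
    'prpdecode-package.R'
    'session-io.R'
    'simulate.R'
    'utils.R'
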