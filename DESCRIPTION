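Package: cryolink
Title: Particle Re-Centering and Crosslink-Based Validation for Cryo-EM Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two recurring tasks in single-particle cryo-EM of
    flexible multi-subunit complexes. First, class-average-guided
    re-centering of particle coordinates: a region-of-interest offset
    recorded on a 2D class average is rotated back through each particle's
    in-plane alignment (origin shift and psi angle) to produce new
    micrograph coordinates centered on that region, enabling segmented
    re-extraction and refinement of flexible assemblies. STAR particle
    tables in both the legacy single-table and optics-grouped RELION
    dialects are read and written round-trip safe. Second, structural
    validation of a model by crosslinking mass spectrometry: crosslink
    identifications are mapped to residue numbers, deduplicated,
    target-decoy FDR filtered, measured as C-alpha to C-alpha distances
    against PDB or mmCIF coordinates, classified as satisfied, violated or
    unresolved, and exported as pseudobond scripts and network tables. A
    transcription of the published intersubunit crosslink table for the
    human augmin (HAUS) octamer is included as a worked example, together
    with seeded synthetic-data generators for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
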