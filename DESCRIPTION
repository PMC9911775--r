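Package: mmhash
Title: Consistency-Preserving Cross-Modal Hashing on Multiple Manifolds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns compact binary hash codes for strongly paired multi-modal
    data (for example T1-weighted MRI and PET slices of the same subjects) so
    that one modality can be used to retrieve semantically similar samples of
    another in Hamming space. Implements heterogeneous, homogeneous and
    multi-manifold similarity constructions with a heat-kernel modified
    distance, a multi-semantic consistency loss, a multi-manifold
    similarity-preserving loss with its Laplacian-embedding counterpart, a
    quantization regularizer, an asymmetric auto-encoder with per-modality
    (pseudo-Siamese) encoders, a shared light decoder and two
    semantics-preserving attention branches, a three-stage Adam training
    schedule, and mean-average-precision retrieval evaluation. Includes a
    seeded generator of paired multi-modal synthetic data with class-conditional
    sub-manifold structure, TSV/JSON interchange formats and optional NIfTI
    single-slice ingestion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
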