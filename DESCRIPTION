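Package: restkit
Title: Resting-State fMRI Metrics, Preprocessing and Voxel-Wise Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable toolkit for resting-state BOLD fMRI analysis:
    linear detrending, ideal rectangle-window bandpass filtering, nuisance
    covariate regression, seed-based functional connectivity (Pearson and
    partial correlation, Fisher z), regional homogeneity (Kendall's
    coefficient of concordance over 7/19/27-voxel neighbourhoods), amplitude
    of low-frequency fluctuation (ALFF) and its fractional variant (fALFF),
    voxel-wise group statistics (one-sample, two-sample and paired t-tests,
    one-way ANOVA/ANCOVA, correlation with image covariates),
    multiple-comparison correction by Benjamini-Hochberg FDR and Monte-Carlo
    cluster-extent simulation, an image-expression calculator, and a
    synthetic 4D fixture generator. Volumes are read and written in NIfTI-1
    (.nii, .nii.gz, .hdr/.img pairs) and ANALYZE 7.5 formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
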