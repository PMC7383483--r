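Package: supradent3d
Title: Three-Dimensional Morphometry and Positional Classification of
    Impacted Supernumerary Teeth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Landmark-based three-dimensional analysis of impacted
    supernumerary teeth as seen in cleidocranial dysplasia. Builds
    occlusal/sagittal/frontal reference planes and arch-local tooth axes
    from named dental landmarks, measures crown and root lengths, crown
    diameters, tooth-axis inclination, cusp number and crown type,
    identifies supernumerary/permanent members of impacted pairs by root
    length, classifies each supernumerary tooth's position (coronal/apical,
    mesial/distal, labial/lingual) and axial direction relative to its
    adjacent permanent tooth, and compares groups with an exact tie-aware
    Wilcoxon signed-rank test, z-scores against norm tables, Dahlberg
    error and intraclass correlation. Includes a synthetic dentition
    generator with known ground truth and a CBCT-like voxel phantom
    renderer with threshold segmentation for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
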