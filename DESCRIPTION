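Package: labseg
Title: Landmark-Based Automated Brainstem Segmentation for T1-Weighted MRI
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@labseg.org",
           role = c("aut", "cre"))
Description: Fully automated segmentation of the human brainstem into midbrain
    and pons from 3D T1-weighted magnetic resonance images. The pipeline
    locates the mid-sagittal plane by tracking the corpus callosum and
    minimizing the upper-brainstem cross-sectional area, derives the
    anatomical landmarks of the Oba/Luft parcellation scheme (pontine
    notches, quadrigeminal plate, mammillary body) on that slice, and carves
    the two subregions with the resulting cut planes using corrected Otsu
    thresholding and connected-component selection on 0.5 mm resampled
    slices. Includes the standard overlap and distance evaluation metrics
    (Dice coefficient, absolute volume difference, modified Hausdorff
    distance), a synthetic T1-like head phantom generator with voxel-exact
    ground truth for validation, NIfTI-1 input/output, isotropic resampling,
    optional mutual-information rigid registration, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    RNifti,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
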