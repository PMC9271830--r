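Package: tumorfract
Title: Morphological and Fractal Characterization of Tumor Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scaling and fractal analysis of brain-tumor interfaces extracted
    from segmented volumetric images. Provides dynamic quantum clustering
    segmentation of image digital levels (Parzen density, Schrodinger
    potential, dissipative Langevin evolution and the two-pass trap-potential
    scheme), interface extraction and cylindrical parameterization,
    box-counting fractal dimension and gliding-box lacunarity, interface-width
    roughness scaling under the Family-Vicsek ansatz, surface-regularity and
    shape-anisotropy measures, natural visibility graphs of angularly ordered
    radius series, and one- and two-dimensional multifractal (partition
    function and detrended fluctuation) analysis. A synthetic-data module
    generates rough self-affine tumor surfaces, intensity mixtures, fractional
    Brownian series, binomial cascades and Koch curves with known ground truth
    for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
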