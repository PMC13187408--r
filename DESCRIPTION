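Package: edofco
Title: End-to-End Co-Design of Extended Depth-of-Field Meta-Optics for
    Multispectral Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A differentiable scalar Fourier-optics simulator for wide-field
    fluorescence microscopy with a learnable meta-optic phase element at the
    pupil plane. Provides space-bandwidth and Fourier-plane sampling planners,
    depth- and wavelength-resolved point spread function (PSF) and modulation
    transfer function (MTF) computation, a nanopillar width-to-phase spectral
    lookup with a surrogate unit-cell library, an MTF-guided extended
    depth-of-field pre-optimization of the meta-optic, a compact encoder-decoder
    reconstruction network with Fourier-domain channel attention, and a joint
    optics-plus-network training loop driven by a built-in reverse-mode
    automatic differentiation engine. Synthetic multispectral fluorescence
    phantoms (nuclei, filaments, membranes, puncta) make the whole pipeline
    runnable at desk scale without external data. PSF metrology (Gaussian-fit
    FWHM), PSNR/SSIM depth sweeps and an ablation harness support evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    tiff,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
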