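Package: ambientsom
Title: Learning Stochastic Object Models from Noisy Imaging Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for establishing stochastic object models (SOMs) from noisy,
    possibly undersampled, simulated imaging measurements with ambient
    generative adversarial networks trained multiresolution-style. Provides a
    stylized Fourier-space (MRI-like) measurement model with Cartesian
    undersampling and complex Gaussian noise, zero-filled pseudoinverse,
    real-part and magnitude reconstructions with a ReLU-based correction for
    magnitude data, lumpy-background object simulators with analytic
    second-order statistics, Rayleigh-fit and wavelet-based noise estimators,
    and task-based image-quality evaluation via the Hotelling observer and
    Frechet distances between image ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
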