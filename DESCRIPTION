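Package: fuzzyweed
Title: Decision-Tree-Based Fuzzy Classification of Crop and Weed Image Blocks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Discriminates peanut plants from broadleaf weeds in small RGB
    image blocks. Extracts a 98-dimensional descriptor per block (18 color
    statistics over RGB/HSV/CIELAB planes, 16 Haralick features from
    direction-averaged gray-level co-occurrence matrices, and the same 16
    descriptors from each of the four one-level Haar wavelet subbands),
    reduces it by correlation-based feature selection or principal component
    analysis, induces C4.5-style (gain ratio), reduced-error-pruning and
    random decision trees, and compiles a fitted tree into a Mamdani fuzzy
    inference system with trapezoidal membership functions and centroid
    defuzzification. Ships faithful reconstructions of two published fuzzy
    peanut/weed classifiers and a synthetic block generator for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    stats,
    utils,
    tools,
    jsonlite,
    png,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jpeg,
    e1071
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
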