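Package: octstent
Title: Three-Dimensional Coronary Stent Reconstruction from OCT and Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs deployed coronary artery stents in three dimensions
    from segmented intravascular optical coherence tomography (OCT) pullbacks
    and an angiography-derived vessel centerline. Lumen contours are packaged,
    oriented and lofted along rotation-minimizing frames; stent contours and
    strut points are straightened and unrolled onto a plane; the planar stent
    wireframe is rebuilt from the unrolled points guided by the stent's
    crown-and-link design template; and the wireframe is rolled back onto the
    reconstructed lumen, filleted at the crowns and swept into a strut volume
    mesh. Includes morphometric validation metrics (stent length, mean stent
    diameter, ellipse ratio, malapposition, Bland-Altman agreement,
    time-averaged wall shear stress) and a synthetic stented-vessel phantom
    generator with known ground truth that emulates OCT pullback sampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    grDevices,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
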