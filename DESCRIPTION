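Package: pfesim
Title: Simulation-Based Assessment of Pupil Foreshortening Error in
    Head-Mounted Eye Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Raytraces synthetic near-eye images of schematic (LeGrand-model)
    eyes with corneal refraction, detects the 2D pupil ellipse, and quantifies
    the gaze-angle dependency (pupil foreshortening error) of three pupil-size
    measurement methods: the pupil-ellipse major axis, a refraction-unaware 3D
    eye-model fit based on conic unprojection and tangency scaling, and a
    simulation-trained polynomial refraction correction. Includes the
    circularity-binned, confidence-weighted aggregation statistics used to
    summarise gaze-angle dependency at the subject and population level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    stats,
    utils,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
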