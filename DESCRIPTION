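Package: tagmove
Title: Quantifying Tracking-Tag Load Effects on Insect Movement from Arena Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how attached tag weight and ambient
    temperature alter insect movement in arena recordings. Segments
    per-individual video-tracking trajectories into alternating movement
    bouts and resting periods, computes six per-recording movement
    properties (mean, maximum and total movement-bout path length, mean
    bout speed, mean resting duration and resting count), and runs the
    associated comparison battery: Mann-Whitney tests of tagged groups
    against controls with Benjamini-Yekutieli false-discovery-rate
    adjustment, per-individual day-slope analyses, paired body-mass tests,
    and a random-intercept linear mixed model of total distance travelled.
    Includes a seeded correlated-random-walk generator of bout-rest
    trajectories so the whole pipeline can be exercised and calibrated
    without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
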