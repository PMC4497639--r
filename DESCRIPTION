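Package: dinsim
Title: Simulation of an Antennal Proprioceptive Pathway and Its Descending Interneuron Coding-Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the descending mechanosensory pathway of the stick insect
    antenna: ramp-and-hold joint-angle stimuli deflect two rows of hair-field
    sensilla, whose phasic-tonic afferents are modelled as lead-lag (low-pass
    plus high-pass) filter cascades feeding a noisy spike generator with an
    absolute refractory period. Afferent spike trains drive four variants of
    descending interneuron (DIN) models (simple position-sensitive, dynamic
    position-sensitive, ON-type and OFF-type velocity-sensitive). Responses are
    characterized by signed selectivity scores for direction, position and
    motion at several stimulus velocities, and neuron populations are mapped
    into a two-dimensional coding-space by principal component analysis with
    Kaiser-Guttman retention, resampling diagnostics, and axis-aligned linear
    separators for group classification. Includes parameter-sweep and synthetic
    reference populations, CSV/JSON export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
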