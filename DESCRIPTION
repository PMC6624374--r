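Package: thiaflow
Title: Vitamin B1 Flow Through a Size-Structured Plankton Food Web
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a size-structured aquatic food web (heterotrophic
    bacteria, pico-, nano- and microalgae, nanoflagellates, ciliates,
    mesozooplankton and planktivorous fish) in an enclosed, instantly mixed
    surface layer, with explicit carbon, nitrogen, phosphorus and vitamin B1
    (thiamin) pools. Light follows a seasonal and diel solar cycle attenuated
    by background absorption and algal self-shading (Lambert-Beer); producer
    growth is allometrically size-structured with Monod/Liebig co-limitation;
    vitamin B1 enters the web in producers and bacteria, is transferred up by
    clearance-rate grazing discounted by bioavailability, and turns over at
    metabolic rates. A scenario engine sweeps fish abundance, nutrient input
    and background light attenuation, classifies each scenario by the fraction
    of days with B1-poor fish, and reports summary statistics of the plankton
    dynamics, together with the analytic trophic decay-chain arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
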