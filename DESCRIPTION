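Package: helixpack
Title: Transmembrane Helix Packing from Sequence-Derived Residue Contacts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts per-residue lipid exposure and inter-helix residue
    contacts of alpha-helical transmembrane proteins with radial-basis-function
    support vector machines trained on sequence profiles, derives helix-helix
    interaction graphs, discriminates native from decoy packing arrangements,
    and constructs two-dimensional helical packing arrangements with a
    Kamada-Kawai force-directed layout, same-side loop-crossover scoring and
    genetic-algorithm optimisation of helix rotations. Includes a synthetic
    fixture generator producing idealized helix bundles with known contacts
    and planted lipid-exposure signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
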