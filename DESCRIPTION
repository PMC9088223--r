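Package: termseed
Title: Peptide Binder Design from Tertiary Structural Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates candidate peptide binders for a protein target by
    mining tertiary structural motifs (TERMs) from a structure database.
    Binding-site fragments on the target surface are used as substructure
    queries; residues that contact the matched motifs are lifted into the
    target frame as interface seeds; seeds are joined through a geometric
    overlap graph and fused into chemically plausible peptide backbones,
    which are then scored and filtered with backbone-only contact statistics.
    Also provides coverage and reconstruction benchmarks over peptide-protein
    complex sets, sequence-ensemble analyses (Monte-Carlo simulated annealing
    over linear energy tables, conservation, consensus) and exact sequence
    optimisation under a charged-residue constraint, plus synthetic fixture
    generators (ideal helices and strands, toy complexes, planted databases)
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
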