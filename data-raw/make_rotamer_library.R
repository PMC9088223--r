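# Regenerates the packaged coarse synthetic rotamer library fixture.
devtools::load_all(".", quiet = TRUE)
lib <- rotamer_library_synthetic()
write_rotamer_library(lib, "inst/extdata/rotamers_synthetic.tsv")
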