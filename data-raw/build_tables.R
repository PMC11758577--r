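# Regenerate the shipped approximate reference tables under
# inst/extdata/xsections from the in-package parameterization.
# Run from the package root:  Rscript data-raw/build_tables.R
pkgload::load_all(".", quiet = TRUE)
dir <- file.path("inst", "extdata", "xsections")
unlink(dir, recursive = TRUE)
for (s in shipped_element_symbols()) {
  rec <- nanoscint:::reference_element_record(s)
  write_element_table(rec, dir)
  cat("wrote", s, "\n")
}
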