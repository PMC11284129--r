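# Regenerates the packaged fixture files under inst/extdata/ from
# make_fixture(). Run from the repository root after any change to the
# synthetic-cohort module:
#   Rscript tools/make_fixtures.R
library(oxbalance)

fx <- make_fixture("tiny")
readr::write_csv(fx$cohort, "inst/extdata/tiny_cohort.csv")
jsonlite::write_json(fx$ledger, "inst/extdata/tiny_cohort_ledger.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote tiny fixture: ", nrow(fx$cohort), "rows\n")
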