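#!/usr/bin/env Rscript
# Score the three illustrative patients with the four published
# clinical-practice response scores and classify them at the published
# whole-group HR cut-offs.
suppressPackageStartupMessages(library(rshte))

dir.create("results", showWarnings = FALSE)
we <- worked_examples()
write.csv(we, file.path("results", "worked_examples.csv"), row.names = FALSE)
print(we, row.names = FALSE)
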