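#!/usr/bin/env Rscript
# Step 5: intragenic promoter candidates.
#
# Clusters the CAGE tag starts, flags clusters by DNase and H3K4me3
# overlap, restricts to the window upstream of the precursor and ranks.
# The planted TSS (550 bp upstream) should surface as the top candidate.
# Expects results/study from step 1.

suppressMessages(library(mirexapt))

study <- file.path("results", "study")
out <- file.path("results", "promoter")

truth <- jsonlite::read_json(file.path(study, "truth.json"),
                             simplifyVector = TRUE)
premirna <- genomic_interval("chrS", truth$premirna[1], truth$premirna[2], "+")

reg <- run_regulation(list(
  tags = file.path(study, "cage_tags.tsv"),
  dnase = file.path(study, "dnase.bed"),
  h3k4me3 = file.path(study, "h3k4me3.bed"),
  premirna = premirna,
  out_dir = out))

cand <- reg$candidates
message("candidates in the upstream window: ", nrow(cand))
if (nrow(cand)) {
  top <- cand[1, ]
  message(sprintf(
    "top candidate: peak %d (planted %d), %d tags, %d bp upstream, evidence %d",
    top$peak_pos, truth$tss, top$total_tags, top$distance_to_premirna,
    top$n_evidence))
  message(sprintf("recovery error: %d bp", abs(top$peak_pos - truth$tss)))
}
message("promoter report written to ", out)
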