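#!/usr/bin/env Rscript
# Step 2: survey the clade for the precursor.
#
# Locates the reference precursor in each species' intron by local
# alignment, folds and classifies every present candidate, and writes the
# per-species distribution matrix (presence / sequence-only / structure-
# supported), alignment hits as BED, per-criterion verdicts and the folds
# in Vienna text. Expects results/study from step 1.

suppressMessages(library(mirexapt))

study <- file.path("results", "study")
out <- file.path("results", "survey")

sv <- run_survey(list(
  introns = file.path(study, "introns.fasta"),
  reference = file.path(study, "reference.fasta"),
  out_dir = out))

message("survey written to ", out)
print(sv$matrix[, c("species", "status", "percent_identity", "coverage", "mfe")])
tb <- table(sv$matrix$status)
message(sprintf("statuses: %d structure-supported, %d sequence-predicted, %d absent",
                tb[["structure_supported"]], tb[["sequence_predicted"]],
                tb[["absent"]]))
if (length(sv$errors)) message("species with errors: ",
                               paste(names(sv$errors), collapse = ", "))
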