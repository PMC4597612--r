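#!/usr/bin/env Rscript
# Step 4: small-RNA arm dominance and host/miRNA co-expression.
#
# Counts the simulated reads per precursor arm, estimates 3p dominance,
# reduces the expression call matrix to the 2x2 co-expression table and
# applies the transcription-mode rule. Expects results/study from step 1.

suppressMessages(library(mirexapt))

study <- file.path("results", "study")
out <- file.path("results", "expression")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

truth <- jsonlite::read_json(file.path(study, "truth.json"),
                             simplifyVector = TRUE)
pre <- rna_seq(read_fasta(file.path(study, "reference.fasta"))[[1]])
arms <- mature_arms(truth$arms$arm5p, truth$arms$arm3p)
reads <- unname(read_fasta(file.path(study, "reads.fasta")))

ac <- count_arm_reads(reads, pre, arms)
dom <- arm_dominance(ac)
write_tsv(data.frame(count5p = ac$count5p, count3p = ac$count3p,
                     count_other = ac$count_other,
                     unassigned = ac$unassigned,
                     dominance_3p = dom),
          file.path(out, "arm_counts.tsv"))
message(sprintf("arm counts 5p/3p/other/unassigned: %d/%d/%d/%d",
                ac$count5p, ac$count3p, ac$count_other, ac$unassigned))
message(sprintf("estimated 3p dominance %.3f (simulated truth %.2f)",
                dom, truth$dominance))

reg <- run_regulation(list(
  expression = file.path(study, "expression.tsv"),
  out_dir = out))
tab <- reg$coexpression
message(sprintf("co-expression both/mirna-only/host-only/neither: %d/%d/%d/%d",
                tab$both, tab$mirna_only, tab$host_only, tab$neither))
message("transcription-mode verdict: ", reg$verdict)
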