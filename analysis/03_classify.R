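#!/usr/bin/env Rscript
# Stage 3 -- cold/warm/mediate classification from two-season trajectories.
#
# A line is cold-type when its relative CT falls (slope < -0.01 C/day)
# and averages below zero in both seasons; warm-type on the mirrored
# conditions; everything else is mediate.  Compares calls against the
# planted ground truth.

suppressPackageStartupMessages(library(thermofill))
out <- "results/run"

rel <- read.csv(file.path(out, "ct_relative.csv"))
calls <- classify_lines(rel, epsilon = 0.01)
write.csv(calls, file.path(out, "type_calls.csv"), row.names = FALSE)

truth <- read.csv(file.path(out, "truth_types.csv"))
concord <- mean(calls$call == truth$type[match(calls$line, truth$line)])
message(sprintf("Classified %d lines: %d cold / %d warm / %d mediate.",
                nrow(calls), sum(calls$call == "cold"),
                sum(calls$call == "warm"), sum(calls$call == "mediate")))
message(sprintf("Concordance with planted types: %.0f%%.", 100 * concord))
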