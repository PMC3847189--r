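# Shared configuration for the analysis workflow. Each numbered script can be
# run from the repository root after the previous ones.

library(mirdiverge)

STUDY_SEED <- 101
SYN_DIR <- "results/synthetic"
OUT_DIR <- "results"
dir.create(SYN_DIR, recursive = TRUE, showWarnings = FALSE)

# species of the emulated study: one reference lineage, one sister lineage
# used for expression comparison, and a panel for site conservation
REF_SPECIES <- "cow"
PANEL <- c("human", "dog", "mouse", "rat", "chicken")
COMPARISON_SPECIES <- "human"
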