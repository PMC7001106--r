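# Shared setup for the numbered analysis drivers.
#
# Every driver is a thin narrative over the memsite package: it states what
# it computes, runs the packaged function, and writes its tables under
# results/.  Run them in order from the repository root:
#
#   Rscript analysis/01_build_bilayer.R
#   Rscript analysis/02_binding_simulation.R
#   ...
#
# Set MEMSITE_PRESET=reference for the full-sampling runs (the default "ci"
# preset keeps each driver in the seconds-to-minutes range).

suppressMessages(library(memsite))

preset <- Sys.getenv("MEMSITE_PRESET", "ci")
cfg <- default_config(preset)
results_dir <- "results"
dir.create(results_dir, showWarnings = FALSE)

say <- function(...) cat(sprintf(...), "\n")
tsv <- function(df, name) {
  path <- file.path(results_dir, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  say("  wrote %s", path)
  invisible(path)
}
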