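# Shared fixtures, built in code at test time.

# a small simulated panel with two planted mutations; cached per session
small_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(target_length = 800L, n_reads = 4000L, seed = 5L,
                        n_reference_samples = 12L)
      cache <<- simulate_panel(cfg, test_freqs = c(0.05, 0.20))
    }
    cache
  }
})

small_error_cfg <- function() error_model_config(min_reference_samples = 5L)

# hand-written SAM over a 20-bp reference, covering forward/reverse strands,
# a secondary alignment, an unmapped read and known mismatch counts
REF20 <- "ACGTACGTACGTACGTACGT"

write_hand_sam <- function(path) {
  q30 <- strrep("?", 8)                      # Phred 30
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:target\tLN:20",
    # forward, start 3, perfect: bases GTACGTAC
    paste("r1", 0, "target", 3, 60, "8M", "*", 0, 0, "GTACGTAC", q30,
          "NM:i:0", "MD:Z:8", sep = "\t"),
    # reverse, start 5, one mismatch at ref pos 7 (G->A)
    paste("r2", 16, "target", 5, 60, "8M", "*", 0, 0, "ACATACGT", q30,
          "NM:i:1", "MD:Z:2G5", sep = "\t"),
    # secondary alignment: must be skipped
    paste("r3", 256, "target", 1, 60, "8M", "*", 0, 0, "ACGTACGT", q30,
          "NM:i:0", "MD:Z:8", sep = "\t"),
    # unmapped read: must be skipped
    paste("r4", 4, "*", 0, 0, "*", "*", 0, 0, "ACGTACGT", q30, sep = "\t"),
    # forward, low mapping quality
    paste("r5", 0, "target", 1, 19, "8M", "*", 0, 0, "ACGTACGT", q30,
          "NM:i:0", "MD:Z:8", sep = "\t"))
  writeLines(lines, path)
  path
}
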