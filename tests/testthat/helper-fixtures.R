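# Shared fixture builders: everything is generated in code at test time.

write_report_lines <- function(lines) {
  f <- tempfile(fileext = ".cx.tsv")
  writeLines(lines, f)
  f
}

make_calls <- function(pos, n_meth, n_unmeth, context = "CHH",
                       chrom = "chr1", strand = "+") {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             n_meth = as.integer(n_meth), n_unmeth = as.integer(n_unmeth),
             context = context, stringsAsFactors = FALSE)
}

# A small two-condition window_quant built directly from synthetic calls:
# `shift` adds methylated calls to the second condition inside window 1.
make_two_condition_wq <- function(n_reps = 3, shift = 0, seed = 99) {
  withr_seed <- function(code) { set.seed(seed); code }
  chrom_sizes <- c(chr1 = 1000)
  windows <- tile_windows(chrom_sizes, width = 100)
  calls <- list()
  set.seed(seed)
  for (cond in 1:2) {
    for (r in seq_len(n_reps)) {
      nm <- rpois(10, 5) + if (cond == 2) shift else 0
      base <- make_calls(pos = seq(5, 95, by = 10), n_meth = nm,
                         n_unmeth = pmax(0, 20 - nm))
      rest <- make_calls(pos = seq(105, 995, by = 10),
                         n_meth = rpois(90, 5),
                         n_unmeth = 15)
      calls[[sprintf("c%d_r%d", cond, r)]] <- rbind(base, rest)
    }
  }
  wq <- quantify_windows(calls, windows, chrom_sizes)
  conds <- setNames(rep(c("A", "B"), each = n_reps), names(calls))
  list(wq = wq, conditions = conds)
}

# Tiny simulation design used by several tests (fast: ~2 s to simulate).
tiny_design <- function(seed = 5, ...) {
  simulation_design(
    seed = seed, chrom_sizes = c(chr1 = 60000), n_genes = 60,
    dmr = list(n = 10, contexts = c(CHH = 1)),
    deg = list(n = 10), pairs = list(n = 4), ...)
}

expect_superset <- function(big, small) {
  expect_true(all(small %in% big))
}
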