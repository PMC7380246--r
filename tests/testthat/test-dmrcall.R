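# Window tiling, enrichment quantification, filters, the ANOVA/BH/fold-
# change DMR procedure and profile utilities.

test_that("tiling covers chromosomes from 1 with partial final windows", {
  w <- tile_windows(c(chr1 = 250))
  expect_equal(w$start, c(1L, 101L, 201L))
  expect_equal(w$end, c(100L, 200L, 250L))

  expect_equal(nrow(tile_windows(c(chr1 = 100))), 1L)

  w2 <- tile_windows(c(chr1 = 200), width = 100, step = 50)
  expect_equal(w2$start, c(1L, 51L, 101L, 151L))
  expect_equal(w2$end, c(100L, 150L, 200L, 200L))

  # disjoint exhaustive tiles under step = width
  w3 <- tile_windows(c(a = 1000, b = 333), width = 100)
  expect_equal(sum(w3$end - w3$start + 1L), 1333L)
  expect_error(tile_windows(c(1000)), "named")
  expect_error(tile_windows(c(chr1 = 100), width = 100, step = 150), "step")
})

test_that("window enrichment follows the log2 density-ratio formula", {
  chrom_sizes <- c(chr1 = 10000)
  w <- tile_windows(chrom_sizes, 100)
  # 40 methylated calls in window 1, 360 spread elsewhere: M = 400
  calls <- rbind(
    make_calls(pos = seq(5, 95, 10), n_meth = 4, n_unmeth = 1),
    make_calls(pos = seq(105, 9995, length.out = 90), n_meth = 4, n_unmeth = 1)
  )
  wq <- quantify_windows(list(s1 = calls), w, chrom_sizes, pseudocount = 0)
  expect_equal(wq$M[["s1"]], 400)
  # E = log2((40/100)/(400/10000)) = log2(10)
  expect_equal(wq$E[1, 1], log2(10), tolerance = 1e-12)

  # density equal to genome-wide density -> E = 0
  even <- make_calls(pos = seq(50, 9950, by = 100), n_meth = 4, n_unmeth = 1)
  wqe <- quantify_windows(list(s1 = even), w, chrom_sizes, pseudocount = 0)
  expect_equal(max(abs(wqe$E)), 0)

  # empty window with pseudocount stays finite:
  # E = log2((0.5/100)/(400.5/10000))
  wq2 <- quantify_windows(list(s1 = calls[-(1:10), ]), w, chrom_sizes,
                          pseudocount = 0.5)
  expect_equal(wq2$E[1, 1], log2((0.5 / 100) / ((wq2$M[["s1"]] + 0.5) / 10000)))
  expect_true(all(is.finite(wq2$E)))

  expect_error(quantify_windows(list(s1 = calls), w, c(chr1 = 0)), "length")
})

test_that("context restriction recomputes totals within the context", {
  chrom_sizes <- c(chr1 = 1000)
  w <- tile_windows(chrom_sizes, 100)
  calls <- rbind(make_calls(pos = c(10, 30), n_meth = 5, n_unmeth = 0, context = "CHH"),
                 make_calls(pos = c(110, 130), n_meth = 7, n_unmeth = 0, context = "CpG"))
  wq <- quantify_windows(list(s1 = calls), w, chrom_sizes, context = "CHH")
  expect_equal(wq$M[["s1"]], 10)
  expect_equal(wq$m[2, 1], 0)  # CpG calls invisible in CHH mode
  # "CG" input token behaves as CpG
  wq2 <- quantify_windows(list(s1 = calls), w, chrom_sizes, context = "CG")
  expect_equal(wq2$M[["s1"]], 14)
})

test_that("methylated-cytosine filter uses the cross-sample union with inclusive threshold", {
  chrom_sizes <- c(chr1 = 200)
  w <- tile_windows(chrom_sizes, 100)
  # window 1: 19 distinct methylated positions in s1 union s2 (10 + 9 extra)
  s1 <- make_calls(pos = seq(1, 19, 2), n_meth = 1, n_unmeth = 5)
  s2 <- make_calls(pos = seq(21, 37, 2), n_meth = 1, n_unmeth = 5)
  wq <- quantify_windows(list(s1 = s1, s2 = s2), w, chrom_sizes)
  expect_equal(wq$meth_positions[1], 19L)
  expect_equal(nrow(filter_windows(wq, 20)$windows), 0L)

  # one more methylated position reaches 20 -> retained (boundary inclusive)
  s2b <- rbind(s2, make_calls(39, 1, 5))
  wq2 <- quantify_windows(list(s1 = s1, s2 = s2b), w, chrom_sizes)
  expect_equal(wq2$meth_positions[1], 20L)
  expect_equal(filter_windows(wq2, 20)$windows$window_id, "chr1:1-100")

  # unmethylated positions never count; duplicated positions count once
  s3 <- make_calls(pos = c(rep(5, 1), 5, 7), n_meth = c(2, 2, 0),
                   n_unmeth = 5, strand = c("+", "+", "+"))
  wq3 <- quantify_windows(list(s1 = s3), w, chrom_sizes)
  expect_equal(wq3$meth_positions[1], 1L)

  # per-sample mode is stricter than the union
  expect_equal(nrow(filter_windows(wq2, 20, per_sample = TRUE)$windows), 0L)

  # empty window set stays empty
  empty <- filter_windows(wq, 1e6)
  expect_equal(nrow(filter_windows(empty, 20)$windows), 0L)
})

test_that("one-way ANOVA conventions: zero variance, separation, textbook oracle", {
  expect_equal(anova_window(list(rep(1, 3), rep(1, 3), rep(1, 3), rep(1, 3))), 1)
  p_sep <- anova_window(list(c(0, 0, 0), c(1, 1, 1)))
  expect_gt(p_sep, 0)
  expect_lt(p_sep, 1e-100)
  expect_warning(p_na <- anova_window(list(1, c(1, 2))), "fewer than 2")
  expect_true(is.na(p_na))
  expect_error(anova_window(list(c(1, 2))), "at least two")

  # independently coded sum-of-squares oracle
  anova_oracle <- function(groups) {
    all <- unlist(groups)
    grand <- mean(all)
    ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                      numeric(1)))
    ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
    df1 <- length(groups) - 1
    df2 <- length(all) - length(groups)
    F <- (ssb / df1) / (ssw / df2)
    pf(F, df1, df2, lower.tail = FALSE)
  }
  gr <- list(c(1, 2, 3), c(2, 3, 4), c(4, 5, 6), c(5, 6, 7))
  expect_equal(anova_window(gr), anova_oracle(gr), tolerance = 1e-12)
})

test_that("BH adjustment matches the hand-applied step-up formula", {
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {
      # explicit step-up: min over j >= i of p_(j) * m / j
      ps <- p[o][i:m]
      q[o[i]] <- min(1, min(ps * m / (i:m)))
    }
    q
  }
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  set.seed(11)
  for (i in 1:5) {
    p <- runif(sample(5:50, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone non-decreasing on sorted input, capped at 1
  p <- sort(runif(30))
  q <- bh_adjust(p)
  expect_true(all(diff(q) >= -1e-15))
  expect_true(all(q <= 1))
})

test_that("DMR calling applies both the FDR and fold-change gates", {
  fx <- make_two_condition_wq(shift = 40)
  res <- call_dmrs(fx$wq, fx$conditions, q_max = 0.01, min_delta = 1,
                   baseline = "A")
  w1 <- res$windows[1, ]
  expect_true(w1$q < 0.01 && w1$delta_max > 1)
  expect_true(w1$is_dmr)
  # the shifted window is hyper vs baseline
  d1 <- res$directions[res$directions$window_id == w1$window_id, ]
  expect_equal(unique(d1$direction), "hyper")

  # fold-change gate: min_delta above the achieved shift kills the call
  res2 <- call_dmrs(fx$wq, fx$conditions, q_max = 0.01,
                    min_delta = w1$delta_max + 0.1, baseline = "A")
  expect_false(res2$windows$is_dmr[1])

  # FDR gate: q_max below the achieved q kills the call
  res3 <- call_dmrs(fx$wq, fx$conditions, q_max = w1$q / 2,
                    min_delta = 1, baseline = "A")
  expect_false(res3$windows$is_dmr[1])

  expect_error(call_dmrs(fx$wq, fx$conditions, baseline = "Z"), "baseline")
})

test_that("relaxing thresholds never shrinks the DMR set; hyper/hypo partition", {
  fx <- make_two_condition_wq(shift = 25)
  strict <- call_dmrs(fx$wq, fx$conditions, q_max = 0.01, min_delta = 1.5,
                      baseline = "A")
  looser_delta <- call_dmrs(fx$wq, fx$conditions, q_max = 0.01,
                            min_delta = 0.5, baseline = "A")
  looser_q <- call_dmrs(fx$wq, fx$conditions, q_max = 0.1, min_delta = 1.5,
                        baseline = "A")
  expect_superset(dmrs(looser_delta)$window_id, dmrs(strict)$window_id)
  expect_superset(dmrs(looser_q)$window_id, dmrs(strict)$window_id)

  d <- looser_delta$directions
  if (nrow(d)) {
    # per contrast, a window is hyper xor hypo, and all are DMRs
    expect_false(any(duplicated(d[, c("window_id", "contrast")])))
    expect_true(all(d$window_id %in% dmrs(looser_delta)$window_id))
    expect_true(all(d$direction %in% c("hyper", "hypo")))
  }
})

test_that("single-context data give identical per-context and all-context calls", {
  chrom_sizes <- c(chr1 = 1000)
  windows <- tile_windows(chrom_sizes, 100)
  set.seed(3)
  calls <- lapply(setNames(1:6, sprintf("s%d", 1:6)), function(i) {
    make_calls(pos = seq(1, 999, 7), n_meth = rpois(143, 3) + (i > 3),
               n_unmeth = 8, context = "CHH")
  })
  conds <- setNames(rep(c("A", "B"), each = 3), names(calls))
  all_ctx <- call_dmrs(filter_windows(quantify_windows(calls, windows, chrom_sizes), 20),
                       conds, q_max = 0.05, min_delta = 0, baseline = "A")
  by_ctx <- call_dmrs_by_context(calls, windows, chrom_sizes, conds, "A",
                                 q_max = 0.05, min_delta = 0)
  expect_equal(by_ctx$CHH$windows, all_ctx$windows)
  expect_equal(nrow(by_ctx$CHG$windows), 0L)  # zero CHG calls -> empty set
  expect_equal(nrow(by_ctx$CpG$windows), 0L)
})

test_that("variance ranking is correct, deterministic, and truncates properly", {
  prof <- rbind(flat = c(1, 1, 1, 1), var2 = c(0, 2, 0, 2),
                mid = c(1, 1.5, 1, 1.5))
  top <- top_variance(prof, 2)
  expect_equal(rownames(top), c("var2", "mid"))
  expect_equal(rownames(top_variance(prof, 10)), c("var2", "mid", "flat"))

  set.seed(21)
  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(sprintf("it%02d", 1:10), NULL))
  got <- top_variance(m, 10)
  vr <- apply(m, 1, var)
  expect_equal(rownames(got), names(sort(vr, decreasing = TRUE)))

  # deterministic tie-break by id
  ties <- rbind(b = c(0, 1), a = c(1, 0), c = c(0, 1))
  expect_equal(rownames(top_variance(ties, 3)), c("a", "b", "c"))
})

test_that("profile clustering recovers planted groups and is seed-deterministic", {
  set.seed(8)
  up <- t(replicate(10, c(0, 1, 2, 3) + rnorm(4, 0, 0.05)))
  down <- t(replicate(10, c(3, 2, 1, 0) + rnorm(4, 0, 0.05)))
  prof <- rbind(up, down)
  rownames(prof) <- sprintf("p%02d", 1:20)
  cl <- cluster_profiles(prof, k = 2, seed = 42)
  expect_equal(length(unique(cl$cluster_id[1:10])), 1L)
  expect_equal(length(unique(cl$cluster_id[11:20])), 1L)
  expect_false(cl$cluster_id[1] == cl$cluster_id[11])

  cl2 <- cluster_profiles(prof, k = 2, seed = 42)
  expect_identical(cl, cl2)

  # k = number of items -> singleton clusters with zero inertia
  small <- matrix(c(0, 1, 2, 3,  3, 2, 1, 0,  0, 3, 0, 3,  2, 0, 2, 0),
                  4, 4, byrow = TRUE,
                  dimnames = list(paste0("s", 1:4), NULL))
  cl3 <- cluster_profiles(small, k = 4, seed = 1, nstart = 1)
  expect_equal(sort(cl3$cluster_id), 1:4)

  expect_error(cluster_profiles(prof, k = 0, seed = 1), "k")
  expect_error(cluster_profiles(prof, k = 21, seed = 1), "k")
})
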