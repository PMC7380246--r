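# Window-based quantification of methylation as log2 enrichment and the
# DMR-calling procedure: coverage/count filters, per-window one-way ANOVA
# across chilling conditions, BH correction and a fold-change gate.

#' Tile chromosomes into fixed-width windows
#'
#' Windows start at position 1 of every chromosome and advance by `step`
#' (default: non-overlapping tiles of width `width`). The final window of a
#' chromosome may be shorter than `width`.
#'
#' @param chrom_sizes named vector of chromosome lengths (bp).
#' @param width window width in bp (default 100).
#' @param step distance between successive window starts; `1 <= step <=
#'   width`. Defaults to `width` (disjoint, exhaustive tiles).
#' @return data.frame with columns `chrom`, `start`, `end`, `window_id`.
#' @examples
#' tile_windows(c(chr1 = 250))
#' @export
tile_windows <- function(chrom_sizes, width = 100L, step = width) {
  if (length(chrom_sizes) == 0L || is.null(names(chrom_sizes)) ||
      any(!nzchar(names(chrom_sizes))) || any(is.na(chrom_sizes)) ||
      any(chrom_sizes < 1)) {
    stop("`chrom_sizes` must be a named vector of positive chromosome lengths")
  }
  check_scalar(width, "width", min = 1)
  check_scalar(step, "step", min = 1, max = width)
  width <- as.integer(width); step <- as.integer(step)
  res <- lapply(names(chrom_sizes), function(ch) {
    len <- as.integer(chrom_sizes[[ch]])
    starts <- seq.int(1L, len, by = step)
    ends <- pmin(starts + width - 1L, len)
    data.frame(chrom = ch, start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$window_id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  rownames(out) <- NULL
  out
}

windows_granges <- function(windows) {
  GenomicRanges::GRanges(windows$chrom,
                         IRanges::IRanges(windows$start, windows$end))
}

#' Quantify windows as per-sample log2 methylation enrichment
#'
#' For each window and sample, the methylation state is the log2 ratio of
#' the observed methylated-call density in the window to the overall
#' methylated-call density of the sample:
#' `E = log2( ((m_w + pc) / L_w) / ((M + pc) / L) )`,
#' where `m_w` is the sum of methylated calls inside the window, `L_w` the
#' window width, `M` the sample's genome-wide methylated-call total and `L`
#' the total genome length. The pseudocount `pc` keeps `E` finite for empty
#' windows.
#'
#' Calls are expected to be coverage-filtered already (see
#' [read_cytosine_report()]); sample totals `M` are computed over the same
#' filtered calls, restricted to `context` when one is given.
#'
#' @param calls_by_sample named list of methylation call data.frames, one
#'   per sample.
#' @param windows window data.frame from [tile_windows()].
#' @param chrom_sizes named chromosome lengths; `L` is their sum.
#' @param pseudocount added to numerator and denominator counts
#'   (default 0.5).
#' @param context optional single context (`"CpG"`, `"CHG"`, `"CHH"`);
#'   restricts both window counts and sample totals to that context.
#' @param sample_totals optional list with elements `M` (named per-sample
#'   genome-wide methylated-call totals) and `L` (genome length), overriding
#'   the internally computed values.
#' @return an object of class `window_quant`: windows plus matrices `E`
#'   (log2 enrichment), `m` (methylated calls) and `c` (covered cytosines),
#'   the union count of methylated cytosine positions per window, and the
#'   per-sample totals used.
#' @export
quantify_windows <- function(calls_by_sample, windows, chrom_sizes,
                             pseudocount = 0.5, context = NULL,
                             sample_totals = NULL) {
  if (!is.list(calls_by_sample) || length(calls_by_sample) == 0L ||
      is.null(names(calls_by_sample))) {
    stop("`calls_by_sample` must be a named list of call data.frames")
  }
  check_scalar(pseudocount, "pseudocount", min = 0)
  if (any(windows$end - windows$start + 1L <= 0L)) {
    stop("window of non-positive width")
  }
  L <- if (!is.null(sample_totals)) sample_totals$L else sum(as.numeric(chrom_sizes))
  if (is.null(L) || L <= 0) stop("total genome length must be positive")
  if (!is.null(context)) {
    context <- normalize_context(context)
    if (!context %in% CONTEXTS) stop("unknown context: ", context)
  }

  samples <- names(calls_by_sample)
  nwin <- nrow(windows)
  win_gr <- windows_granges(windows)
  width <- windows$end - windows$start + 1L

  E <- m <- cc <- matrix(0, nrow = nwin, ncol = length(samples),
                         dimnames = list(windows$window_id, samples))
  M <- numeric(length(samples)); names(M) <- samples
  meth_pos <- vector("list", length(samples))

  for (j in seq_along(samples)) {
    calls <- validate_calls(calls_by_sample[[j]])
    if (!is.null(context)) {
      calls <- calls[normalize_context(calls$context) == context, , drop = FALSE]
    }
    M[j] <- sum(as.numeric(calls$n_meth))
    if (nrow(calls) == 0L) next
    gr <- GenomicRanges::GRanges(calls$chrom,
                                 IRanges::IRanges(calls$pos, calls$pos))
    hits <- GenomicRanges::findOverlaps(gr, win_gr)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    if (length(qh)) {
      msum <- rowsum(as.numeric(calls$n_meth[qh]), sh)
      m[as.integer(rownames(msum)), j] <- msum[, 1L]
      csum <- rowsum(rep(1, length(qh)), sh)
      cc[as.integer(rownames(csum)), j] <- csum[, 1L]
      is_meth <- calls$n_meth[qh] >= 1L
      if (any(is_meth)) {
        meth_pos[[j]] <- data.table::data.table(
          win = sh[is_meth],
          pos = calls$pos[qh[is_meth]],
          strand = calls$strand[qh[is_meth]]
        )
      }
    }
  }
  if (!is.null(sample_totals)) {
    Mo <- sample_totals$M
    if (!is.null(Mo)) {
      if (is.null(names(Mo))) stop("`sample_totals$M` must be named")
      M[names(Mo)] <- Mo
    }
  }

  # Distinct methylated cytosine positions per window: per sample and as a
  # union over the samples of the experiment.
  meth_by_sample <- matrix(0L, nrow = nwin, ncol = length(samples),
                           dimnames = dimnames(E))
  union_count <- integer(nwin)
  keep <- !vapply(meth_pos, is.null, logical(1L))
  if (any(keep)) {
    for (j in which(keep)) {
      u <- unique(meth_pos[[j]])
      tab <- rowsum(rep(1L, nrow(u)), u$win)
      meth_by_sample[as.integer(rownames(tab)), j] <- tab[, 1L]
    }
    all_pos <- unique(data.table::rbindlist(meth_pos[keep]))
    tab <- rowsum(rep(1L, nrow(all_pos)), all_pos$win)
    union_count[as.integer(rownames(tab))] <- tab[, 1L]
  }

  for (j in seq_along(samples)) {
    E[, j] <- log2(((m[, j] + pseudocount) / width) / ((M[j] + pseudocount) / L))
  }

  structure(list(windows = windows, E = E, m = m, c = cc,
                 meth_positions = union_count,
                 meth_positions_by_sample = meth_by_sample,
                 samples = samples, M = M, L = L,
                 pseudocount = pseudocount,
                 context = context %||% "all"),
            class = "window_quant")
}

#' @export
print.window_quant <- function(x, ...) {
  cat(sprintf("window_quant: %d windows x %d samples (context: %s)\n",
              nrow(x$windows), length(x$samples), x$context))
  invisible(x)
}

#' Discard windows with too few methylated cytosines
#'
#' Windows with fewer than `min_meth_cytosines` methylated cytosines are
#' discarded; windows with exactly the threshold are retained. A methylated
#' cytosine is a distinct position (and strand) carrying at least one
#' methylated call; by default positions are pooled across the union of
#' samples, with a stricter per-sample mode available.
#'
#' @param wq `window_quant` object.
#' @param min_meth_cytosines threshold (default 20).
#' @param per_sample if `TRUE`, require every sample to individually reach
#'   the threshold instead of the cross-sample union.
#' @return filtered `window_quant`.
#' @export
filter_windows <- function(wq, min_meth_cytosines = 20L, per_sample = FALSE) {
  stopifnot(inherits(wq, "window_quant"))
  check_scalar(min_meth_cytosines, "min_meth_cytosines", min = 0)
  keep <- if (per_sample) {
    apply(wq$meth_positions_by_sample, 1L,
          function(r) all(r >= min_meth_cytosines))
  } else {
    wq$meth_positions >= min_meth_cytosines
  }
  wq$windows <- wq$windows[keep, , drop = FALSE]
  wq$E <- wq$E[keep, , drop = FALSE]
  wq$m <- wq$m[keep, , drop = FALSE]
  wq$c <- wq$c[keep, , drop = FALSE]
  wq$meth_positions <- wq$meth_positions[keep]
  wq$meth_positions_by_sample <- wq$meth_positions_by_sample[keep, , drop = FALSE]
  rownames(wq$windows) <- NULL
  wq
}

#' One-way fixed-effects ANOVA p-value for one window
#'
#' Compares replicate-level enrichment values across conditions with a
#' classical one-way F test (equal-variance). Two degenerate conventions:
#' if every value is identical the p-value is 1; if the within-group
#' variance is zero but groups differ, the smallest positive representable
#' p-value is returned instead of 0.
#'
#' @param groups list of numeric vectors, one per condition, each holding
#'   the replicate enrichment values of that condition.
#' @return p-value in (0, 1], or `NA` (with a warning) when any group has
#'   fewer than 2 replicates.
#' @export
anova_window <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("`groups` must be a list of at least two condition vectors")
  }
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    warning("group with fewer than 2 replicates; window skipped")
    return(NA_real_)
  }
  values <- unlist(groups, use.names = FALSE)
  if (all(values == values[1L])) return(1)
  g <- factor(rep.int(seq_along(groups), sizes))
  p <- stats::oneway.test(values ~ g, var.equal = TRUE)$p.value
  if (is.na(p)) return(1)           # zero total variance edge
  max(p, .Machine$double.xmin)      # never report exactly 0
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH: p-values are ranked ascending, `q_(i) = min_{j >= i}
#' p_(j) * m / j`, capped at 1, and returned in the original order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]` (NAs pass through).
#' @return q-values in the original order.
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals)) stop("`pvals` must be numeric")
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Call differentially methylated regions across conditions
#'
#' A window is a DMR when (i) the BH-adjusted one-way ANOVA q-value across
#' conditions is below `q_max` and (ii) the largest absolute difference in
#' condition-mean enrichment between any two conditions exceeds
#' `min_delta` (log2 units). Direction is reported per
#' condition-vs-baseline contrast: among DMR windows, a window is counted
#' for contrast `c` when `|mean E(c) - mean E(baseline)| > min_delta`, as
#' hypermethylated if the difference is positive and hypomethylated
#' otherwise.
#'
#' @param wq `window_quant`, already passed through [filter_windows()];
#'   q-values are computed over exactly this window set.
#' @param conditions named character vector mapping each sample in `wq` to
#'   its condition label.
#' @param q_max FDR threshold (default 0.01).
#' @param min_delta log2 fold-change threshold (default 3).
#' @param baseline baseline condition label (the no-chill condition).
#' @return object of class `dmr_result` with elements `windows` (per-window
#'   statistics and `is_dmr` flag), `cond_means` (window x condition mean
#'   enrichment), `directions` (long table: window, contrast, delta,
#'   direction), `E`, and the calling parameters.
#' @export
call_dmrs <- function(wq, conditions, q_max = 0.01, min_delta = 3.0,
                      baseline) {
  stopifnot(inherits(wq, "window_quant"))
  check_scalar(q_max, "q_max", min = 0, max = 1)
  check_scalar(min_delta, "min_delta", min = 0)
  if (is.null(names(conditions))) {
    if (length(conditions) == length(wq$samples)) {
      names(conditions) <- wq$samples
    } else stop("`conditions` must be named by sample")
  }
  missing <- setdiff(wq$samples, names(conditions))
  if (length(missing)) stop("no condition for sample(s): ",
                            paste(missing, collapse = ", "))
  conditions <- as.character(conditions[wq$samples])
  levels <- unique(conditions)
  if (missing(baseline) || !baseline %in% levels) {
    stop("`baseline` must be one of the condition labels")
  }

  nwin <- nrow(wq$windows)
  idx_by_cond <- lapply(levels, function(cd) which(conditions == cd))
  names(idx_by_cond) <- levels

  p <- rep(NA_real_, nwin)
  if (nwin > 0L) {
    bad_design <- any(lengths(idx_by_cond) < 2L)
    if (bad_design) {
      warning("condition with fewer than 2 replicates; ANOVA undefined for all windows")
    } else {
      for (i in seq_len(nwin)) {
        p[i] <- anova_window(lapply(idx_by_cond, function(ix) wq$E[i, ix]))
      }
    }
  }
  q <- rep(NA_real_, nwin)
  ok <- !is.na(p)
  q[ok] <- bh_adjust(p[ok])

  cond_means <- matrix(NA_real_, nrow = nwin, ncol = length(levels),
                       dimnames = list(wq$windows$window_id, levels))
  for (cd in levels) {
    ix <- idx_by_cond[[cd]]
    cond_means[, cd] <- if (length(ix) == 1L) wq$E[, ix]
                        else rowMeans(wq$E[, ix, drop = FALSE])
  }
  delta_max <- if (nwin > 0L) {
    apply(cond_means, 1L, function(x) max(x) - min(x))
  } else numeric(0)

  is_dmr <- ok & q < q_max & delta_max > min_delta

  win <- cbind(wq$windows,
               data.frame(p = p, q = q, delta_max = delta_max,
                          is_dmr = is_dmr, stringsAsFactors = FALSE))

  dirs <- list()
  for (cd in setdiff(levels, baseline)) {
    d <- cond_means[, cd] - cond_means[, baseline]
    sig <- is_dmr & abs(d) > min_delta
    if (any(sig)) {
      dirs[[cd]] <- data.frame(
        window_id = wq$windows$window_id[sig],
        contrast = cd,
        delta = d[sig],
        direction = ifelse(d[sig] > 0, "hyper", "hypo"),
        stringsAsFactors = FALSE
      )
    }
  }
  directions <- if (length(dirs)) do.call(rbind, dirs) else
    data.frame(window_id = character(), contrast = character(),
               delta = numeric(), direction = character(),
               stringsAsFactors = FALSE)
  rownames(directions) <- NULL

  structure(list(windows = win, cond_means = cond_means,
                 directions = directions, E = wq$E,
                 conditions = stats::setNames(conditions, wq$samples),
                 baseline = baseline, context = wq$context,
                 params = list(q_max = q_max, min_delta = min_delta)),
            class = "dmr_result")
}

#' @export
print.dmr_result <- function(x, ...) {
  cat(sprintf("dmr_result (context: %s): %d windows tested, %d DMRs (q < %g, delta > %g)\n",
              x$context, nrow(x$windows), sum(x$windows$is_dmr),
              x$params$q_max, x$params$min_delta))
  if (nrow(x$directions)) {
    tab <- table(x$directions$contrast, x$directions$direction)
    print(tab)
  }
  invisible(x)
}

#' Extract called DMR windows
#'
#' @param x `dmr_result`.
#' @return data.frame of windows with `is_dmr == TRUE`.
#' @export
dmrs <- function(x) {
  stopifnot(inherits(x, "dmr_result"))
  out <- x$windows[x$windows$is_dmr, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call DMRs independently per cytosine context
#'
#' Repeats quantification, the methylated-cytosine filter and DMR calling
#' three times, restricting the calls (and genome-wide totals) to a single
#' context each time. A window may be a DMR in several contexts.
#'
#' @inheritParams quantify_windows
#' @inheritParams call_dmrs
#' @param contexts which contexts to run (default all three).
#' @param min_meth_cytosines filter threshold applied within each context.
#' @return named list of `dmr_result`, one per context.
#' @export
call_dmrs_by_context <- function(calls_by_sample, windows, chrom_sizes,
                                 conditions, baseline,
                                 contexts = CONTEXTS,
                                 min_meth_cytosines = 20L,
                                 q_max = 0.01, min_delta = 3.0,
                                 pseudocount = 0.5) {
  contexts <- normalize_context(contexts)
  stopifnot(all(contexts %in% CONTEXTS))
  out <- lapply(contexts, function(ctx) {
    wq <- quantify_windows(calls_by_sample, windows, chrom_sizes,
                           pseudocount = pseudocount, context = ctx)
    wq <- filter_windows(wq, min_meth_cytosines = min_meth_cytosines)
    call_dmrs(wq, conditions, q_max = q_max, min_delta = min_delta,
              baseline = baseline)
  })
  names(out) <- contexts
  out
}

#' Rank profiles by variance and keep the top n
#'
#' Items (windows or genes) are sorted by descending variance of their
#' per-condition mean profile; ties are broken lexicographically by row
#' name so output is deterministic.
#'
#' @param profiles numeric matrix, items x conditions, with row names.
#' @param n how many to keep (default 1000); `n` larger than the item count
#'   returns everything.
#' @return the ranked subset of `profiles`, with a `variance` attribute.
#' @export
top_variance <- function(profiles, n = 1000L) {
  check_scalar(n, "n", min = 1)
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles))) {
    rownames(profiles) <- sprintf("item_%06d", seq_len(nrow(profiles)))
  }
  v <- apply(profiles, 1L, stats::var)
  ord <- order(-v, rownames(profiles))
  keep <- ord[seq_len(min(n, nrow(profiles)))]
  out <- profiles[keep, , drop = FALSE]
  attr(out, "variance") <- v[keep]
  out
}

#' K-means subclusters of per-condition profiles
#'
#' Profiles are z-scored per item (rows with zero spread become all-zero)
#' and partitioned with k-means under a fixed seed and a fixed number of
#' random restarts, so the assignment is deterministic for a given seed.
#' The conventional choices in this workflow are `k = 16` for DMR
#' methylation profiles and `k = 10` for co-expression profiles.
#'
#' @param profiles numeric matrix, items x conditions, with row names.
#' @param k number of clusters; must satisfy `1 <= k <= nrow(profiles)`.
#' @param seed RNG seed.
#' @param nstart number of k-means restarts (default 10).
#' @return data.frame with `item_id` and `cluster_id` (1..k); the z-scored
#'   centroid profiles are attached as attribute `centroids`.
#' @export
cluster_profiles <- function(profiles, k, seed = 1L, nstart = 10L) {
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles))) {
    rownames(profiles) <- sprintf("item_%06d", seq_len(nrow(profiles)))
  }
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > nrow(profiles)) {
    stop("`k` must satisfy 1 <= k <= number of items")
  }
  z <- t(apply(profiles, 1L, function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  if (k == nrow(profiles)) {
    # degenerate partition: every item its own cluster (zero inertia)
    out <- data.frame(item_id = rownames(profiles),
                      cluster_id = seq_len(k), stringsAsFactors = FALSE)
    attr(out, "centroids") <- z
    return(out)
  }
  km <- with_seed(seed, stats::kmeans(z, centers = k, nstart = nstart,
                                      iter.max = 100L))
  out <- data.frame(item_id = rownames(profiles),
                    cluster_id = as.integer(km$cluster),
                    stringsAsFactors = FALSE)
  attr(out, "centroids") <- km$centers
  out
}

#' Mean-enrichment profile of called DMRs across conditions
#'
#' @param x `dmr_result`.
#' @param only_dmrs keep only called DMRs (default) or all tested windows.
#' @return matrix window x condition of mean log2 enrichment.
#' @export
dmr_condition_profiles <- function(x, only_dmrs = TRUE) {
  stopifnot(inherits(x, "dmr_result"))
  if (only_dmrs) x$cond_means[x$windows$is_dmr, , drop = FALSE]
  else x$cond_means
}

#' Write DMR calls to disk
#'
#' Emits a BED-like TSV (0-based half-open coordinates) of called DMRs and
#' optionally a full per-window TSV carrying per-sample enrichment.
#' The BED `direction` column holds the direction of the strongest
#' vs-baseline contrast ("." when no contrast passed the per-contrast
#' gate).
#'
#' @param x `dmr_result`.
#' @param path output TSV path for the BED-like summary.
#' @param full_path optional path for the full per-window table.
#' @return `path`, invisibly.
#' @export
write_dmrs <- function(x, path, full_path = NULL) {
  stopifnot(inherits(x, "dmr_result"))
  d <- dmrs(x)
  dir_of <- function(id) {
    rows <- x$directions[x$directions$window_id == id, , drop = FALSE]
    if (nrow(rows) == 0L) return(".")
    rows$direction[which.max(abs(rows$delta))]
  }
  bed <- data.frame(
    chrom = d$chrom, start = d$start - 1L, end = d$end, id = d$window_id,
    q = d$q, delta_max = d$delta_max,
    direction = if (nrow(d)) vapply(d$window_id, dir_of, character(1L))
                else character(0),
    contexts = rep(x$context, nrow(d)), stringsAsFactors = FALSE
  )
  data.table::fwrite(bed, path, sep = "\t", quote = FALSE)
  if (!is.null(full_path)) {
    full <- cbind(x$windows, as.data.frame(x$E))
    data.table::fwrite(full, full_path, sep = "\t", quote = FALSE)
  }
  invisible(path)
}
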