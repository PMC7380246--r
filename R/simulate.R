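# Seeded synthetic experiments: genome and gene models, per-sample
# cytosine reports with planted hyper/hypo DMRs, NB count matrices with
# planted DEGs, and planted anti-correlated gene-DMR pairs, all recorded
# in truth tables so that recovery can be scored against the planting.

#' Describe a synthetic chilling-accumulation experiment
#'
#' Collects every parameter of the generator into a validated design
#' object. The defaults emulate a two-genotype bud-dormancy study at desk
#' scale: a low-chill genotype sampled at 0/173/348/516 chilling hours
#' (CH) with RNA-seq at 0/348/516, and a high-chill genotype sampled at
#' 0/443/1,295/1,637 CH for both assays; three biological replicates per
#' condition; one 200 kb chromosome (2,000 windows of 100 bp); 500 genes;
#' 40 planted DMRs (CHH-dominant, methylation-proportion shift 0.4
#' switching on at the second condition), 50 planted DEGs (four-fold,
#' switching on at the second condition) and 10 planted anti-correlated
#' gene-DMR pairs (methylation ramping up while expression ramps down
#' monotonically).
#'
#' Per-context baseline methylation proportions default to typical plant
#' methylome rates (CpG 0.60, CHG 0.35, CHH 0.10); coverage is negative
#' binomial with mean 20 and size 5. Shifted proportions are clipped to
#' `[0.01, 0.99]` to avoid degenerate binomials.
#'
#' @param seed master seed; every random draw in the generator flows from
#'   it deterministically.
#' @param genotypes named list; each element has `meth_conditions` and
#'   `rna_conditions` (chilling-hour labels, first = baseline).
#' @param replicates biological replicates per condition (default 3).
#' @param chrom_sizes named chromosome lengths (default one 200 kb
#'   chromosome).
#' @param n_genes number of gene models (default 500).
#' @param gene_length length-2 range of gene lengths in bp.
#' @param baseline_meth named per-context methylation proportions.
#' @param coverage_mean,coverage_size negative-binomial coverage model.
#' @param window_width window width used for planting (default 100).
#' @param dmr list: `n`, `delta` (proportion shift), `contexts` (sampling
#'   weights per context), `prop_hyper`, `onset_index`.
#' @param deg list: `n`, `lfc`, `prop_up`, `dispersion`, `onset_index`,
#'   `baseline_meanlog`, `baseline_sdlog`.
#' @param pairs list: `n`, `delta`, `context`, `expr_span` (total log2
#'   drop across conditions), `flank`.
#' @param clip proportion clipping bounds.
#' @return object of class `sim_design`.
#' @export
simulation_design <- function(
    seed = 1L,
    genotypes = list(
      low_chill = list(meth_conditions = c("0", "173", "348", "516"),
                       rna_conditions = c("0", "348", "516")),
      high_chill = list(meth_conditions = c("0", "443", "1295", "1637"),
                        rna_conditions = c("0", "443", "1295", "1637"))
    ),
    replicates = 3L,
    chrom_sizes = c(chr1 = 200000L),
    n_genes = 500L,
    gene_length = c(150L, 300L),
    baseline_meth = c(CpG = 0.60, CHG = 0.35, CHH = 0.10),
    coverage_mean = 20, coverage_size = 5,
    window_width = 100L,
    dmr = list(n = 40L, delta = 0.4,
               contexts = c(CHH = 0.8, CpG = 0.1, CHG = 0.1),
               prop_hyper = 0.7, onset_index = 2L),
    deg = list(n = 50L, lfc = 2, prop_up = 0.5, dispersion = 0.1,
               onset_index = 2L, baseline_meanlog = log(100),
               baseline_sdlog = 1),
    pairs = list(n = 10L, delta = 0.4, context = "CHH", expr_span = 2,
                 flank = 2000L),
    clip = c(0.01, 0.99)) {
  check_scalar(seed, "seed")
  if (seed < 0 || seed > 2^31 - 1000) stop("`seed` must lie in [0, 2^31 - 1000]")
  stopifnot(is.list(genotypes), length(genotypes) >= 1L,
            !is.null(names(genotypes)))
  for (g in genotypes) {
    stopifnot(length(g$meth_conditions) >= 2L, length(g$rna_conditions) >= 2L)
    if (!all(g$rna_conditions %in% g$meth_conditions)) {
      stop("rna_conditions must be a subset of meth_conditions")
    }
  }
  check_scalar(replicates, "replicates", min = 2)
  if (any(chrom_sizes < 10000)) stop("chromosome sizes must be >= 10 kb")
  stopifnot(all(names(baseline_meth) %in% CONTEXTS),
            all(baseline_meth >= 0 & baseline_meth <= 1))
  check_scalar(coverage_mean, "coverage_mean", min = 1)
  check_scalar(coverage_size, "coverage_size", min = 0.1)
  defaults <- list(dmr = list(n = 40L, delta = 0.4,
                              contexts = c(CHH = 0.8, CpG = 0.1, CHG = 0.1),
                              prop_hyper = 0.7, onset_index = 2L),
                   deg = list(n = 50L, lfc = 2, prop_up = 0.5,
                              dispersion = 0.1, onset_index = 2L,
                              baseline_meanlog = log(100), baseline_sdlog = 1),
                   pairs = list(n = 10L, delta = 0.4, context = "CHH",
                                expr_span = 2, flank = 2000L))
  dmr <- utils::modifyList(defaults$dmr, dmr)
  deg <- utils::modifyList(defaults$deg, deg)
  pairs <- utils::modifyList(defaults$pairs, pairs)
  stopifnot(dmr$delta >= 0, dmr$delta <= 1, deg$dispersion > 0)
  for (g in genotypes) {
    if (dmr$onset_index > length(g$meth_conditions)) {
      stop("DMR onset index beyond the condition list")
    }
    if (deg$onset_index > length(g$rna_conditions)) {
      stop("DEG onset index beyond the condition list")
    }
  }
  stopifnot(length(clip) == 2L, clip[1L] > 0, clip[2L] < 1, clip[1L] < clip[2L])

  structure(list(seed = as.integer(seed), genotypes = genotypes,
                 replicates = as.integer(replicates),
                 chrom_sizes = chrom_sizes, n_genes = as.integer(n_genes),
                 gene_length = gene_length, baseline_meth = baseline_meth,
                 coverage_mean = coverage_mean, coverage_size = coverage_size,
                 window_width = as.integer(window_width),
                 dmr = dmr, deg = deg, pairs = pairs, clip = clip),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf(
    "sim_design: %d genotype(s) x %d replicates, genome %s bp, %d genes\n",
    length(x$genotypes), x$replicates,
    format(sum(as.numeric(x$chrom_sizes)), big.mark = ","), x$n_genes))
  cat(sprintf("  planted: %d DMRs (delta %.2f), %d DEGs (lfc %.1f), %d pairs\n",
              x$dmr$n, x$dmr$delta, x$deg$n, x$pairs$n))
  invisible(x)
}

#' Classify every cytosine of a genome by sequence context
#'
#' Scans both strands for cytosines (C on the plus strand, G on the minus
#' strand) and assigns CpG/CHG/CHH from the trinucleotide read in the
#' cytosine's own 5'->3' direction. The last two positions of each strand,
#' whose trinucleotide is incomplete, are omitted.
#'
#' @param genome `Biostrings::DNAStringSet` (or named character vector of
#'   sequences).
#' @return data.frame: `chrom`, `pos`, `strand`, `context`.
#' @export
classify_cytosines <- function(genome) {
  seqs <- if (inherits(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else genome
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- lapply(names(seqs), function(ch) {
    b <- strsplit(seqs[[ch]], "", fixed = TRUE)[[1L]]
    n <- length(b)
    # plus strand: C at i, trinucleotide b[i..i+2]
    ip <- which(b == "C")
    ip <- ip[ip <= n - 2L]
    ctx_p <- ifelse(b[ip + 1L] == "G", "CpG",
                    ifelse(b[ip + 2L] == "G", "CHG", "CHH"))
    # minus strand: G at i; reading 5'->3' on the minus strand the next two
    # bases are the complements of b[i-1], b[i-2]
    im <- which(b == "G")
    im <- im[im >= 3L]
    n1 <- comp[b[im - 1L]]; n2 <- comp[b[im - 2L]]
    ctx_m <- ifelse(n1 == "G", "CpG", ifelse(n2 == "G", "CHG", "CHH"))
    data.frame(chrom = ch,
               pos = c(ip, im),
               strand = c(rep("+", length(ip)), rep("-", length(im))),
               context = c(ctx_p, ctx_m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a genome and non-overlapping gene models
#'
#' Random sequence with a uniform base mix (which yields a realistic blend
#' of CpG/CHG/CHH cytosine contexts) and genes placed uniformly without
#' overlap; deterministic under the design seed.
#'
#' @param design `sim_design`.
#' @param classify also classify cytosine contexts (needed for methylome
#'   simulation; can be skipped for expression-only runs).
#' @return list with `genome` (`DNAStringSet`), `genes` (data.frame) and
#'   `cytosines` (context table from [classify_cytosines()], or `NULL`
#'   when `classify = FALSE`).
#' @export
simulate_genome <- function(design, classify = TRUE) {
  stopifnot(inherits(design, "sim_design"))
  with_seed(design$seed + 1L, {
    seqs <- lapply(design$chrom_sizes, function(len) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = "")
    })
    genome <- Biostrings::DNAStringSet(unlist(seqs))
    names(genome) <- names(design$chrom_sizes)

    lens <- sample(seq(design$gene_length[1L], design$gene_length[2L]),
                   design$n_genes, replace = TRUE)
    chroms <- sample(names(design$chrom_sizes), design$n_genes,
                     replace = TRUE,
                     prob = as.numeric(design$chrom_sizes) /
                       sum(as.numeric(design$chrom_sizes)))
    placed <- vector("list", design$n_genes)
    occupied <- lapply(design$chrom_sizes, function(...) IRanges::IRanges())
    for (i in seq_len(design$n_genes)) {
      ch <- chroms[i]; len <- lens[i]
      lim <- design$chrom_sizes[[ch]] - len
      ok <- FALSE
      for (try in seq_len(1000L)) {
        s <- sample.int(lim, 1L)
        cand <- IRanges::IRanges(s, s + len - 1L)
        if (length(GenomicRanges::findOverlaps(cand, occupied[[ch]])) == 0L) {
          occupied[[ch]] <- c(occupied[[ch]], cand)
          placed[[i]] <- data.frame(chrom = ch, start = s, end = s + len - 1L,
                                    stringsAsFactors = FALSE)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place gene ", i, " without overlap")
    }
    genes <- do.call(rbind, placed)
    genes$strand <- sample(c("+", "-"), design$n_genes, replace = TRUE)
    genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
    genes <- data.frame(gene_id = sprintf("g%04d", seq_len(nrow(genes))),
                        genes, stringsAsFactors = FALSE)
    rownames(genes) <- NULL
    list(genome = genome, genes = genes,
         cytosines = if (classify) classify_cytosines(genome) else NULL)
  })
}

#' Plant DMRs, DEGs and anti-correlated pairs; build the truth table
#'
#' Picks planted DMR windows (window-aligned, disjoint), planted DEGs, and
#' gene-DMR pairs in which a window inside the gene's flank carries a
#' monotone methylation ramp while the gene's expression ramps the
#' opposite way. Gene baseline expression (shared across genotypes) is
#' drawn here too.
#'
#' Planted windows are drawn among windows that carry at least 20
#' cytosines of the planted context (all contexts pooled for
#' context-`"all"` plantings), so every planted DMR is assayable under the
#' methylated-cytosine window filter; when too few such windows exist the
#' densest available ones are used. Pair genes are drawn among genes with
#' baseline expression of at least 20 expected counts, keeping replicate
#' noise of the planted monotone expression profile moderate on the log
#' scale.
#'
#' @param design `sim_design`.
#' @param genome output of [simulate_genome()].
#' @return object of class `sim_truth`: `dmrs`, `degs`, `pairs`,
#'   `gene_baseline`, `windows`.
#' @export
simulate_truth <- function(design, genome) {
  stopifnot(inherits(design, "sim_design"))
  genes <- genome$genes
  windows <- tile_windows(design$chrom_sizes, design$window_width)
  with_seed(design$seed + 2L, {
    win_gr <- windows_granges(windows)

    # per-window cytosine-context counts decide which windows can carry a
    # detectable planted DMR of a given context
    ctx_counts <- matrix(Inf, nrow = nrow(windows), ncol = length(CONTEXTS),
                         dimnames = list(NULL, CONTEXTS))
    if (!is.null(genome$cytosines)) {
      cyto <- genome$cytosines
      cgr <- GenomicRanges::GRanges(cyto$chrom,
                                    IRanges::IRanges(cyto$pos, cyto$pos))
      hits <- GenomicRanges::findOverlaps(cgr, win_gr)
      ctx_counts[] <- 0
      tab <- table(factor(S4Vectors::subjectHits(hits),
                          levels = seq_len(nrow(windows))),
                   factor(cyto$context[S4Vectors::queryHits(hits)],
                          levels = CONTEXTS))
      ctx_counts[] <- as.matrix(tab)
    }
    eligible <- function(ctx, min_cyt = 20L) {
      cnt <- if (ctx == "all") rowSums(ctx_counts) else ctx_counts[, ctx]
      which(cnt >= min_cyt)
    }
    densest <- function(ctx, pool, n) {
      cnt <- if (ctx == "all") rowSums(ctx_counts) else ctx_counts[, ctx]
      pool[order(-cnt[pool])][seq_len(min(n, length(pool)))]
    }

    # gene baseline expression first: pair genes must be expressed enough
    # that the planted monotone profile is not drowned by shot noise
    gene_baseline <- stats::setNames(
      stats::rlnorm(nrow(genes), meanlog = design$deg$baseline_meanlog,
                    sdlog = design$deg$baseline_sdlog),
      genes$gene_id)

    # pairs: each needs an assayable window inside the gene's +/- flank
    n_pairs <- design$pairs$n
    expressed <- names(gene_baseline)[gene_baseline >= 20]
    if (length(expressed) < n_pairs) {
      expressed <- names(sort(gene_baseline, decreasing = TRUE))[
        seq_len(min(n_pairs, nrow(genes)))]
    }
    pair_genes <- if (n_pairs > 0L) sample(expressed, n_pairs) else character()
    pair_windows <- integer(0)
    taken <- integer(0)
    for (g in pair_genes) {
      row <- genes[genes$gene_id == g, ]
      flank_gr <- GenomicRanges::GRanges(
        row$chrom,
        IRanges::IRanges(max(1L, row$start - design$pairs$flank),
                         min(design$chrom_sizes[[row$chrom]],
                             row$end + design$pairs$flank)))
      cand <- S4Vectors::subjectHits(
        GenomicRanges::findOverlaps(flank_gr, win_gr, type = "any"))
      # keep windows fully inside the flank so the link is unambiguous
      cand <- cand[windows$start[cand] >= GenomicRanges::start(flank_gr) &
                     windows$end[cand] <= GenomicRanges::end(flank_gr)]
      cand <- setdiff(cand, taken)
      if (length(cand) == 0L) stop("no free window in the flank of gene ", g)
      good <- intersect(cand, eligible(design$pairs$context))
      if (length(good) == 0L) good <- densest(design$pairs$context, cand, 1L)
      w <- if (length(good) == 1L) good else sample(good, 1L)
      pair_windows <- c(pair_windows, w)
      taken <- c(taken, w)
    }

    # plain DMR windows: assayable windows of the sampled context
    n_dmr <- design$dmr$n
    ctx_w <- design$dmr$contexts
    dmr_ctx <- if (n_dmr > 0L) {
      sample(names(ctx_w), n_dmr, replace = TRUE, prob = ctx_w)
    } else character()
    dmr_windows <- integer(0)
    for (k in seq_len(n_dmr)) {
      pool <- setdiff(eligible(dmr_ctx[k]), c(taken, dmr_windows))
      if (length(pool) == 0L) {
        pool <- densest(dmr_ctx[k],
                        setdiff(seq_len(nrow(windows)), c(taken, dmr_windows)),
                        1L)
      }
      if (length(pool) == 0L) stop("no free window for planted DMR ", k)
      dmr_windows <- c(dmr_windows,
                       if (length(pool) == 1L) pool else sample(pool, 1L))
    }
    dmr_dir <- if (n_dmr > 0L) {
      ifelse(stats::runif(n_dmr) < design$dmr$prop_hyper, "hyper", "hypo")
    } else character()

    dmrs <- data.frame(
      dmr_id = windows$window_id[c(dmr_windows, pair_windows)],
      chrom = windows$chrom[c(dmr_windows, pair_windows)],
      start = windows$start[c(dmr_windows, pair_windows)],
      end = windows$end[c(dmr_windows, pair_windows)],
      context = c(dmr_ctx, rep(design$pairs$context, n_pairs)),
      direction = c(dmr_dir, rep("hyper", n_pairs)),
      delta = c(rep(design$dmr$delta, n_dmr),
                rep(design$pairs$delta, n_pairs)),
      profile = c(rep("step", n_dmr), rep("ramp", n_pairs)),
      onset_index = c(rep(design$dmr$onset_index, n_dmr),
                      rep(NA_integer_, n_pairs)),
      source = c(rep("dmr", n_dmr), rep("pair", n_pairs)),
      stringsAsFactors = FALSE
    )

    # planted DEGs among genes not used for pairs
    n_deg <- design$deg$n
    deg_pool <- setdiff(genes$gene_id, pair_genes)
    deg_genes <- if (n_deg > 0L) sample(deg_pool, n_deg) else character()
    degs <- data.frame(
      gene_id = deg_genes,
      sign = ifelse(stats::runif(n_deg) < design$deg$prop_up, 1L, -1L),
      lfc = rep(design$deg$lfc, n_deg),
      onset_index = rep(design$deg$onset_index, n_deg),
      stringsAsFactors = FALSE
    )

    pairs <- data.frame(
      pair_id = if (n_pairs) sprintf("pair%02d", seq_len(n_pairs)) else character(),
      gene_id = pair_genes,
      dmr_id = windows$window_id[pair_windows],
      expected_r_sign = rep(-1L, n_pairs),
      expr_span = rep(design$pairs$expr_span, n_pairs),
      stringsAsFactors = FALSE
    )

    structure(list(dmrs = dmrs, degs = degs, pairs = pairs,
                   gene_baseline = gene_baseline, windows = windows),
              class = "sim_truth")
  })
}

# Per-cytosine methylation probability for one condition index, given the
# planted truth. `ci` indexes the genotype's meth_conditions.
planted_probabilities <- function(design, cyto, truth, ci, n_cond) {
  p <- design$baseline_meth[cyto$context]
  names(p) <- NULL
  tr <- truth$dmrs
  for (k in seq_len(nrow(tr))) {
    row <- tr[k, ]
    sel <- cyto$chrom == row$chrom & cyto$pos >= row$start &
      cyto$pos <= row$end
    if (row$context != "all") sel <- sel & cyto$context == row$context
    if (!any(sel)) next
    frac <- if (row$profile == "ramp") {
      (ci - 1) / (n_cond - 1)
    } else {
      as.numeric(ci >= row$onset_index)
    }
    shift <- if (row$direction == "hyper") row$delta * frac
             else row$delta * (1 - frac) # hypo: elevated early, drops later
    p[sel] <- p[sel] + shift
  }
  pmin(pmax(p, design$clip[1L]), design$clip[2L])
}

#' Simulate per-sample cytosine reports for one genotype
#'
#' For every cytosine, coverage is drawn from the design's negative
#' binomial and the methylated-call count from a binomial whose success
#' probability is the context baseline, shifted inside planted DMR windows
#' (step at the onset condition for plain DMRs, monotone ramp for planted
#' pair DMRs). Cytosines with zero drawn coverage are omitted from the
#' report.
#'
#' @param design `sim_design`.
#' @param genome output of [simulate_genome()].
#' @param truth output of [simulate_truth()].
#' @param genotype genotype name (an entry of `design$genotypes`).
#' @return list with `calls` (named list of call data.frames, one per
#'   sample) and `samples` (sample sheet: `sample_id`, `genotype`,
#'   `condition`, `replicate`).
#' @export
simulate_methylome <- function(design, genome, truth, genotype) {
  stopifnot(inherits(design, "sim_design"), inherits(truth, "sim_truth"))
  gi <- match(genotype, names(design$genotypes))
  if (is.na(gi)) stop("unknown genotype: ", genotype)
  conds <- design$genotypes[[gi]]$meth_conditions
  cyto <- genome$cytosines %||% classify_cytosines(genome$genome)
  ncyt <- nrow(cyto)

  with_seed(design$seed + 10L + gi, {
    calls <- list()
    sheet <- list()
    for (ci in seq_along(conds)) {
      p <- planted_probabilities(design, cyto, truth, ci, length(conds))
      for (r in seq_len(design$replicates)) {
        coverage <- stats::rnbinom(ncyt, mu = design$coverage_mean,
                                   size = design$coverage_size)
        n_meth <- stats::rbinom(ncyt, coverage, p)
        keep <- coverage > 0L
        df <- data.frame(chrom = cyto$chrom[keep], pos = cyto$pos[keep],
                         strand = cyto$strand[keep],
                         n_meth = n_meth[keep],
                         n_unmeth = coverage[keep] - n_meth[keep],
                         context = cyto$context[keep],
                         stringsAsFactors = FALSE)
        id <- sprintf("%s_CH%s_rep%d", genotype, conds[ci], r)
        calls[[id]] <- df
        sheet[[id]] <- data.frame(sample_id = id, genotype = genotype,
                                  condition = conds[ci], replicate = r,
                                  stringsAsFactors = FALSE)
      }
    }
    list(calls = calls, samples = do.call(rbind, sheet))
  })
}

#' Simulate an RNA-seq count matrix for one genotype
#'
#' Baseline gene expression is log-normal (shared across genotypes via the
#' truth table); counts are negative binomial around
#' `baseline * 2^effect * size_factor`, where the effect is the planted
#' DEG log2 fold-change from its onset condition onward, or, for planted
#' anti-correlated pair genes, a linear log2 ramp down across conditions.
#'
#' @inheritParams simulate_methylome
#' @return list with `counts` (genes x samples integer matrix) and
#'   `samples` (sample sheet).
#' @export
simulate_counts <- function(design, genome, truth, genotype) {
  stopifnot(inherits(design, "sim_design"), inherits(truth, "sim_truth"))
  gi <- match(genotype, names(design$genotypes))
  if (is.na(gi)) stop("unknown genotype: ", genotype)
  conds <- design$genotypes[[gi]]$rna_conditions
  genes <- genome$genes$gene_id
  base <- truth$gene_baseline[genes]

  effect <- matrix(0, nrow = length(genes), ncol = length(conds),
                   dimnames = list(genes, conds))
  for (k in seq_len(nrow(truth$degs))) {
    row <- truth$degs[k, ]
    on <- seq_along(conds) >= row$onset_index
    effect[row$gene_id, on] <- row$sign * row$lfc
  }
  for (k in seq_len(nrow(truth$pairs))) {
    row <- truth$pairs[k, ]
    effect[row$gene_id, ] <- -row$expr_span *
      (seq_along(conds) - 1) / (length(conds) - 1)
  }

  with_seed(design$seed + 20L + gi, {
    nsamp <- length(conds) * design$replicates
    sizefac <- stats::runif(nsamp, 0.9, 1.1)
    counts <- matrix(0L, nrow = length(genes), ncol = nsamp)
    ids <- character(nsamp)
    sheet <- vector("list", nsamp)
    s <- 0L
    for (ci in seq_along(conds)) {
      mu_c <- base * 2^effect[, ci]
      for (r in seq_len(design$replicates)) {
        s <- s + 1L
        counts[, s] <- stats::rnbinom(length(genes), mu = mu_c * sizefac[s],
                                      size = 1 / design$deg$dispersion)
        ids[s] <- sprintf("%s_CH%s_rep%d", genotype, conds[ci], r)
        sheet[[s]] <- data.frame(sample_id = ids[s], genotype = genotype,
                                 condition = conds[ci], replicate = r,
                                 stringsAsFactors = FALSE)
      }
    }
    dimnames(counts) <- list(genes, ids)
    list(counts = counts, samples = do.call(rbind, sheet))
  })
}

#' Generate a complete synthetic experiment
#'
#' Runs [simulate_genome()], [simulate_truth()], and per-genotype
#' [simulate_methylome()] and [simulate_counts()], in a fixed order so the
#' whole experiment is a deterministic function of `(seed, design)`.
#'
#' @param design `sim_design`.
#' @return list with `design`, `genome`, `genes`, `truth`, `methylomes`
#'   (per genotype: `calls`, `samples`) and `rnaseq` (per genotype:
#'   `counts`, `samples`).
#' @export
simulate_experiment <- function(design = simulation_design()) {
  stopifnot(inherits(design, "sim_design"))
  genome <- simulate_genome(design)
  truth <- simulate_truth(design, genome)
  methylomes <- lapply(names(design$genotypes), function(g)
    simulate_methylome(design, genome, truth, g))
  names(methylomes) <- names(design$genotypes)
  rnaseq <- lapply(names(design$genotypes), function(g)
    simulate_counts(design, genome, truth, g))
  names(rnaseq) <- names(design$genotypes)
  list(design = design, genome = genome$genome, genes = genome$genes,
       cytosines = genome$cytosines, truth = truth,
       methylomes = methylomes, rnaseq = rnaseq)
}

#' Write a simulated experiment to disk
#'
#' Emits FASTA, GFF3, per-sample cytosine reports, per-genotype count
#' matrices and sample sheets, truth tables, and the resolved design (as
#' YAML), in a fixed layout under `outdir`.
#'
#' @param sim output of [simulate_experiment()].
#' @param outdir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  p <- file.path(outdir, "genome.fa")
  Biostrings::writeXStringSet(sim$genome, p)
  paths["genome"] <- p

  p <- file.path(outdir, "genes.gff3")
  gff <- sprintf("%s\tchillmeth\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                 sim$genes$chrom, sim$genes$start, sim$genes$end,
                 sim$genes$strand, sim$genes$gene_id)
  writeLines(c("##gff-version 3", gff), p)
  paths["genes"] <- p

  meth_dir <- file.path(outdir, "methylomes")
  dir.create(meth_dir, showWarnings = FALSE)
  sheets <- list()
  for (g in names(sim$methylomes)) {
    mm <- sim$methylomes[[g]]
    for (id in names(mm$calls)) {
      fp <- file.path(meth_dir, paste0(id, ".cx.tsv"))
      write_cytosine_report(mm$calls[[id]], fp)
      paths[paste0("meth_", id)] <- fp
    }
    sheets[[g]] <- mm$samples
  }
  p <- file.path(outdir, "samples_meth.tsv")
  data.table::fwrite(do.call(rbind, sheets), p, sep = "\t", quote = FALSE)
  paths["samples_meth"] <- p

  sheets <- list()
  for (g in names(sim$rnaseq)) {
    rr <- sim$rnaseq[[g]]
    p <- file.path(outdir, paste0("counts_", g, ".tsv"))
    out <- data.frame(gene_id = rownames(rr$counts), rr$counts,
                      check.names = FALSE, stringsAsFactors = FALSE)
    data.table::fwrite(out, p, sep = "\t", quote = FALSE)
    paths[paste0("counts_", g)] <- p
    sheets[[g]] <- rr$samples
  }
  p <- file.path(outdir, "samples_rna.tsv")
  data.table::fwrite(do.call(rbind, sheets), p, sep = "\t", quote = FALSE)
  paths["samples_rna"] <- p

  for (nm in c("dmrs", "degs", "pairs")) {
    p <- file.path(outdir, paste0("truth_", nm, ".tsv"))
    data.table::fwrite(sim$truth[[nm]], p, sep = "\t", quote = FALSE, na = "NA")
    paths[paste0("truth_", nm)] <- p
  }

  p <- file.path(outdir, "design.yaml")
  d <- sim$design
  yaml::write_yaml(list(seed = d$seed,
                        genotypes = d$genotypes,
                        replicates = d$replicates,
                        chrom_sizes = as.list(d$chrom_sizes),
                        n_genes = d$n_genes,
                        gene_length = d$gene_length,
                        baseline_meth = as.list(d$baseline_meth),
                        coverage_mean = d$coverage_mean,
                        coverage_size = d$coverage_size,
                        window_width = d$window_width,
                        dmr = d$dmr, deg = d$deg, pairs = d$pairs,
                        clip = d$clip), p)
  paths["design"] <- p
  invisible(paths)
}

#' Score DMR calls against the planted truth
#'
#' @param called character vector of called DMR window ids.
#' @param truth_ids character vector of planted DMR window ids.
#' @return list with `recall`, `precision`, `tp`, `fp`, `fn`.
#' @export
score_against_truth <- function(called, truth_ids) {
  called <- unique(called); truth_ids <- unique(truth_ids)
  tp <- length(intersect(called, truth_ids))
  list(recall = if (length(truth_ids)) tp / length(truth_ids) else NA_real_,
       precision = if (length(called)) tp / length(called) else NA_real_,
       tp = tp, fp = length(called) - tp, fn = length(truth_ids) - tp)
}
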