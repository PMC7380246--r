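# Count normalisation (TMM), negative-binomial differential expression,
# FPKM, co-expression clustering, PCA, and the small physiology utilities
# (chilling hours, chilling requirement, delta-Ct relative expression).

as_count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("gene_%06d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("sample_%02d", seq_len(ncol(counts)))
  }
  if (anyDuplicated(colnames(counts))) stop("sample labels must be unique")
  if (any(counts < 0)) stop("counts must be non-negative")
  counts
}

#' Trimmed mean of M-values (TMM) scaling factors
#'
#' Between-sample normalisation for count libraries following the
#' Robinson-Oshlack procedure. Unless a reference is given, the reference
#' sample is the one whose 75th-percentile count fraction is closest to
#' the mean across samples. For every sample, gene-wise log ratios
#' `M_g = log2((y_gj/N_j)/(y_gr/N_r))` and average abundances
#' `A_g = 0.5 log2((y_gj/N_j)(y_gr/N_r))` are computed over genes with
#' non-zero counts in both samples, doubly trimmed (30% of the M tails,
#' 5% of the A tails), and combined as a precision-weighted mean with
#' inverse asymptotic binomial variances as weights. Factors are rescaled
#' so their geometric mean is 1.
#'
#' @param counts genes x samples matrix of non-negative counts.
#' @param ref_sample optional reference sample name or index.
#' @param trim_M two-sided trim fraction on log ratios (default 0.30).
#' @param trim_A two-sided trim fraction on abundance (default 0.05).
#' @return object of class `tmm_norm`: `factors` (geometric mean 1),
#'   `lib_sizes`, `eff_lib_sizes` (= `lib_sizes * factors`) and
#'   `ref_sample`.
#' @export
tmm_factors <- function(counts, ref_sample = NULL, trim_M = 0.30,
                        trim_A = 0.05) {
  counts <- as_count_matrix(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least two samples")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("sample with all-zero counts: ", colnames(counts)[which(lib == 0)[1L]])
  }
  check_scalar(trim_M, "trim_M", min = 0, max = 0.5)
  check_scalar(trim_A, "trim_A", min = 0, max = 0.5)

  if (is.null(ref_sample)) {
    f75 <- vapply(seq_len(ncol(counts)), function(j)
      stats::quantile(counts[, j] / lib[j], 0.75), numeric(1L))
    ref <- which.min(abs(f75 - mean(f75)))
  } else {
    ref <- if (is.character(ref_sample)) match(ref_sample, colnames(counts))
           else as.integer(ref_sample)
    if (is.na(ref) || ref < 1L || ref > ncol(counts)) {
      stop("`ref_sample` not found")
    }
  }

  yr <- counts[, ref]; Nr <- lib[ref]
  logf <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    if (j == ref) { logf[j] <- 0; next }
    yj <- counts[, j]; Nj <- lib[j]
    keep <- yj > 0 & yr > 0
    y1 <- yj[keep]; y2 <- yr[keep]
    if (length(y1) == 0L) { logf[j] <- 0; next }
    M <- log2((y1 / Nj) / (y2 / Nr))
    A <- 0.5 * log2((y1 / Nj) * (y2 / Nr))
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; y1 <- y1[fin]; y2 <- y2[fin]
    n <- length(M)
    if (n == 0L) { logf[j] <- 0; next }
    if (max(abs(M)) < 1e-6) { logf[j] <- 0; next }
    loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep2)) { logf[j] <- 0; next }
    v <- (Nj - y1) / (Nj * y1) + (Nr - y2) / (Nr * y2)
    f <- sum(M[keep2] / v[keep2]) / sum(1 / v[keep2])
    logf[j] <- if (is.na(f)) 0 else f
  }
  factors <- 2^logf
  factors <- factors / exp(mean(log(factors)))
  names(factors) <- colnames(counts)

  structure(list(factors = factors, lib_sizes = lib,
                 eff_lib_sizes = lib * factors,
                 ref_sample = colnames(counts)[ref]),
            class = "tmm_norm")
}

#' @export
print.tmm_norm <- function(x, ...) {
  cat("TMM normalisation (reference:", x$ref_sample, ")\n")
  print(round(x$factors, 4))
  invisible(x)
}

# Normalised counts on a common scale (counts rescaled by effective library
# size relative to the mean effective library size).
normalized_counts <- function(counts, norm) {
  eff <- norm$eff_lib_sizes[colnames(counts)]
  sweep(counts, 2L, eff / mean(eff), "/")
}

# Pooled method-of-moments NB dispersion: per-gene moment estimates
# (pooled within-group variance vs mean on normalised counts), averaged
# over adequately expressed genes. Individual estimates are clamped to a
# wide band so no single gene dominates the pool.
estimate_dispersion <- function(z, grp) {
  lv <- split(seq_along(grp), grp)
  mu_g <- rowMeans(z)
  wv <- rep(0, nrow(z)); df <- 0
  for (ix in lv) {
    if (length(ix) < 2L) next
    sub <- z[, ix, drop = FALSE]
    wv <- wv + apply(sub, 1L, stats::var) * (length(ix) - 1L)
    df <- df + (length(ix) - 1L)
  }
  if (df == 0) return(0.1)
  wv <- wv / df
  use <- mu_g >= 5
  if (!any(use)) use <- mu_g >= 1
  if (!any(use)) return(0.1)
  phi_g <- (wv[use] - mu_g[use]) / mu_g[use]^2
  phi_g <- pmin(pmax(phi_g, -0.5), 10)
  max(mean(phi_g), 1e-4)
}

#' Negative-binomial differential expression for one contrast
#'
#' Gene-wise NB likelihood-ratio test of a two-group effect with
#' `log(effective library size)` offsets. The dispersion is common across
#' genes by default, estimated by pooled method of moments on normalised
#' counts; `"tagwise-moments"` uses, per gene, the larger of the common and
#' the gene's own moment estimate (a conservative option for heterogeneous
#' data). The log2 fold-change is computed from group means of normalised
#' counts with a pseudocount, and calls follow the usual thresholds:
#' `up` when `q < q_max` and `log2FC >= lfc_min`, `down` when `q < q_max`
#' and `log2FC <= -lfc_min`, otherwise `ns`. BH adjustment is applied
#' within the contrast.
#'
#' @param counts genes x samples count matrix (all samples; only the two
#'   contrast groups are used for testing).
#' @param conditions named vector mapping samples to condition labels.
#' @param contrast length-2 character vector `c(condition, baseline)`.
#' @param norm optional [tmm_factors()] result for `counts`; computed
#'   internally when absent.
#' @param dispersion `"common"` (default) or `"tagwise-moments"`.
#' @param q_max FDR threshold for calls (default 0.01).
#' @param lfc_min absolute log2 fold-change threshold (default 1,
#'   i.e. two-fold).
#' @param pseudocount added to group means before the log ratio
#'   (default 0.5).
#' @return data.frame with one row per gene: `gene_id`, `contrast`,
#'   `log2FC`, `p`, `q`, `call`; the dispersion used is attached as
#'   attribute `dispersion`.
#' @export
deg_test <- function(counts, conditions, contrast, norm = NULL,
                     dispersion = c("common", "tagwise-moments"),
                     q_max = 0.01, lfc_min = 1, pseudocount = 0.5) {
  dispersion <- match.arg(dispersion)
  counts <- as_count_matrix(counts)
  check_scalar(q_max, "q_max", min = 0, max = 1)
  check_scalar(lfc_min, "lfc_min", min = 0)
  check_scalar(pseudocount, "pseudocount", min = 0)
  if (length(contrast) != 2L) stop("`contrast` must be c(condition, baseline)")
  if (is.null(names(conditions))) stop("`conditions` must be named by sample")
  conditions <- conditions[colnames(counts)]
  for (lab in contrast) {
    if (sum(conditions == lab, na.rm = TRUE) == 0L) {
      stop("contrast group absent from design: ", lab)
    }
  }
  if (any(table(conditions[conditions %in% contrast]) < 2L)) {
    stop("each contrast group needs at least 2 replicates")
  }
  if (is.null(norm)) norm <- tmm_factors(counts)

  idx <- which(conditions %in% contrast)
  sub <- counts[, idx, drop = FALSE]
  grp <- factor(conditions[idx], levels = c(contrast[2L], contrast[1L]))
  eff <- norm$eff_lib_sizes[colnames(sub)]
  off <- log(eff)
  z <- normalized_counts(sub, norm)

  phi_common <- estimate_dispersion(z, grp)
  phi <- rep(phi_common, nrow(sub))
  if (dispersion == "tagwise-moments") {
    mu_g <- rowMeans(z)
    lv <- split(seq_along(grp), grp)
    wv <- rep(0, nrow(z)); df <- 0
    for (ix in lv) {
      wv <- wv + apply(z[, ix, drop = FALSE], 1L, stats::var) * (length(ix) - 1L)
      df <- df + (length(ix) - 1L)
    }
    wv <- wv / df
    tag <- ifelse(mu_g > 0, (wv - mu_g) / mu_g^2, NA_real_)
    phi <- pmax(phi_common, ifelse(is.na(tag), phi_common, tag))
  }

  n <- ncol(sub)
  X0 <- matrix(1, n, 1L)
  X1 <- stats::model.matrix(~grp)
  p <- rep(NA_real_, nrow(sub))
  for (g in seq_len(nrow(sub))) {
    y <- sub[g, ]
    if (all(y == 0)) { p[g] <- 1; next }
    fam <- MASS::negative.binomial(theta = 1 / phi[g])
    p[g] <- tryCatch({
      f0 <- suppressWarnings(stats::glm.fit(X0, y, family = fam, offset = off))
      f1 <- suppressWarnings(stats::glm.fit(X1, y, family = fam, offset = off))
      lr <- max(0, f0$deviance - f1$deviance)
      stats::pchisq(lr, df = 1L, lower.tail = FALSE)
    }, error = function(e) NA_real_)
  }
  p[is.na(p)] <- 1

  mc <- rowMeans(z[, grp == contrast[1L], drop = FALSE])
  mb <- rowMeans(z[, grp == contrast[2L], drop = FALSE])
  log2fc <- log2((mc + pseudocount) / (mb + pseudocount))
  q <- bh_adjust(p)
  call <- rep("ns", nrow(sub))
  call[q < q_max & log2fc >= lfc_min] <- "up"
  call[q < q_max & log2fc <= -lfc_min] <- "down"

  out <- data.frame(gene_id = rownames(sub),
                    contrast = contrast[1L],
                    log2FC = log2fc, p = p, q = q, call = call,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "dispersion") <- phi_common
  attr(out, "baseline") <- contrast[2L]
  out
}

#' FPKM from counts, gene lengths and effective library sizes
#'
#' `FPKM_gj = counts_gj * 1e9 / (eff_lib_size_j * length_g)`. Genes with a
#' missing length are skipped with a warning.
#'
#' @param counts genes x samples count matrix.
#' @param lengths named numeric vector of gene lengths (bp).
#' @param norm [tmm_factors()] result; computed internally when absent.
#' @return FPKM matrix (possibly fewer rows than `counts`).
#' @export
fpkm <- function(counts, lengths, norm = NULL) {
  counts <- as_count_matrix(counts)
  if (is.null(norm)) norm <- tmm_factors(counts)
  len <- lengths[rownames(counts)]
  missing <- is.na(len) | len <= 0
  if (any(missing)) {
    warning(sum(missing), " gene(s) without a valid length skipped")
    counts <- counts[!missing, , drop = FALSE]
    len <- len[!missing]
  }
  eff <- norm$eff_lib_sizes[colnames(counts)]
  sweep(counts * 1e9 / as.numeric(len), 2L, eff, "/")
}

#' Co-expression subclusters of gene profiles
#'
#' Thin wrapper over [cluster_profiles()] with the co-expression default
#' of `k = 10` subclusters (FPKM or otherwise normalised per-condition
#' mean profiles are the intended input).
#'
#' @inheritParams cluster_profiles
#' @export
coexpression_clusters <- function(profiles, k = 10L, seed = 1L, nstart = 10L) {
  cluster_profiles(profiles, k = k, seed = seed, nstart = nstart)
}

#' PCA summary of an expression matrix
#'
#' Samples are projected after a `log2(x + 1)` transform with per-gene
#' centring (the standard sample-level PCA via singular value
#' decomposition). Feed TMM-scaled counts or FPKM.
#'
#' @param x genes x samples numeric matrix.
#' @param log_transform apply `log2(x + 1)` first (default `TRUE`).
#' @return list with `scores` (samples x components data.frame) and
#'   `var_explained` (percent per component, summing to <= 100).
#' @export
pca_summary <- function(x, log_transform = TRUE) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("PCA needs at least 2 samples")
  m <- if (log_transform) log2(x + 1) else x
  pr <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  tot <- sum(pr$sdev^2)
  ve <- if (tot > 0) 100 * pr$sdev^2 / tot else rep(0, length(pr$sdev))
  scores <- as.data.frame(pr$x)
  scores <- cbind(data.frame(sample = rownames(scores),
                             stringsAsFactors = FALSE), scores)
  rownames(scores) <- NULL
  list(scores = scores, var_explained = ve)
}

#' Relative expression by the delta-Ct method
#'
#' qPCR relative expression of a target normalised to a reference gene:
#' `2^-(Ct_target - Ct_reference)`.
#'
#' @param ct_target,ct_reference cycle-threshold values (vectorised).
#' @return relative expression values.
#' @examples
#' relative_expression_dct(20, 20)    # 1
#' relative_expression_dct(21, 20)    # 0.5
#' @export
relative_expression_dct <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference))) {
    stop("Ct values must be finite")
  }
  2^(-(ct_target - ct_reference))
}

#' Chilling hours from an hourly temperature series
#'
#' Counts hours with temperature strictly below the threshold (7.2 degrees
#' Celsius by convention); an hour at exactly the threshold does not count.
#'
#' @param temps numeric vector of hourly temperatures (degrees C).
#' @param threshold chilling threshold (default 7.2).
#' @return integer count of chilling hours (0 for an empty series).
#' @export
chilling_hours <- function(temps, threshold = 7.2) {
  if (length(temps) == 0L) return(0L)
  if (any(!is.finite(temps))) stop("temperatures must be finite")
  check_scalar(threshold, "threshold")
  sum(temps < threshold)
}

#' Chilling requirement from a bud-break series
#'
#' The chilling requirement is complete at the first condition where at
#' least 50% of buds break (are swelling under forcing conditions).
#'
#' @param budbreak numeric vector of bud-break fractions in `[0, 1]`, in
#'   increasing order of chilling exposure.
#' @param conditions labels for the conditions (defaults to
#'   `names(budbreak)` or indices).
#' @param threshold completion fraction (default 0.5).
#' @return the label of the first condition meeting the threshold, or `NA`
#'   if none does.
#' @export
chilling_requirement <- function(budbreak, conditions = NULL,
                                 threshold = 0.5) {
  if (any(budbreak < 0 | budbreak > 1, na.rm = TRUE)) {
    stop("bud-break fractions must lie in [0, 1]")
  }
  if (is.null(conditions)) {
    conditions <- names(budbreak) %||% seq_along(budbreak)
  }
  hit <- which(budbreak >= threshold)
  if (length(hit) == 0L) return(NA)
  conditions[hit[1L]]
}

#' Per-condition mean expression profiles
#'
#' Gene x condition matrix of mean `log2(normalised count + pseudocount)`,
#' the expression side of methylation-expression correlation.
#'
#' @param counts genes x samples count matrix.
#' @param conditions named vector mapping samples to condition labels.
#' @param norm optional [tmm_factors()] result.
#' @param pseudocount added before the log (default 0.5).
#' @return matrix genes x conditions.
#' @export
expression_condition_profiles <- function(counts, conditions, norm = NULL,
                                          pseudocount = 0.5) {
  counts <- as_count_matrix(counts)
  if (is.null(norm)) norm <- tmm_factors(counts)
  z <- log2(normalized_counts(counts, norm) + pseudocount)
  conditions <- as.character(conditions[colnames(counts)])
  levels <- unique(conditions)
  out <- vapply(levels, function(cd)
    rowMeans(z[, conditions == cd, drop = FALSE]), numeric(nrow(z)))
  out <- matrix(out, nrow = nrow(z),
                dimnames = list(rownames(counts), levels))
  out
}
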