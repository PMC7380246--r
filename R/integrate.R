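# Joining DMRs to genes and crossing methylation direction with expression
# direction: flank-based linking, quadrant tables, cross-genotype
# conservation, methylation-expression correlation and term enrichment.

#' Link DMRs to genes within a flank
#'
#' A DMR is linked to a gene when its interval intersects the gene span
#' extended by `flank` bp on both sides (default 2,000 bp, i.e. a region
#' overlapping a gene "including 2 kb upstream and downstream"). Relative
#' position is `gene_body` when the DMR overlaps the gene span itself,
#' otherwise `upstream`/`downstream` according to the gene's strand, with
#' a signed distance (negative upstream, positive downstream, 0 for
#' overlap). A DMR falling in the extended span of several genes links to
#' each of them.
#'
#' @param dmr_windows data.frame of DMR windows with columns `window_id`
#'   (or `dmr_id`), `chrom`, `start`, `end` (1-based inclusive).
#' @param genes gene models data.frame from [read_gene_models()].
#' @param flank flank size in bp (default 2000).
#' @return data.frame with one row per (gene, DMR) pair: `gene_id`,
#'   `dmr_id`, `position`, `distance`.
#' @export
link_dmrs_to_genes <- function(dmr_windows, genes, flank = 2000L) {
  check_scalar(flank, "flank", min = 0)
  id_col <- if ("dmr_id" %in% names(dmr_windows)) "dmr_id" else "window_id"
  if (!id_col %in% names(dmr_windows)) {
    stop("`dmr_windows` needs a `window_id` or `dmr_id` column")
  }
  if (nrow(dmr_windows) == 0L || nrow(genes) == 0L) {
    return(data.frame(gene_id = character(), dmr_id = character(),
                      position = character(), distance = integer(),
                      stringsAsFactors = FALSE))
  }
  dmr_gr <- GenomicRanges::GRanges(dmr_windows$chrom,
                                   IRanges::IRanges(dmr_windows$start,
                                                    dmr_windows$end))
  ext_gr <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(genes$start - flank,
                                                    genes$end + flank))
  hits <- GenomicRanges::findOverlaps(dmr_gr, ext_gr)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  if (length(qh) == 0L) {
    return(data.frame(gene_id = character(), dmr_id = character(),
                      position = character(), distance = integer(),
                      stringsAsFactors = FALSE))
  }
  ds <- dmr_windows$start[qh]; de <- dmr_windows$end[qh]
  gs <- genes$start[sh]; ge <- genes$end[sh]
  strand <- genes$strand[sh]

  body <- de >= gs & ds <= ge
  before <- de < gs   # DMR left of the gene span
  gap <- integer(length(qh))
  gap[before] <- gs[before] - de[before]
  after <- ds > ge
  gap[after] <- ds[after] - ge[after]

  position <- rep("gene_body", length(qh))
  # left of a + gene (or right of a - gene) is upstream
  position[before & strand == "+"] <- "upstream"
  position[before & strand == "-"] <- "downstream"
  position[after & strand == "+"] <- "downstream"
  position[after & strand == "-"] <- "upstream"
  distance <- integer(length(qh))
  distance[position == "upstream"] <- -gap[position == "upstream"]
  distance[position == "downstream"] <- gap[position == "downstream"]

  out <- data.frame(gene_id = genes$gene_id[sh],
                    dmr_id = dmr_windows[[id_col]][qh],
                    position = position, distance = distance,
                    stringsAsFactors = FALSE)
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Cross DMR direction with DEG call for one contrast
#'
#' Every DMR-linked gene is assigned to a quadrant cell by the direction of
#' its linked DMR (hyper/hypo, for the given contrast) and its DEG call
#' (up/down/ns). Genes linked only to DMRs with no direction in this
#' contrast are not counted. Genes linked to DMRs of conflicting direction
#' are counted once per direction and flagged as ambiguous. Genes absent
#' from the DEG table are tallied under `no_test`, never silently dropped.
#'
#' @param links data.frame from [link_dmrs_to_genes()].
#' @param directions per-contrast DMR direction table (columns `window_id`
#'   or `dmr_id`, `contrast`, `direction`), e.g. `x$directions` of a
#'   [call_dmrs()] result.
#' @param degs DEG table from [deg_test()] (must carry the same contrast).
#' @param contrast contrast label shared by `directions` and `degs`.
#' @return object of class `quadrant_table`: cell counts (`hyper_up`,
#'   `hyper_down`, `hyper_ns`, `hypo_up`, `hypo_down`, `hypo_ns`,
#'   `no_test`), the underlying gene assignments, and ambiguous gene ids.
#' @export
quadrant_overlap <- function(links, directions, degs, contrast) {
  if (!contrast %in% degs$contrast) {
    stop("contrast '", contrast, "' absent from the DEG table")
  }
  id_col <- if ("dmr_id" %in% names(directions)) "dmr_id" else "window_id"
  dirs <- directions[directions$contrast == contrast, , drop = FALSE]
  degs <- degs[degs$contrast == contrast, , drop = FALSE]

  merged <- merge(links, dirs[, c(id_col, "direction")],
                  by.x = "dmr_id", by.y = id_col)
  cells <- c("hyper_up", "hyper_down", "hyper_ns",
             "hypo_up", "hypo_down", "hypo_ns")
  counts <- stats::setNames(integer(7L), c(cells, "no_test"))
  if (nrow(merged) == 0L) {
    return(structure(list(contrast = contrast, counts = counts,
                          genes = data.frame(gene_id = character(),
                                             direction = character(),
                                             call = character(),
                                             stringsAsFactors = FALSE),
                          ambiguous = character()),
                     class = "quadrant_table"))
  }
  gd <- unique(merged[, c("gene_id", "direction")])
  amb <- names(which(table(gd$gene_id) > 1L))
  if (length(amb)) {
    warning(length(amb), " gene(s) linked to DMRs of conflicting direction; ",
            "counted once per direction")
  }
  call_of <- stats::setNames(degs$call, degs$gene_id)
  gd$call <- call_of[gd$gene_id]
  gd$call[is.na(gd$call)] <- "no_test"

  tested <- gd$call != "no_test"
  key <- paste(gd$direction[tested], gd$call[tested], sep = "_")
  tab <- table(factor(key, levels = cells))
  counts[cells] <- as.integer(tab)
  counts["no_test"] <- sum(!tested)
  rownames(gd) <- NULL

  structure(list(contrast = contrast, counts = counts, genes = gd,
                 ambiguous = amb),
            class = "quadrant_table")
}

#' @export
print.quadrant_table <- function(x, ...) {
  cat("quadrant_table, contrast", x$contrast, "\n")
  print(x$counts)
  invisible(x)
}

#' Genes with methylation/expression patterns conserved across genotypes
#'
#' Given per-contrast quadrant tables for two genotypes, returns genes that
#' fall in the same selected class (by default hypermethylated-with-
#' downregulation or hypomethylated-with-upregulation) in at least one
#' contrast of each genotype. The contrast in which the pattern appears may
#' differ between genotypes — chilling temporality is genotype-specific —
#' so per-genotype contrast provenance is carried in the output.
#'
#' @param tables_a,tables_b lists of `quadrant_table` (one per contrast)
#'   for genotypes A and B.
#' @param classes quadrant classes to screen (default
#'   `c("hyper_down", "hypo_up")`).
#' @return data.frame: `gene_id`, `class`, `contrasts_a`, `contrasts_b`.
#' @export
conserved_patterns <- function(tables_a, tables_b,
                               classes = c("hyper_down", "hypo_up")) {
  collect <- function(tables, cls) {
    dir_call <- strsplit(cls, "_")[[1L]]
    hits <- lapply(tables, function(qt) {
      g <- qt$genes
      sel <- g$direction == dir_call[1L] & g$call == dir_call[2L]
      if (any(sel)) data.frame(gene_id = g$gene_id[sel],
                               contrast = qt$contrast,
                               stringsAsFactors = FALSE)
      else NULL
    })
    hits <- do.call(rbind, hits)
    if (is.null(hits)) {
      return(data.frame(gene_id = character(), contrast = character(),
                        stringsAsFactors = FALSE))
    }
    hits
  }
  out <- NULL
  for (cls in classes) {
    a <- collect(tables_a, cls); b <- collect(tables_b, cls)
    shared <- intersect(unique(a$gene_id), unique(b$gene_id))
    if (length(shared) == 0L) next
    rows <- data.frame(
      gene_id = shared, class = cls,
      contrasts_a = vapply(shared, function(g)
        paste(sort(unique(a$contrast[a$gene_id == g])), collapse = ","),
        character(1L)),
      contrasts_b = vapply(shared, function(g)
        paste(sort(unique(b$contrast[b$gene_id == g])), collapse = ","),
        character(1L)),
      stringsAsFactors = FALSE
    )
    out <- rbind(out, rows)
  }
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), class = character(),
                      contrasts_a = character(), contrasts_b = character(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$class, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson correlation between methylation and expression profiles
#'
#' For each gene-DMR link, computes the Pearson correlation between the
#' DMR's per-condition mean enrichment and the gene's per-condition mean
#' expression, across the conditions shared by both profiles (at least
#' `min_points`, default 3). Links are retained when `r <= r_max`
#' (default -0.5, a negative-correlation screen). Links with a
#' zero-variance profile on either side have no defined correlation and
#' are excluded with a warning.
#'
#' @param links data.frame from [link_dmrs_to_genes()].
#' @param meth_profiles matrix, DMR x condition mean enrichment (e.g. from
#'   [dmr_condition_profiles()]).
#' @param expr_profiles matrix, gene x condition mean expression (e.g.
#'   from [expression_condition_profiles()]).
#' @param r_max retention threshold on r (default -0.5).
#' @param min_points minimum shared conditions for a defined r (default 3).
#' @param closest_only keep, per gene, only the link with the smallest
#'   absolute distance (ties broken by DMR id).
#' @return data.frame: `gene_id`, `dmr_id`, `r`, `n_points`, `retained`.
#' @export
methylation_expression_correlation <- function(links, meth_profiles,
                                               expr_profiles,
                                               r_max = -0.5,
                                               min_points = 3L,
                                               closest_only = FALSE) {
  check_scalar(r_max, "r_max", min = -1, max = 1)
  check_scalar(min_points, "min_points", min = 2)
  shared <- intersect(colnames(meth_profiles), colnames(expr_profiles))
  if (length(shared) == 0L) {
    stop("condition axes of methylation and expression profiles do not match")
  }
  if (length(shared) < min_points) {
    stop(sprintf("only %d shared condition(s); %d needed for a defined r",
                 length(shared), as.integer(min_points)))
  }
  if (closest_only && nrow(links) > 0L) {
    if (!"distance" %in% names(links)) stop("`links` lacks a distance column")
    links <- links[order(links$gene_id, abs(links$distance), links$dmr_id), ,
                   drop = FALSE]
    links <- links[!duplicated(links$gene_id), , drop = FALSE]
  }
  usable <- links$dmr_id %in% rownames(meth_profiles) &
    links$gene_id %in% rownames(expr_profiles)
  links <- links[usable, , drop = FALSE]
  n <- nrow(links)
  r <- rep(NA_real_, n)
  if (n > 0L) {
    mm <- meth_profiles[links$dmr_id, shared, drop = FALSE]
    ee <- expr_profiles[links$gene_id, shared, drop = FALSE]
    for (i in seq_len(n)) {
      x <- mm[i, ]; y <- ee[i, ]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      r[i] <- stats::cor(x, y)
    }
  }
  dropped <- is.na(r)
  if (any(dropped)) {
    warning(sum(dropped),
            " link(s) with a zero-variance profile excluded (undefined r)")
  }
  out <- data.frame(gene_id = links$gene_id, dmr_id = links$dmr_id,
                    r = r, n_points = length(shared),
                    stringsAsFactors = FALSE)
  out <- out[!dropped, , drop = FALSE]
  out$retained <- out$r <= r_max
  rownames(out) <- NULL
  out
}

#' Hypergeometric term enrichment of a gene selection
#'
#' For every term in the gene-to-term map, tests whether the selection
#' contains at least the observed number of the term's genes, via the
#' hypergeometric upper tail, with BH adjustment across terms. Genes of
#' the universe not covered by the map are dropped with a warning (as is
#' any selected gene among them).
#'
#' @param selected character vector of selected gene ids (subset of
#'   `universe`).
#' @param universe character vector of background gene ids.
#' @param term_map data.frame with columns `gene_id`, `term_id` and an
#'   optional `term_name`.
#' @param q_max FDR threshold for the `enriched` flag (default 0.01).
#' @return data.frame, one row per term: `term_id`, `term_name`,
#'   `n_selected`, `n_term`, `n_universe`, `n_selection`, `p`, `q`,
#'   `enriched`; sorted by p.
#' @export
term_enrichment <- function(selected, universe, term_map, q_max = 0.01) {
  check_scalar(q_max, "q_max", min = 0, max = 1)
  if (!all(c("gene_id", "term_id") %in% names(term_map))) {
    stop("`term_map` needs columns gene_id and term_id")
  }
  selected <- unique(selected); universe <- unique(universe)
  if (!all(selected %in% universe)) {
    stop("`selected` must be a subset of `universe`")
  }
  empty <- data.frame(term_id = character(), term_name = character(),
                      n_selected = integer(), n_term = integer(),
                      n_universe = integer(), n_selection = integer(),
                      p = numeric(), q = numeric(), enriched = logical(),
                      stringsAsFactors = FALSE)
  if (length(selected) == 0L) return(empty)

  covered <- unique(term_map$gene_id)
  uncovered <- setdiff(universe, covered)
  if (length(uncovered)) {
    warning(length(uncovered), " universe gene(s) not covered by the term map dropped")
    universe <- intersect(universe, covered)
    selected <- intersect(selected, covered)
  }
  if (length(selected) == 0L || length(universe) == 0L) return(empty)

  tm <- term_map[term_map$gene_id %in% universe, , drop = FALSE]
  tm <- unique(tm[, intersect(c("gene_id", "term_id", "term_name"),
                              names(tm))])
  terms <- unique(tm$term_id)
  N <- length(universe); ns <- length(selected)
  rows <- lapply(terms, function(t) {
    tg <- unique(tm$gene_id[tm$term_id == t])
    K <- length(tg)
    k <- length(intersect(tg, selected))
    p <- stats::phyper(k - 1, K, N - K, ns, lower.tail = FALSE)
    nm <- if ("term_name" %in% names(tm)) {
      v <- tm$term_name[tm$term_id == t]
      v[which(!is.na(v))[1L]] %||% NA_character_
    } else NA_character_
    data.frame(term_id = t, term_name = nm, n_selected = k, n_term = K,
               n_universe = N, n_selection = ns, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$enriched <- out$q < q_max
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
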