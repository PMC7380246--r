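# End-to-end orchestration: simulate -> DMR calling -> DEG calling ->
# integration, with a manifest (file hashes + parameters) so a rerun with
# the same configuration is byte-identical and verifiable.

#' Build and validate a pipeline configuration
#'
#' Collects all module thresholds and paths. Defaults follow the package
#' conventions: coverage filter 5, 100-bp windows, 20 methylated cytosines
#' per window, DMR FDR 0.01 with log2 fold-change 3, DEG FDR 0.01 with
#' two-fold change, 2 kb gene flank, correlation threshold -0.5, 16 DMR
#' subclusters and 10 co-expression subclusters.
#'
#' @param outdir output directory for all stage outputs.
#' @param seed master seed (drives the simulation design unless a custom
#'   `design` is given).
#' @param design optional [simulation_design()]; default
#'   `simulation_design(seed)`.
#' @param min_coverage per-cytosine coverage filter.
#' @param window_width,window_step window tiling (step defaults to width).
#' @param min_meth_cytosines window methylated-cytosine filter.
#' @param dmr_q,dmr_delta DMR FDR and log2 fold-change thresholds.
#' @param contexts cytosine contexts for per-context DMR calling; the
#'   union of per-context calls feeds integration.
#' @param deg_q,deg_lfc DEG FDR and absolute log2 fold-change thresholds.
#' @param flank gene flank for DMR linking (bp).
#' @param r_max methylation-expression correlation retention threshold.
#' @param k_dmr,k_expr subcluster counts for DMR and co-expression
#'   profiles.
#' @param closest_only use only each gene's closest DMR for correlation.
#' @param term_map optional path to a two/three-column gene-to-term TSV;
#'   enables the enrichment stage.
#' @param threads data.table thread count (must not change results).
#' @return object of class `run_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L, design = NULL,
                            min_coverage = 5L,
                            window_width = 100L, window_step = NULL,
                            min_meth_cytosines = 20L,
                            dmr_q = 0.01, dmr_delta = 3.0,
                            contexts = CONTEXTS,
                            deg_q = 0.01, deg_lfc = 1,
                            flank = 2000L, r_max = -0.5,
                            k_dmr = 16L, k_expr = 10L,
                            closest_only = FALSE,
                            term_map = NULL, threads = 1L) {
  check_scalar(seed, "seed")
  if (is.null(design)) design <- simulation_design(seed = seed)
  stopifnot(inherits(design, "sim_design"))
  check_scalar(min_coverage, "min_coverage", min = 0)
  check_scalar(window_width, "window_width", min = 1)
  if (is.null(window_step)) window_step <- window_width
  check_scalar(window_step, "window_step", min = 1, max = window_width)
  check_scalar(min_meth_cytosines, "min_meth_cytosines", min = 0)
  check_scalar(dmr_q, "dmr_q", min = 0, max = 1)
  check_scalar(dmr_delta, "dmr_delta", min = 0)
  contexts <- normalize_context(contexts)
  stopifnot(all(contexts %in% CONTEXTS))
  check_scalar(deg_q, "deg_q", min = 0, max = 1)
  check_scalar(deg_lfc, "deg_lfc", min = 0)
  check_scalar(flank, "flank", min = 0)
  check_scalar(r_max, "r_max", min = -1, max = 1)
  check_scalar(k_dmr, "k_dmr", min = 1)
  check_scalar(k_expr, "k_expr", min = 1)
  check_scalar(threads, "threads", min = 1)
  if (!is.null(term_map) && !file.exists(term_map)) {
    stop("`term_map` path not resolvable: ", term_map)
  }
  structure(list(outdir = outdir, seed = as.integer(seed), design = design,
                 min_coverage = min_coverage, window_width = window_width,
                 window_step = window_step,
                 min_meth_cytosines = min_meth_cytosines,
                 dmr_q = dmr_q, dmr_delta = dmr_delta, contexts = contexts,
                 deg_q = deg_q, deg_lfc = deg_lfc, flank = flank,
                 r_max = r_max, k_dmr = k_dmr, k_expr = k_expr,
                 closest_only = isTRUE(closest_only), term_map = term_map,
                 threads = as.integer(threads)),
            class = "run_config")
}

log_stage <- function(...) {
  message(sprintf("[chillmeth] %s", sprintf(...)))
}

config_echo <- function(config) {
  keep <- setdiff(names(config), "design")
  out <- config[keep]
  out$design_seed <- config$design$seed
  out$genotypes <- names(config$design$genotypes)
  out
}

#' Run the full pipeline on a synthetic experiment
#'
#' Stages, in dependency order: simulate (genome, methylomes, counts,
#' truth written to disk), DMR calling per genotype (cytosine reports are
#' read back from disk through the coverage filter; per-context calls are
#' made for each configured context and their union feeds integration),
#' DEG calling per genotype and contrast, integration (links, quadrant
#' tables, cross-genotype conserved patterns, methylation-expression
#' correlation, optional term enrichment), and subclustering summaries.
#' Every output file is recorded in a manifest with its MD5 hash and the
#' full parameter echo; a rerun with an identical configuration is
#' byte-identical.
#'
#' @param config [pipeline_config()] object.
#' @return object of class `run_report` (stage counts and paths),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  old_threads <- data.table::getDTthreads()
  data.table::setDTthreads(config$threads)
  on.exit(data.table::setDTthreads(old_threads))

  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage_status <- list()
  paths <- c()
  report <- list(seed = config$seed)

  run_stage <- function(name, fn) {
    log_stage("stage %s: start (seed %d)", name, config$seed)
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      stage_status[[name]] <<- "failed"
      write_manifest(config, paths, stage_status, outdir)
      stop("stage ", name, " failed: ", conditionMessage(res), call. = FALSE)
    }
    stage_status[[name]] <<- "ok"
    log_stage("stage %s: done", name)
    res
  }

  # --- simulate ------------------------------------------------------
  sim <- run_stage("simulate", function() {
    sim <- simulate_experiment(config$design)
    paths <<- c(paths, write_simulation(sim, file.path(outdir, "sim")))
    sim
  })
  genotypes <- names(config$design$genotypes)
  report$genotypes <- genotypes

  # --- dmr ------------------------------------------------------------
  dmr_results <- run_stage("dmr", function() {
    windows <- tile_windows(config$design$chrom_sizes,
                            width = config$window_width,
                            step = config$window_step)
    lapply(stats::setNames(genotypes, genotypes), function(g) {
      sheet <- sim$methylomes[[g]]$samples
      calls <- lapply(stats::setNames(sheet$sample_id, sheet$sample_id),
                      function(id) {
        read_cytosine_report(
          file.path(outdir, "sim", "methylomes", paste0(id, ".cx.tsv")),
          min_coverage = config$min_coverage)
      })
      conds <- stats::setNames(sheet$condition, sheet$sample_id)
      baseline <- config$design$genotypes[[g]]$meth_conditions[1L]
      by_ctx <- call_dmrs_by_context(
        calls, windows, config$design$chrom_sizes, conds, baseline,
        contexts = config$contexts,
        min_meth_cytosines = config$min_meth_cytosines,
        q_max = config$dmr_q, min_delta = config$dmr_delta)
      for (ctx in names(by_ctx)) {
        p <- file.path(outdir, sprintf("dmr_%s_%s.tsv", g, ctx))
        fullp <- file.path(outdir, sprintf("dmr_%s_%s_full.tsv", g, ctx))
        write_dmrs(by_ctx[[ctx]], p, fullp)
        paths[[sprintf("dmr_%s_%s", g, ctx)]] <<- p
        paths[[sprintf("dmr_%s_%s_full", g, ctx)]] <<- fullp
      }
      by_ctx
    })
  })
  report$windows_tested <- lapply(dmr_results, function(rr)
    vapply(rr, function(x) nrow(x$windows), integer(1L)))
  report$dmrs_by_context <- lapply(dmr_results, function(rr)
    vapply(rr, function(x) sum(x$windows$is_dmr), integer(1L)))
  report$dmr_direction_counts <- lapply(dmr_results, function(rr) {
    d <- do.call(rbind, lapply(rr, function(x) x$directions))
    if (is.null(d) || nrow(d) == 0L) list() else
      as.list(table(paste(d$contrast, d$direction, sep = ":")))
  })

  # --- deg ------------------------------------------------------------
  deg_results <- run_stage("deg", function() {
    lapply(stats::setNames(genotypes, genotypes), function(g) {
      counts <- sim$rnaseq[[g]]$counts
      sheet <- sim$rnaseq[[g]]$samples
      conds <- stats::setNames(sheet$condition, sheet$sample_id)
      baseline <- config$design$genotypes[[g]]$rna_conditions[1L]
      norm <- tmm_factors(counts)
      res <- lapply(setdiff(unique(sheet$condition), baseline), function(cd) {
        deg_test(counts, conds, contrast = c(cd, baseline), norm = norm,
                 q_max = config$deg_q, lfc_min = config$deg_lfc)
      })
      tab <- do.call(rbind, res)
      p <- file.path(outdir, sprintf("degs_%s.tsv", g))
      data.table::fwrite(tab, p, sep = "\t", quote = FALSE)
      paths[[sprintf("degs_%s", g)]] <<- p
      list(table = tab, norm = norm, conditions = conds,
           baseline = baseline)
    })
  })
  report$degs_by_contrast <- lapply(deg_results, function(dd) {
    t <- dd$table[dd$table$call != "ns", , drop = FALSE]
    if (nrow(t) == 0L) list() else
      as.list(table(paste(t$contrast, t$call, sep = ":")))
  })

  # --- integrate ------------------------------------------------------
  integration <- run_stage("integrate", function() {
    lapply(stats::setNames(genotypes, genotypes), function(g) {
      by_ctx <- dmr_results[[g]]
      # union of per-context DMR windows, context provenance kept
      dmr_tabs <- lapply(names(by_ctx), function(ctx) {
        d <- dmrs(by_ctx[[ctx]])
        if (nrow(d)) cbind(d, context = ctx, stringsAsFactors = FALSE)
        else NULL
      })
      dmr_tab <- do.call(rbind, dmr_tabs)
      merged <- if (is.null(dmr_tab) || nrow(dmr_tab) == 0L) {
        data.frame(window_id = character(), chrom = character(),
                   start = integer(), end = integer(),
                   stringsAsFactors = FALSE)
      } else {
        agg <- stats::aggregate(context ~ window_id, dmr_tab,
                                function(x) paste(sort(unique(x)),
                                                  collapse = ","))
        u <- dmr_tab[!duplicated(dmr_tab$window_id),
                     c("window_id", "chrom", "start", "end")]
        merge(u, agg, by = "window_id")
      }
      directions <- unique(do.call(rbind, lapply(by_ctx, function(x)
        x$directions))[, c("window_id", "contrast", "delta", "direction")])
      directions <- directions[directions$window_id %in% merged$window_id, ,
                               drop = FALSE]
      # profiles: first context (in configured order) that called the window
      prof <- NULL
      for (ctx in names(by_ctx)) {
        pm <- dmr_condition_profiles(by_ctx[[ctx]])
        pm <- pm[!(rownames(pm) %in% rownames(prof)), , drop = FALSE]
        prof <- rbind(prof, pm)
      }

      links <- link_dmrs_to_genes(merged, sim$genes, flank = config$flank)
      p <- file.path(outdir, sprintf("links_%s.tsv", g))
      data.table::fwrite(links, p, sep = "\t", quote = FALSE)
      paths[[sprintf("links_%s", g)]] <<- p

      degs <- deg_results[[g]]$table
      quads <- lapply(unique(degs$contrast), function(cd) {
        suppressWarnings(quadrant_overlap(links, directions, degs, cd))
      })
      names(quads) <- unique(degs$contrast)
      qtab <- do.call(rbind, lapply(names(quads), function(cd)
        data.frame(contrast = cd, t(quads[[cd]]$counts),
                   stringsAsFactors = FALSE)))
      p <- file.path(outdir, sprintf("quadrants_%s.tsv", g))
      data.table::fwrite(qtab, p, sep = "\t", quote = FALSE)
      paths[[sprintf("quadrants_%s", g)]] <<- p

      expr_prof <- expression_condition_profiles(
        sim$rnaseq[[g]]$counts, deg_results[[g]]$conditions,
        norm = deg_results[[g]]$norm)
      corr <- if (is.null(prof) || nrow(links) == 0L) {
        data.frame(gene_id = character(), dmr_id = character(),
                   r = numeric(), n_points = integer(),
                   retained = logical(), stringsAsFactors = FALSE)
      } else {
        suppressWarnings(methylation_expression_correlation(
          links, prof, expr_prof, r_max = config$r_max,
          closest_only = config$closest_only))
      }
      p <- file.path(outdir, sprintf("correlations_%s.tsv", g))
      data.table::fwrite(corr, p, sep = "\t", quote = FALSE)
      paths[[sprintf("correlations_%s", g)]] <<- p

      list(links = links, quadrants = quads, correlations = corr,
           dmr_profiles = prof, expr_profiles = expr_prof)
    })
  })
  report$links <- vapply(integration, function(x) nrow(x$links), integer(1L))
  report$quadrant_counts <- lapply(integration, function(x)
    lapply(x$quadrants, function(q) as.list(q$counts)))
  report$correlations_retained <- vapply(integration, function(x)
    sum(x$correlations$retained), integer(1L))

  # --- conserved patterns across the first two genotypes --------------
  if (length(genotypes) >= 2L) {
    conserved <- run_stage("conserved", function() {
      cp <- conserved_patterns(integration[[genotypes[1L]]]$quadrants,
                               integration[[genotypes[2L]]]$quadrants)
      p <- file.path(outdir, "conserved_genes.tsv")
      data.table::fwrite(cp, p, sep = "\t", quote = FALSE)
      paths[["conserved"]] <<- p
      cp
    })
    report$conserved_genes <- nrow(conserved)
  }

  # --- enrichment (optional) -----------------------------------------
  if (!is.null(config$term_map)) {
    enr <- run_stage("enrichment", function() {
      tm <- utils::read.delim(config$term_map, header = TRUE,
                              stringsAsFactors = FALSE)
      lapply(stats::setNames(genotypes, genotypes), function(g) {
        sel <- unique(integration[[g]]$correlations$gene_id[
          integration[[g]]$correlations$retained])
        res <- suppressWarnings(
          term_enrichment(intersect(sel, sim$genes$gene_id),
                          sim$genes$gene_id, tm))
        p <- file.path(outdir, sprintf("enrichment_%s.tsv", g))
        data.table::fwrite(res, p, sep = "\t", quote = FALSE, na = "NA")
        paths[[sprintf("enrichment_%s", g)]] <<- p
        res
      })
    })
    report$enriched_terms <- vapply(enr, function(x) sum(x$enriched),
                                    integer(1L))
  }

  # --- subclusters ----------------------------------------------------
  clusters <- run_stage("subclusters", function() {
    out <- list()
    for (g in genotypes) {
      prof <- integration[[g]]$dmr_profiles
      if (!is.null(prof) && nrow(prof) >= config$k_dmr) {
        cl <- cluster_profiles(top_variance(prof, 1000L), config$k_dmr,
                               seed = config$seed)
        p <- file.path(outdir, sprintf("dmr_clusters_%s.tsv", g))
        data.table::fwrite(cl, p, sep = "\t", quote = FALSE)
        paths[[sprintf("dmr_clusters_%s", g)]] <<- p
        out[[paste0(g, "_dmr")]] <- cl
      }
      ep <- integration[[g]]$expr_profiles
      if (nrow(ep) >= config$k_expr) {
        cl <- coexpression_clusters(ep, config$k_expr, seed = config$seed)
        p <- file.path(outdir, sprintf("expr_clusters_%s.tsv", g))
        data.table::fwrite(cl, p, sep = "\t", quote = FALSE)
        paths[[sprintf("expr_clusters_%s", g)]] <<- p
        out[[paste0(g, "_expr")]] <- cl
      }
    }
    out
  })
  report$subclustered <- names(clusters)

  # --- report + manifest ---------------------------------------------
  report_path <- file.path(outdir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths[["report"]] <- report_path
  write_manifest(config, paths, stage_status, outdir)

  structure(list(report = report, paths = paths, outdir = outdir),
            class = "run_report")
}

write_manifest <- function(config, paths, stage_status, outdir) {
  files <- sort(unlist(paths))
  hashes <- tools::md5sum(files[file.exists(files)])
  manifest <- list(
    parameters = config_echo(config),
    stages = stage_status,
    files = lapply(stats::setNames(names(hashes), sub(paste0("^", outdir, "/?"), "",
                                                      names(hashes))),
                   function(f) unname(hashes[f]))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read the manifest of a completed run
#'
#' @param outdir run output directory.
#' @return manifest list (parameters, stage status, file hashes).
#' @export
read_manifest <- function(outdir) {
  jsonlite::read_json(file.path(outdir, "manifest.json"),
                      simplifyVector = TRUE)
}

#' @export
print.run_report <- function(x, ...) {
  cat("chillmeth run report (", x$outdir, ")\n", sep = "")
  cat("  genotypes:", paste(x$report$genotypes, collapse = ", "), "\n")
  for (g in x$report$genotypes) {
    cat(sprintf("  %s: DMRs %s; links %d; retained correlations %d\n", g,
                paste(sprintf("%s=%d", names(x$report$dmrs_by_context[[g]]),
                              x$report$dmrs_by_context[[g]]), collapse = " "),
                x$report$links[[g]], x$report$correlations_retained[[g]]))
  }
  if (!is.null(x$report$conserved_genes)) {
    cat("  conserved genes:", x$report$conserved_genes, "\n")
  }
  invisible(x)
}
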