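# DMR-gene linking, quadrant tables, cross-genotype conservation,
# methylation-expression correlation and term enrichment.

mk_dmr <- function(id, start, end, chrom = "chr1") {
  data.frame(window_id = id, chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}
mk_gene <- function(id, start, end, strand = "+", chrom = "chr1") {
  data.frame(gene_id = id, chrom = chrom, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

test_that("flank linking: 2 kb boundary, gene-body overlap, strand-aware sides", {
  gene <- mk_gene("g1", 10000, 12000)
  # 500 bp past the gene end: linked, downstream
  l1 <- link_dmrs_to_genes(mk_dmr("d1", 12500, 12600), gene)
  expect_equal(nrow(l1), 1L)
  expect_equal(l1$position, "downstream")
  expect_equal(l1$distance, 500L)
  # 2,100 bp past the end: outside the 2 kb flank
  expect_equal(nrow(link_dmrs_to_genes(mk_dmr("d2", 14100, 14200), gene)), 0L)
  # exactly at the boundary (gap 2,000) still links
  expect_equal(nrow(link_dmrs_to_genes(mk_dmr("d3", 14000, 14100), gene)), 1L)
  # overlapping the span: gene_body, distance 0
  l4 <- link_dmrs_to_genes(mk_dmr("d4", 9950, 10050), gene)
  expect_equal(l4$position, "gene_body")
  expect_equal(l4$distance, 0L)
  # upstream of a + gene carries a negative signed distance
  l5 <- link_dmrs_to_genes(mk_dmr("d5", 9000, 9100), gene)
  expect_equal(l5$position, "upstream")
  expect_equal(l5$distance, -900L)
  # on a minus-strand gene the same side is downstream
  l6 <- link_dmrs_to_genes(mk_dmr("d6", 9000, 9100), mk_gene("g1", 10000, 12000, "-"))
  expect_equal(l6$position, "downstream")
  expect_equal(l6$distance, 900L)

  # one DMR inside two genes' flanks links to both
  two <- rbind(mk_gene("ga", 10000, 12000), mk_gene("gb", 13000, 15000))
  l7 <- link_dmrs_to_genes(mk_dmr("d7", 12400, 12500), two)
  expect_equal(sort(l7$gene_id), c("ga", "gb"))
})

test_that("linking is invariant under whole-genome translation", {
  set.seed(6)
  genes <- do.call(rbind, lapply(1:10, function(i)
    mk_gene(sprintf("g%02d", i), i * 5000, i * 5000 + 1500,
            sample(c("+", "-"), 1))))
  dmrs <- do.call(rbind, lapply(1:15, function(i)
    mk_dmr(sprintf("d%02d", i), s <- sample(60000, 1), s + 99)))
  l0 <- link_dmrs_to_genes(dmrs, genes)
  shift <- 12345L
  genes2 <- genes; genes2$start <- genes2$start + shift; genes2$end <- genes2$end + shift
  dmrs2 <- dmrs; dmrs2$start <- dmrs2$start + shift; dmrs2$end <- dmrs2$end + shift
  expect_equal(link_dmrs_to_genes(dmrs2, genes2), l0)
})

test_that("quadrant tables classify, conserve and flag ambiguity", {
  links <- data.frame(gene_id = c("g1", "g2", "g3"),
                      dmr_id = c("d1", "d2", "d3"),
                      position = "downstream", distance = c(100L, 50L, 10L),
                      stringsAsFactors = FALSE)
  dirs <- data.frame(window_id = c("d1", "d2", "d3"), contrast = "348",
                     delta = c(2, -2, 2),
                     direction = c("hyper", "hypo", "hyper"),
                     stringsAsFactors = FALSE)
  degs <- data.frame(gene_id = c("g1", "g2"), contrast = "348",
                     log2FC = c(-2, 1.5), p = 1e-5, q = 1e-4,
                     call = c("down", "up"), stringsAsFactors = FALSE)
  qt <- quadrant_overlap(links, dirs, degs, "348")
  expect_equal(unname(qt$counts["hyper_down"]), 1L)
  expect_equal(unname(qt$counts["hypo_up"]), 1L)
  # g3 is absent from the DEG table: tallied, never dropped
  expect_equal(unname(qt$counts["no_test"]), 1L)
  expect_equal(sum(qt$counts), nrow(qt$genes))

  expect_error(quadrant_overlap(links, dirs, degs, "516"), "absent")

  # conflicting directions: counted once per direction, flagged
  links2 <- rbind(links, data.frame(gene_id = "g1", dmr_id = "d2",
                                    position = "upstream", distance = -10L))
  expect_warning(qt2 <- quadrant_overlap(links2, dirs, degs, "348"),
                 "conflicting")
  expect_equal(qt2$ambiguous, "g1")
  expect_equal(unname(qt2$counts["hyper_down"]), 1L)
  expect_equal(unname(qt2$counts["hypo_down"]), 1L)
})

test_that("quadrant cells plus no-test account for every linked gene-direction", {
  fx <- make_two_condition_wq(shift = 30)
  res <- call_dmrs(fx$wq, fx$conditions, q_max = 0.05, min_delta = 0.5,
                   baseline = "A")
  genes <- mk_gene("g1", 40, 160)
  links <- link_dmrs_to_genes(dmrs(res), genes)
  degs <- data.frame(gene_id = "g1", contrast = "B", log2FC = -2,
                     p = 1e-6, q = 1e-5, call = "down",
                     stringsAsFactors = FALSE)
  qt <- suppressWarnings(quadrant_overlap(links, res$directions, degs, "B"))
  expect_equal(sum(qt$counts), nrow(qt$genes))
})

test_that("conserved patterns require the same class in both genotypes, any contrast", {
  mk_qt <- function(contrast, gene, direction, call) {
    structure(list(contrast = contrast,
                   counts = setNames(integer(7),
                                     c("hyper_up", "hyper_down", "hyper_ns",
                                       "hypo_up", "hypo_down", "hypo_ns",
                                       "no_test")),
                   genes = data.frame(gene_id = gene, direction = direction,
                                      call = call, stringsAsFactors = FALSE),
                   ambiguous = character()),
              class = "quadrant_table")
  }
  a <- list(mk_qt("348", c("g1", "g2"), c("hyper", "hyper"), c("down", "down")))
  b <- list(mk_qt("443", "g1", "hyper", "down"),
            mk_qt("1295", "g2", "hypo", "up"))
  cp <- conserved_patterns(a, b)
  expect_equal(cp$gene_id, "g1")   # g2's class differs between genotypes
  expect_equal(cp$class, "hyper_down")
  expect_equal(cp$contrasts_a, "348")
  expect_equal(cp$contrasts_b, "443")

  # symmetric up to the provenance columns
  cp_rev <- conserved_patterns(b, a)
  expect_equal(cp_rev$gene_id, cp$gene_id)
  expect_equal(cp_rev$contrasts_a, cp$contrasts_b)

  # disjoint gene universes -> empty
  c2 <- list(mk_qt("1", "zz", "hyper", "down"))
  expect_equal(nrow(conserved_patterns(a, c2)), 0L)
})

test_that("correlation screen: known r values, retention, zero-variance exclusion", {
  links <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                      dmr_id = c("d1", "d2", "d3", "d4"),
                      position = "gene_body", distance = 0L,
                      stringsAsFactors = FALSE)
  meth <- rbind(d1 = c(1, 2, 3, 4), d2 = c(1, 2, 3, 4),
                d3 = c(0, 1, 1, 2), d4 = c(2, 2, 2, 2))
  expr <- rbind(g1 = c(4, 3, 2, 1), g2 = c(1, 2, 3, 4),
                g3 = c(5, 4, 4, 2), g4 = c(1, 5, 3, 2))
  colnames(meth) <- colnames(expr) <- c("0", "173", "348", "516")
  expect_warning(cr <- methylation_expression_correlation(links, meth, expr),
                 "zero-variance")
  expect_equal(cr$r[cr$gene_id == "g1"], -1)
  expect_true(cr$retained[cr$gene_id == "g1"])
  expect_equal(cr$r[cr$gene_id == "g2"], 1)
  expect_false(cr$retained[cr$gene_id == "g2"])
  # hand-computed Pearson for (0,1,1,2) vs (5,4,4,2)
  r_hand <- -3 / sqrt(2 * 4.75)
  expect_equal(cr$r[cr$gene_id == "g3"], r_hand, tolerance = 1e-12)
  expect_true(cr$retained[cr$gene_id == "g3"])  # r < -0.5
  # zero-variance link excluded entirely
  expect_false("g4" %in% cr$gene_id)
  expect_equal(unique(cr$n_points), 4L)

  # retention is monotone in r_max
  loose <- suppressWarnings(
    methylation_expression_correlation(links, meth, expr, r_max = -0.4))
  expect_superset(loose$gene_id[loose$retained], cr$gene_id[cr$retained])

  # condition-axis mismatch errors
  colnames(expr) <- c("0", "96", "348", "516")
  expect_error(suppressWarnings(
    methylation_expression_correlation(links, meth, expr, min_points = 4)),
    "shared condition")
})

test_that("correlation uses the conditions shared by both assays", {
  links <- data.frame(gene_id = "g1", dmr_id = "d1", position = "gene_body",
                      distance = 0L, stringsAsFactors = FALSE)
  meth <- rbind(d1 = c(`0` = 0, `173` = 1, `348` = 2, `516` = 3))
  expr <- rbind(g1 = c(`0` = 6, `348` = 4, `516` = 2))  # 3-condition assay
  cr <- methylation_expression_correlation(links, meth, expr)
  expect_equal(cr$n_points, 3L)
  expect_equal(cr$r, cor(c(0, 2, 3), c(6, 4, 2)), tolerance = 1e-12)
})

test_that("closest-only mode keeps one DMR per gene", {
  links <- data.frame(gene_id = c("g1", "g1"), dmr_id = c("dfar", "dnear"),
                      position = "downstream", distance = c(1500L, 100L),
                      stringsAsFactors = FALSE)
  meth <- rbind(dfar = c(1, 2, 3), dnear = c(3, 2, 1))
  expr <- rbind(g1 = c(3, 2, 1))
  colnames(meth) <- colnames(expr) <- c("a", "b", "c")
  cr <- methylation_expression_correlation(links, meth, expr,
                                           closest_only = TRUE)
  expect_equal(cr$dmr_id, "dnear")
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # universe 20 (fully covered by a background term), term T1 covers 5,
  # selection of 5 contains 4 of them
  universe <- sprintf("g%02d", 1:20)
  term_map <- rbind(
    data.frame(gene_id = universe, term_id = "background",
               stringsAsFactors = FALSE),
    data.frame(gene_id = universe[1:5], term_id = "T1",
               stringsAsFactors = FALSE))
  selected <- c(universe[1:4], universe[10])
  res <- term_enrichment(selected, universe, term_map, q_max = 0.05)
  p_enum <- sum(vapply(4:5, function(k)
    choose(5, k) * choose(15, 5 - k) / choose(20, 5), numeric(1)))
  expect_equal(res$p[res$term_id == "T1"], p_enum, tolerance = 1e-12)
  expect_equal(res$n_selected[res$term_id == "T1"], 4L)

  # selection = universe -> p = 1 for every term
  map2 <- data.frame(gene_id = universe,
                     term_id = rep(c("T1", "T2"), 10),
                     stringsAsFactors = FALSE)
  res2 <- term_enrichment(universe, universe, map2)
  expect_true(all(res2$p == 1))
  expect_true(all(!res2$enriched))

  # a term disjoint from the selection is never enriched
  map3 <- rbind(map2, data.frame(gene_id = universe[11:15], term_id = "T3"))
  res3 <- term_enrichment(universe[1:5], universe, map3)
  expect_gte(res3$p[res3$term_id == "T3"], 0.5)
  expect_false(res3$enriched[res3$term_id == "T3"])

  # uncovered universe genes dropped with a warning
  map4 <- data.frame(gene_id = universe[1:10], term_id = "T1")
  expect_warning(term_enrichment(universe[1:2], universe, map4), "not covered")

  expect_equal(nrow(term_enrichment(character(), universe, map2)), 0L)
  expect_error(term_enrichment("zz", universe, map2), "subset")
})
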