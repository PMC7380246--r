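# Reading/writing per-cytosine methylation calls and gene annotations, and
# targeted region summaries (control-gene and amplicon-style percentages).

empty_calls <- function() {
  data.frame(chrom = character(), pos = integer(), strand = character(),
             n_meth = integer(), n_unmeth = integer(), context = character(),
             stringsAsFactors = FALSE)
}

validate_calls <- function(calls) {
  need <- c("chrom", "pos", "strand", "n_meth", "n_unmeth", "context")
  if (!is.data.frame(calls) || !all(need %in% names(calls))) {
    stop("`calls` must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  invisible(calls)
}

#' Read a per-cytosine methylation call report
#'
#' Parses the tab-separated cytosine-report dialect produced by bisulfite
#' aligners: one line per cytosine with columns chrom, 1-based position,
#' strand, methylated-read count, unmethylated-read count, context
#' (`CG`/`CHG`/`CHH`), and an optional trinucleotide column. Context token
#' `CG` is normalised to `CpG`. Input order is preserved.
#'
#' The coverage filter lives here so that downstream window quantification
#' only ever sees qualifying cytosines; the default keeps cytosines covered
#' by at least five reads.
#'
#' @param path path to a tab-separated cytosine report.
#' @param min_coverage minimum total reads (methylated + unmethylated) for a
#'   cytosine to be retained. Default 5.
#' @return data.frame with columns `chrom`, `pos`, `strand`, `n_meth`,
#'   `n_unmeth`, `context`.
#' @examples
#' f <- tempfile()
#' writeLines("chr1\t100\t+\t5\t1\tCHH\tCCA", f)
#' read_cytosine_report(f, min_coverage = 0)
#' @export
read_cytosine_report <- function(path, min_coverage = 5L) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("`path` must name an existing file")
  }
  check_scalar(min_coverage, "min_coverage", min = 0)
  if (file.size(path) == 0) return(empty_calls())

  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character", fill = TRUE, quote = "",
                          data.table = TRUE, showProgress = FALSE)
  if (nrow(dt) == 0L) return(empty_calls())

  nc <- ncol(dt)
  if (nc < 6L) {
    stop(sprintf("malformed cytosine report at line 1: expected 6 or 7 tab-separated columns, found %d", nc))
  }
  if (nc > 7L) {
    extra <- which(!is.na(dt[[8L]]) & dt[[8L]] != "")
    stop(sprintf("malformed cytosine report at line %d: wrong column count",
                 if (length(extra)) extra[1L] else 1L))
  }
  # With fill=TRUE a short line shows up as empty/NA trailing fields.
  short <- which(is.na(dt[[6L]]) | dt[[6L]] == "")
  if (length(short)) {
    stop(sprintf("malformed cytosine report at line %d: wrong column count", short[1L]))
  }

  pos <- suppressWarnings(as.integer(dt[[2L]]))
  bad <- which(is.na(pos) | pos < 1L)
  if (length(bad)) {
    stop(sprintf("malformed cytosine report at line %d: position '%s' is not a positive integer",
                 bad[1L], dt[[2L]][bad[1L]]))
  }
  strand <- dt[[3L]]
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) {
    stop(sprintf("malformed cytosine report at line %d: strand '%s' is not '+' or '-'",
                 bad[1L], strand[bad[1L]]))
  }
  n_meth <- suppressWarnings(as.integer(dt[[4L]]))
  n_unmeth <- suppressWarnings(as.integer(dt[[5L]]))
  bad <- which(is.na(n_meth) | is.na(n_unmeth) | n_meth < 0L | n_unmeth < 0L)
  if (length(bad)) {
    stop(sprintf("malformed cytosine report at line %d: counts '%s'/'%s' are not non-negative integers",
                 bad[1L], dt[[4L]][bad[1L]], dt[[5L]][bad[1L]]))
  }
  context <- normalize_context(dt[[6L]])
  bad <- which(!context %in% CONTEXTS)
  if (length(bad)) {
    stop(sprintf("malformed cytosine report at line %d: unknown context '%s'",
                 bad[1L], dt[[6L]][bad[1L]]))
  }

  out <- data.frame(chrom = dt[[1L]], pos = pos, strand = strand,
                    n_meth = n_meth, n_unmeth = n_unmeth, context = context,
                    stringsAsFactors = FALSE)
  out <- out[(out$n_meth + out$n_unmeth) >= min_coverage, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write methylation calls as a cytosine report
#'
#' Emits the six mandatory columns of the cytosine-report dialect; a
#' write/read round trip with `min_coverage = 0` reproduces the input
#' field-for-field.
#'
#' @param calls data.frame as returned by [read_cytosine_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(calls, path) {
  validate_calls(calls)
  data.table::fwrite(calls[, c("chrom", "pos", "strand", "n_meth", "n_unmeth", "context")],
                     path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply a coverage filter to methylation calls in memory
#'
#' @param calls methylation call data.frame.
#' @param min_coverage minimum `n_meth + n_unmeth`.
#' @return filtered data.frame.
#' @export
filter_calls <- function(calls, min_coverage = 5L) {
  validate_calls(calls)
  check_scalar(min_coverage, "min_coverage", min = 0)
  out <- calls[(calls$n_meth + calls$n_unmeth) >= min_coverage, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene models from GFF3 or BED
#'
#' Returns gene coordinates in the package-wide convention: 1-based,
#' inclusive on both ends. BED input (0-based half-open) is converted at
#' this boundary; GFF3 is taken as-is. For GFF3, only features of type
#' `gene` are kept and the identifier is taken from the `ID` (or `Name`)
#' attribute; for BED, from the name column.
#'
#' @param path path to a GFF3 or 6-column BED file.
#' @param format `"auto"` (by extension/content), `"gff3"` or `"bed"`.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_models <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("`path` must name an existing file")
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  if (format == "auto") {
    if (grepl("\\.gff3?$|\\.gff$", path, ignore.case = TRUE)) {
      format <- "gff3"
    } else if (grepl("\\.bed$", path, ignore.case = TRUE)) {
      format <- "bed"
    } else {
      nf <- length(strsplit(body[1L], "\t", fixed = TRUE)[[1L]])
      format <- if (nf == 9L) "gff3" else "bed"
    }
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = format),
    error = function(e) stop("parse error reading gene models: ",
                             conditionMessage(e), call. = FALSE)
  )
  md <- S4Vectors::mcols(gr)
  if (format == "gff3") {
    if ("type" %in% names(md)) {
      keep <- as.character(md$type) == "gene"
      if (any(keep)) gr <- gr[keep]
    }
    md <- S4Vectors::mcols(gr)
    ids <- if ("ID" %in% names(md) && !all(is.na(md$ID))) as.character(md$ID)
           else if ("Name" %in% names(md)) as.character(md$Name)
           else sprintf("gene_%06d", seq_along(gr))
  } else {
    ids <- if ("name" %in% names(md) && !all(is.na(md$name))) as.character(md$name)
           else sprintf("gene_%06d", seq_along(gr))
  }
  out <- data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  out$strand[!out$strand %in% c("+", "-")] <- "+"
  if (any(out$end < out$start)) stop("parse error: gene end precedes start")
  if (anyDuplicated(out$gene_id)) {
    stop("gene identifiers are not unique: ",
         out$gene_id[duplicated(out$gene_id)][1L])
  }
  rownames(out) <- NULL
  out
}

#' Per-context percent methylation over a targeted region
#'
#' Summarises methylation calls falling inside `[start, end]` of `chrom`,
#' separately for each cytosine context, the way targeted amplicon
#' bisulfite assays are reported. The percentage is read-weighted:
#' `100 * sum(n_meth) / sum(n_meth + n_unmeth)` over qualifying cytosines.
#' Contexts with no qualifying cytosine are reported as `NA` (undefined),
#' not 0. Calls from both strands are pooled.
#'
#' @param calls methylation call data.frame.
#' @param chrom,start,end region coordinates (1-based inclusive).
#' @param min_coverage minimum per-cytosine coverage to qualify. Default 5.
#' @return data.frame with one row per context: `chrom`, `start`, `end`,
#'   `context`, `n_cytosines`, `n_meth_calls`, `n_total_calls`, `percent`.
#' @examples
#' calls <- data.frame(chrom = "chr1", pos = c(10, 20, 30), strand = "+",
#'                     n_meth = c(4, 3, 5), n_unmeth = c(1, 2, 0),
#'                     context = "CHH")
#' region_methylation_summary(calls, "chr1", 1, 100)  # CHH percent = 80
#' @export
region_methylation_summary <- function(calls, chrom, start, end,
                                       min_coverage = 5L) {
  validate_calls(calls)
  check_scalar(start, "start", min = 1)
  check_scalar(end, "end", min = 1)
  if (start > end) stop("region start exceeds end")
  check_scalar(min_coverage, "min_coverage", min = 0)

  sel <- calls$chrom == chrom & calls$pos >= start & calls$pos <= end &
    (calls$n_meth + calls$n_unmeth) >= min_coverage
  sub <- calls[sel, , drop = FALSE]
  out <- data.frame(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    context = CONTEXTS,
    n_cytosines = 0L, n_meth_calls = 0L, n_total_calls = 0L,
    percent = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(CONTEXTS)) {
    cc <- sub[sub$context == CONTEXTS[i], , drop = FALSE]
    if (nrow(cc) == 0L) next
    meth <- sum(cc$n_meth)
    total <- meth + sum(cc$n_unmeth)
    out$n_cytosines[i] <- nrow(cc)
    out$n_meth_calls[i] <- meth
    out$n_total_calls[i] <- total
    out$percent[i] <- if (total > 0) 100 * meth / total else NA_real_
  }
  out
}

#' Write region methylation summaries as TSV
#'
#' @param summary data.frame from [region_methylation_summary()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_summary <- function(summary, path) {
  data.table::fwrite(summary, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
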