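#' Read GWAS summary statistics
#'
#' Tab-delimited text with a header naming columns `snp`, `chrom`, `pos`
#' (1-based) and `p`. Positions are converted to the package's internal
#' 0-based convention on parse (column `pos0`). Rows with p outside (0, 1]
#' are rejected and counted; a non-numeric p is a row-level error.
#'
#' @param con File path or connection.
#' @return `data.frame` with columns `snp`, `chrom`, `pos0`, `p` and an
#'   attribute `n_rejected` giving the count of out-of-range rows dropped.
#' @export
read_gwas_table <- function(con) {
  lines <- read_input_lines(con)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("empty GWAS table")
  hdr <- tolower(strsplit(lines[1L], "\t", fixed = TRUE)[[1]])
  need <- c("snp", "chrom", "pos", "p")
  miss <- setdiff(need, hdr)
  if (length(miss))
    stop("GWAS table missing column(s): ", paste(miss, collapse = ", "))
  idx <- match(need, hdr)
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  short <- which(lengths(rows) < max(idx))
  if (length(short))
    stop(sprintf("GWAS table line %d has too few fields", short[1L] + 1L))
  getcol <- function(j) vapply(rows, `[[`, character(1), j)
  snp <- getcol(idx[1L]); chrom <- getcol(idx[2L])
  pos <- suppressWarnings(as.numeric(getcol(idx[3L])))
  praw <- getcol(idx[4L])
  p <- suppressWarnings(as.numeric(praw))
  if (anyNA(p))
    stop(sprintf("non-numeric p-value '%s' at GWAS table line %d",
                 praw[which(is.na(p))[1L]], which(is.na(p))[1L] + 1L))
  if (anyNA(pos) || any(pos < 1))
    stop("GWAS positions must be integers >= 1 (1-based)")
  keep <- p > 0 & p <= 1
  n_rej <- sum(!keep)
  if (n_rej > 0L)
    message(n_rej, " GWAS row(s) rejected: p outside (0, 1]")
  out <- data.frame(snp = snp[keep], chrom = chrom[keep],
                    pos0 = as.integer(pos[keep]) - 1L, p = p[keep],
                    stringsAsFactors = FALSE)
  attr(out, "n_rejected") <- n_rej
  out
}

#' Write GWAS summary statistics
#'
#' Inverse of [read_gwas_table()]; positions are written back 1-based.
#'
#' @param snps `data.frame` with columns `snp`, `chrom`, `pos0`, `p`.
#' @param path Output file path.
#' @param provenance Optional character vector written as `#`-prefixed
#'   header lines.
#' @return `path`, invisibly.
#' @export
write_gwas_table <- function(snps, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  writeLines("snp\tchrom\tpos\tp", con)
  writeLines(paste(snps$snp, snps$chrom, snps$pos0 + 1L,
                   sprintf("%.15g", snps$p), sep = "\t"), con)
  invisible(path)
}

#' Read gene coordinates from BED6
#'
#' BED6 (chrom, start, end, name, score, strand), 0-based half-open, the
#' package's internal coordinate convention.
#'
#' @param con File path or connection.
#' @return `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, input order preserved.
#' @export
read_gene_bed <- function(con) {
  lines <- read_input_lines(con)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty BED input")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 6L)
  if (length(bad))
    stop(sprintf("BED line %d has fewer than 6 columns", bad[1L]))
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  gene_id <- vapply(fields, `[[`, character(1), 4L)
  strand <- vapply(fields, `[[`, character(1), 6L)
  if (anyNA(start) || anyNA(end)) stop("non-integer BED coordinates")
  if (any(start >= end)) {
    i <- which(start >= end)[1L]
    stop(sprintf("BED line %d: start (%d) must be < end (%d)",
                 i, start[i], end[i]))
  }
  if (!all(strand %in% c("+", "-")))
    stop("BED strand must be '+' or '-'")
  data.frame(gene_id = gene_id, chrom = chrom, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

#' Write gene coordinates to BED6
#'
#' @param genes `data.frame` as returned by [read_gene_bed()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(genes, path) {
  writeLines(paste(genes$chrom, genes$start, genes$end, genes$gene_id, 0L,
                   genes$strand, sep = "\t"), path)
  invisible(path)
}

#' Order convergence-report rows
#'
#' The canonical display order: GWAS-SNP-bearing genes first, then genes
#' without a SNP, then genes with unknown SNP status; within a block by
#' descending differential-expression -log10(p), ties broken by gene id.
#'
#' @param report Convergence-report `data.frame` (see [convergence_report()]).
#' @return The report, reordered.
#' @export
order_report <- function(report) {
  snp_rank <- ifelse(is.na(report$has_gwas_snp), 2L,
                     ifelse(report$has_gwas_snp, 0L, 1L))
  report[order(snp_rank, -report$de_minus_log10_p, report$gene_id), ,
         drop = FALSE]
}

#' Write a convergence report
#'
#' TSV uses `"."` for missing values; JSON is round-trippable via
#' [read_report_json()]. Rows are emitted in the deterministic order of
#' [order_report()].
#'
#' @param report Convergence-report `data.frame`.
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @param provenance Optional character vector; written as `#`-prefixed
#'   header lines (TSV) or a `provenance` field (JSON).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv", "json"),
                         provenance = NULL) {
  format <- match.arg(format)
  report <- order_report(report)
  if (format == "json") {
    payload <- list(provenance = as.list(provenance), genes = report)
    jsonlite::write_json(payload, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  cols <- c("gene_id", "has_gwas_snp", "de_minus_log10_p", "in_gvm",
            "in_mvg", "pathways_gvm", "pathways_mvg")
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(report)) {
    fmt <- function(v) {
      out <- as.character(v)
      if (is.logical(v)) out <- ifelse(v, "true", "false")
      if (is.numeric(v)) out <- sprintf("%.15g", v)
      out[is.na(v) | !nzchar(out)] <- "."
      out
    }
    writeLines(do.call(paste, c(lapply(report[cols], fmt), sep = "\t")), con)
  }
  invisible(path)
}

#' Read a JSON convergence report
#'
#' @param path JSON file written by [write_report()].
#' @return List with `provenance` and the `genes` `data.frame`.
#' @export
read_report_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  genes <- obj$genes
  if (is.null(genes) || length(genes) == 0L) {
    genes <- empty_report()
  } else {
    genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  }
  list(provenance = unlist(obj$provenance), genes = genes)
}

# internal: zero-row report skeleton
empty_report <- function() {
  data.frame(gene_id = character(0), has_gwas_snp = logical(0),
             de_minus_log10_p = numeric(0), in_gvm = logical(0),
             in_mvg = logical(0), pathways_gvm = character(0),
             pathways_mvg = character(0), stringsAsFactors = FALSE)
}
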