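#' Read a GCT expression matrix
#'
#' Parses the GSEA GCT dialect: a `#1.2` version line, a dimensions line, a
#' header line (`Name`, `Description`, sample ids) and one row per gene.
#' Declared dimensions must match the body exactly; mismatches are errors,
#' never repaired.
#'
#' @param con File path or connection.
#' @return A list with `matrix` (genes x samples, dimnames set) and
#'   `gene_desc` (named character).
#' @export
read_gct <- function(con) {
  lines <- read_input_lines(con)
  if (length(lines) < 3L || !startsWith(lines[1L], "#1.2"))
    stop("not a GCT file: missing #1.2 version line")
  dims <- as.integer(strsplit(trimws(lines[2L]), "\t|\\s+")[[1]][1:2])
  if (anyNA(dims)) stop("GCT dimensions line unreadable")
  header <- strsplit(lines[3L], "\t", fixed = TRUE)[[1]]
  samples <- header[-(1:2)]
  if (length(samples) != dims[2L])
    stop(sprintf("GCT declares %d samples but header has %d columns",
                 dims[2L], length(samples)))
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  if (length(body) != dims[1L])
    stop(sprintf("GCT declares %d genes but body has %d rows",
                 dims[1L], length(body)))
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != dims[2L] + 2L))
    stop(sprintf("GCT row %d has %d fields, expected %d",
                 which(nf != dims[2L] + 2L)[1L],
                 nf[nf != dims[2L] + 2L][1L], dims[2L] + 2L))
  gene_ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers in GCT")
  desc <- setNames(vapply(fields, `[[`, character(1), 2L), gene_ids)
  vals <- vapply(fields, function(f) as.numeric(f[-(1:2)]),
                 numeric(dims[2L]))
  x <- if (dims[2L] == 1L) matrix(vals, ncol = 1L) else t(vals)
  if (anyNA(x)) stop("non-numeric expression values in GCT body")
  dimnames(x) <- list(gene_ids, samples)
  list(matrix = x, gene_desc = desc)
}

#' Write a GCT expression matrix
#'
#' @param x Numeric genes x samples matrix with dimnames.
#' @param path Output file path.
#' @param gene_desc Optional named descriptions; defaults to `"na"`.
#' @return `path`, invisibly.
#' @export
write_gct <- function(x, path, gene_desc = NULL) {
  check_expression_matrix(x)
  desc <- setNames(rep("na", nrow(x)), rownames(x))
  if (!is.null(gene_desc)) desc[names(gene_desc)] <- gene_desc
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(x), ncol(x), sep = "\t"),
               paste(c("Name", "Description", colnames(x)), collapse = "\t")),
             con)
  rows <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], desc[[rownames(x)[i]]],
            sprintf("%.15g", x[i, ])), collapse = "\t")
  }, character(1))
  writeLines(rows, con)
  invisible(path)
}

#' Read a CLS phenotype file
#'
#' Supports the two GSEA CLS dialects: categorical
#' (`<n> <k> 1` / `# name1 name2` / label line) and continuous
#' (`#numeric` / `#name` / value line).
#'
#' @param con File path or connection.
#' @return A [phenotype].
#' @export
read_cls <- function(con) {
  lines <- read_input_lines(con)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("CLS file needs 3 non-empty lines")
  if (startsWith(trimws(lines[1L]), "#numeric")) {
    name <- sub("^#", "", trimws(lines[2L]))
    vals <- as.numeric(strsplit(trimws(lines[3L]), "\\s+")[[1]])
    if (anyNA(vals)) stop("non-numeric value in continuous CLS")
    return(phenotype(vals, kind = "continuous", name = name))
  }
  hdr <- suppressWarnings(
    as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1]]))
  if (length(hdr) < 2L || anyNA(hdr[1:2]))
    stop("unknown CLS dialect: bad header line")
  n <- hdr[1L]; k <- hdr[2L]
  if (k != 2L) stop("only two-class categorical CLS supported, got ", k)
  cls_names <- strsplit(sub("^#\\s*", "", trimws(lines[2L])), "\\s+")[[1]]
  if (length(cls_names) != k) stop("CLS class-name line does not list ",
                                   k, " names")
  toks <- strsplit(trimws(lines[3L]), "\\s+")[[1]]
  if (length(toks) != n)
    stop(sprintf("CLS declares %d samples but label line has %d", n,
                 length(toks)))
  labels <- if (all(toks %in% cls_names)) {
    toks
  } else if (all(grepl("^[0-9]+$", toks))) {
    cls_names[as.integer(toks) + 1L]
  } else stop("CLS labels neither class names nor 0-based indices")
  phenotype(labels, kind = "binary", class_names = cls_names)
}

#' Write a CLS phenotype file
#'
#' @param pheno A [phenotype].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cls <- function(pheno, path) {
  stopifnot(inherits(pheno, "phenotype"))
  lines <- if (pheno$kind == "continuous") {
    c("#numeric", paste0("#", pheno$name),
      paste(sprintf("%.15g", pheno$values), collapse = " "))
  } else {
    c(paste(length(pheno$values), 2, 1),
      paste("#", paste(pheno$class_names, collapse = " ")),
      paste(pheno$values, collapse = " "))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GCT/CLS pair
#'
#' Reads an expression matrix and its phenotype together, enforcing that the
#' CLS sample count matches the GCT column count.
#'
#' @param gct,cls File paths or connections.
#' @return List with `matrix`, `gene_desc` and `phenotype`.
#' @export
read_gct_cls <- function(gct, cls) {
  g <- read_gct(gct)
  p <- read_cls(cls)
  if (length(p$values) != ncol(g$matrix))
    stop(sprintf("CLS has %d samples but GCT has %d columns",
                 length(p$values), ncol(g$matrix)))
  list(matrix = g$matrix, gene_desc = g$gene_desc, phenotype = p)
}
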