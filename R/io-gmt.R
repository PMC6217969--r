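# line-oriented readers accept a file path or an open connection
read_input_lines <- function(con) {
  if (inherits(con, "connection")) readLines(con, warn = FALSE)
  else readLines(con, warn = FALSE)
}

#' Read a GMT gene-set file
#'
#' Parses the tab-delimited GMT format (one gene set per line:
#' name, description, members...). Duplicate gene symbols within a line are
#' deduplicated preserving first occurrence; line order is preserved.
#'
#' @param con File path or connection.
#' @param source_label Label recorded on the returned collection; defaults to
#'   the file path.
#' @return A [gene_set_collection].
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("S1\tdesc\tG1\tG2", f)
#' read_gmt(f)
#' @export
read_gmt <- function(con, source_label = NULL) {
  if (is.null(source_label))
    source_label <- if (is.character(con)) basename(con) else "gmt"
  lines <- read_input_lines(con)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT input")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop(sprintf("GMT format error: line %d has %d field(s), need >= 3",
                 bad[1L], length(fields[[bad[1L]]])))
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene-set names in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  desc <- setNames(vapply(fields, `[[`, character(1), 2L), nm)
  sets <- setNames(lapply(fields, function(f) {
    m <- f[-(1:2)]
    m <- m[nzchar(m)]
    m[!duplicated(m)]
  }), nm)
  gene_set_collection(sets, desc, source_label)
}

#' Write a gene-set collection to GMT
#'
#' @param collection A [gene_set_collection].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$desc[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
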