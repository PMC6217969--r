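#' Gene-set collection
#'
#' A lightweight container for a collection of gene sets, the in-memory
#' analogue of a GMT file: a named list of unique member vectors plus an
#' optional per-set description and a free-text source label.
#'
#' @param sets Named list of character vectors; names are set identifiers,
#'   elements are gene identifiers. Members must be non-empty and unique
#'   within a set; set names must be unique within the collection.
#' @param desc Optional named character vector of set descriptions; missing
#'   entries default to `""`.
#' @param source_label Free-text provenance label for the collection.
#'
#' @return An object of class `gene_set_collection` with fields `sets`,
#'   `desc` and `source_label`.
#' @examples
#' gs <- gene_set_collection(list(S1 = c("G1", "G2"), S2 = c("G2", "G3")))
#' length(gs)
#' @export
gene_set_collection <- function(sets, desc = NULL, source_label = "") {
  if (!is.list(sets) || length(sets) == 0L)
    stop("'sets' must be a non-empty named list of character vectors")
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("every gene set needs a non-empty name")
  if (anyDuplicated(nm))
    stop("duplicate gene-set names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(sets, function(m) {
    m <- as.character(m)
    if (length(m) == 0L || any(!nzchar(m)))
      stop("gene-set members must be non-empty identifiers")
    if (anyDuplicated(m)) stop("duplicate members within a gene set")
    m
  })
  d <- setNames(rep("", length(sets)), nm)
  if (!is.null(desc)) d[names(desc)] <- as.character(desc)
  structure(list(sets = sets, desc = d, source_label = source_label),
            class = "gene_set_collection")
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
names.gene_set_collection <- function(x) names(x$sets)

#' @export
`[.gene_set_collection` <- function(x, i) {
  gene_set_collection(x$sets[i], x$desc[names(x$sets[i])], x$source_label)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- lengths(x$sets)
  cat(sprintf("gene_set_collection: %d sets (sizes %d-%d)%s\n",
              length(x$sets), min(sz), max(sz),
              if (nzchar(x$source_label)) paste0(" [", x$source_label, "]")
              else ""))
  invisible(x)
}

#' Sample phenotype
#'
#' Per-sample phenotype, either a two-class factor (e.g. symptomatic vs
#' asymptomatic plaques) or a continuous covariate (e.g. %plaque-lipid area
#' from MRI T2 mapping). Class 1 for differential statistics is always
#' `class_names[1]`.
#'
#' @param values For `kind = "binary"`, a character vector of class labels;
#'   for `kind = "continuous"`, a numeric vector.
#' @param kind `"binary"` or `"continuous"`.
#' @param class_names For binary phenotypes, the two class names in the order
#'   (class 1, class 2); defaults to order of first appearance in `values`.
#'   Each class needs at least one sample at construction; the differential
#'   statistics impose their own stricter per-class minima.
#' @param name Phenotype name used when serializing to CLS.
#'
#' @return An object of class `phenotype` with fields `kind`, `values`,
#'   `class_names` and `name`.
#' @examples
#' phenotype(rep(c("sym", "asym"), each = 3))
#' phenotype(c(10.2, 33.8, 25.0), kind = "continuous", name = "lipid_pct")
#' @export
phenotype <- function(values, kind = c("binary", "continuous"),
                      class_names = NULL, name = "phenotype") {
  kind <- match.arg(kind)
  if (kind == "binary") {
    values <- as.character(values)
    if (is.null(class_names)) class_names <- unique(values)
    class_names <- as.character(class_names)
    if (length(class_names) != 2L)
      stop("binary phenotype needs exactly 2 classes, got ",
           length(class_names))
    if (!all(values %in% class_names))
      stop("labels outside declared class names")
    tab <- table(factor(values, levels = class_names))
    if (any(tab < 1L))
      stop("each class needs at least 1 sample")
  } else {
    values <- as.numeric(values)
    if (anyNA(values)) stop("continuous phenotype has missing values")
    class_names <- NULL
  }
  structure(list(kind = kind, values = values, class_names = class_names,
                 name = name),
            class = "phenotype")
}

#' @export
length.phenotype <- function(x) length(x$values)

#' @export
print.phenotype <- function(x, ...) {
  if (x$kind == "binary") {
    tab <- table(factor(x$values, levels = x$class_names))
    cat(sprintf("binary phenotype '%s': %s\n", x$name,
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  } else {
    cat(sprintf("continuous phenotype '%s': n=%d, range [%g, %g]\n",
                x$name, length(x$values), min(x$values), max(x$values)))
  }
  invisible(x)
}

# internal: validate a gene x sample expression matrix
check_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(x))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(x))) stop("duplicate sample identifiers")
  if (anyNA(x)) stop("expression matrix contains missing values")
  invisible(x)
}

# internal: indices of the two phenotype classes, class 1 first
class_indices <- function(pheno) {
  stopifnot(inherits(pheno, "phenotype"), pheno$kind == "binary")
  list(i1 = which(pheno$values == pheno$class_names[1L]),
       i2 = which(pheno$values == pheno$class_names[2L]))
}
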