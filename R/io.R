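#' Labeled expression matrix
#'
#' The container every pipeline stage consumes: a dense cells x genes matrix
#' of nonnegative expression values, unique gene identifiers, and one class
#' label per cell drawn from an ordered set of class names.
#'
#' @param values numeric matrix, cells in rows, genes in columns.
#' @param gene_ids character vector of unique gene identifiers (one per column).
#' @param labels character vector of class labels (one per row).
#' @param class_names ordered character vector of the class set; defaults to
#'   the sorted unique labels.
#' @return object of class `labeled_matrix` with elements `values`,
#'   `gene_ids`, `labels`, `class_names`.
#' @export
labeled_matrix <- function(values, gene_ids, labels,
                           class_names = sort(unique(labels))) {
  values <- as.matrix(values)
  gene_ids <- as.character(gene_ids)
  labels <- as.character(labels)
  if (ncol(values) != length(gene_ids)) {
    stop("gene_ids length (", length(gene_ids), ") must equal ncol(values) (",
         ncol(values), ")")
  }
  if (nrow(values) != length(labels)) {
    stop("labels length (", length(labels), ") must equal nrow(values) (",
         nrow(values), ")")
  }
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (anyNA(values)) stop("values must not contain missing entries")
  bad <- setdiff(unique(labels), class_names)
  if (length(bad)) {
    stop("labels contain values outside class_names: ",
         paste(bad, collapse = ", "))
  }
  colnames(values) <- gene_ids
  structure(list(values = values, gene_ids = gene_ids, labels = labels,
                 class_names = as.character(class_names)),
            class = "labeled_matrix")
}

#' @export
print.labeled_matrix <- function(x, ...) {
  cat(sprintf("labeled_matrix: %d cells x %d genes, %d classes (%s)\n",
              nrow(x$values), ncol(x$values), length(x$class_names),
              paste(sprintf("%s=%d", x$class_names,
                            tabulate(factor(x$labels, x$class_names),
                                     length(x$class_names))),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.labeled_matrix <- function(x) dim(x$values)

#' Write a labeled matrix to disk
#'
#' `csv`/`tsv`: one row per cell, header row of gene IDs, final column
#' `label`. `mtx`: MatrixMarket coordinate file plus two sidecar text files
#' `<path>.genes.txt` (one gene ID per line) and `<path>.labels.txt` (one
#' label per line).
#'
#' @param x a [labeled_matrix()].
#' @param path output file path.
#' @param format one of "csv", "tsv", "mtx".
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, format = c("csv", "tsv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "labeled_matrix"))
  if (format %in% c("csv", "tsv")) {
    df <- data.table::as.data.table(x$values)
    data.table::setnames(df, x$gene_ids)
    data.table::set(df, j = "label", value = x$labels)
    data.table::fwrite(df, path, sep = if (format == "csv") "," else "\t")
  } else {
    m <- Matrix::Matrix(x$values, sparse = TRUE)
    Matrix::writeMM(m, path)
    writeLines(x$gene_ids, paste0(path, ".genes.txt"))
    writeLines(x$labels, paste0(path, ".labels.txt"))
  }
  invisible(path)
}

#' Read a labeled matrix written by [write_matrix()]
#'
#' @param path input file path.
#' @param format one of "csv", "tsv", "mtx".
#' @param class_names optional ordered class set; defaults to sorted unique
#'   labels found in the file.
#' @return a [labeled_matrix()].
#' @export
read_matrix <- function(path, format = c("csv", "tsv", "mtx"),
                        class_names = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format %in% c("csv", "tsv")) {
    df <- data.table::fread(path, sep = if (format == "csv") "," else "\t",
                            header = TRUE, data.table = FALSE,
                            colClasses = NULL)
    if (!"label" %in% names(df)) {
      stop("format error: no 'label' column in ", path)
    }
    labels <- as.character(df[["label"]])
    df[["label"]] <- NULL
    miss <- which(is.na(labels) | labels == "")
    if (length(miss)) {
      stop("format error: missing label on row ", miss[1])
    }
    vals <- as.matrix(df)
    if (!is.numeric(vals)) {
      bad_col <- which(!vapply(df, is.numeric, logical(1)))[1]
      bad_row <- which(is.na(suppressWarnings(as.numeric(df[[bad_col]]))))[1]
      stop("parse error: non-numeric expression value at row ", bad_row,
           ", column ", names(df)[bad_col])
    }
    labeled_matrix(vals, gene_ids = names(df), labels = labels,
                   class_names = class_names %||% sort(unique(labels)))
  } else {
    genes_path <- paste0(path, ".genes.txt")
    labels_path <- paste0(path, ".labels.txt")
    if (!file.exists(genes_path) || !file.exists(labels_path)) {
      stop("format error: missing sidecar file(s) ", genes_path, " / ",
           labels_path)
    }
    m <- as.matrix(Matrix::readMM(path))
    gene_ids <- readLines(genes_path)
    labels <- readLines(labels_path)
    labeled_matrix(m, gene_ids = gene_ids, labels = labels,
                   class_names = class_names %||% sort(unique(labels)))
  }
}

#' Map gene identifiers to symbols through a two-column mapping table
#'
#' Unmapped identifiers pass through unchanged (with a message). Duplicate
#' identifier rows with conflicting symbols are an error; malformed rows are
#' reported with their line number.
#'
#' @param ids character vector of identifiers to map.
#' @param mapping_table path to a two-column delimited file (id, symbol;
#'   tab or comma separated, no header required) or a two-column data frame.
#' @return character vector of symbols, same length/order as `ids`.
#' @export
map_gene_ids <- function(ids, mapping_table) {
  stopifnot(length(ids) > 0)
  if (is.character(mapping_table) && length(mapping_table) == 1L) {
    lines <- readLines(mapping_table)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
      map <- data.frame(id = character(), symbol = character())
    } else {
      parts <- strsplit(lines, "[\t,]")
      bad <- which(lengths(parts) != 2L)
      if (length(bad)) {
        stop("malformed mapping row at line ", bad[1], ": ", lines[bad[1]])
      }
      map <- data.frame(id = trimws(vapply(parts, `[[`, "", 1L)),
                        symbol = trimws(vapply(parts, `[[`, "", 2L)))
    }
  } else {
    map <- as.data.frame(mapping_table)
    if (ncol(map) < 2L) stop("mapping table must have two columns (id, symbol)")
    names(map)[1:2] <- c("id", "symbol")
  }
  if (nrow(map)) {
    dup <- map[duplicated(map$id) | duplicated(map$id, fromLast = TRUE), ]
    if (nrow(dup)) {
      conflicts <- tapply(dup$symbol, dup$id, function(s) length(unique(s)) > 1L)
      if (any(conflicts)) {
        stop("conflicting symbols for duplicated id(s): ",
             paste(names(conflicts)[conflicts], collapse = ", "))
      }
      map <- map[!duplicated(map$id), ]
    }
  }
  out <- map$symbol[match(ids, map$id)]
  unmapped <- is.na(out)
  if (any(unmapped)) {
    message(sum(unmapped), " identifier(s) not in mapping table; passed through")
    out[unmapped] <- ids[unmapped]
  }
  out
}
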