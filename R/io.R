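# Readers/writers for the interchange formats: GMT gene sets, expression /
# beta matrices as TSV (feature ids in the first column, sample ids as
# header), metadata TSV (one row per sample), and full-precision results
# tables.

#' Read gene sets from a GMT file
#'
#' Tab-separated: set name, description, then member genes.  Trailing empty
#' fields (a common dialect) are dropped.
#'
#' @param path file path.
#' @return a [pathway_collection()] with descriptions in
#'   `attr(x, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_invalid("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(f) {
    if (length(f) < 3L) stop_invalid("GMT line with fewer than 3 fields")
    genes <- f[-(1:2)]
    genes[nzchar(genes)]
  })
  names(sets) <- vapply(parts, `[[`, "", 1L)
  out <- pathway_collection(sets)
  attr(out, "description") <- stats::setNames(vapply(parts, `[[`, "", 2L),
                                              names(sets))
  out
}

#' Write gene sets to a GMT file
#'
#' @param collection a [pathway_collection()].
#' @param path output path.
#' @param description optional named character of per-set descriptions
#'   (defaults to the set name).
#' @export
write_gmt <- function(collection, path, description = NULL) {
  stopifnot(inherits(collection, "pathway_collection"))
  if (is.null(description)) {
    description <- attr(collection, "description") %||%
      stats::setNames(names(collection), names(collection))
  }
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, description[[nm]] %||% nm, collection[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
}

# numeric matrix with feature ids in column 1, sample ids as header
read_feature_matrix <- function(path, what = "feature") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_invalid("matrix file needs id column plus samples")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop_invalid("duplicate ", what, " ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1L], is.numeric, TRUE))
    culprit <- df[[bad[1L] + 1L]]
    row <- which(is.na(suppressWarnings(as.numeric(culprit))))[1L]
    stop_invalid("non-numeric cell at row ", row %||% "?", ", column '",
                 names(df)[bad[1L] + 1L], "'")
  }
  rownames(m) <- ids
  m
}

write_feature_matrix <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), format_full(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# full-precision decimal rendering so tables round-trip losslessly
format_full <- function(x) {
  if (is.matrix(x)) {
    out <- apply(x, 2L, function(col) sprintf("%.17g", col))
    dimnames(out) <- dimnames(x)
    return(out)
  }
  sprintf("%.17g", x)
}

#' Read an expression study from matrix + metadata TSVs
#'
#' The matrix has probe ids in the first column and sample ids as header;
#' the metadata has one row per sample.  Header sample ids and metadata rows
#' must match exactly (offenders are listed), duplicate probe ids are
#' rejected, and non-numeric cells raise a parse error naming the position.
#'
#' @param matrix_path path to the expression TSV.
#' @param metadata_path path to the sample metadata TSV.
#' @param gene_map_path optional two-column TSV (probe, gene); identity map
#'   when absent.
#' @return an [expression_study()].
#' @export
read_expression <- function(matrix_path, metadata_path, gene_map_path = NULL) {
  m <- read_feature_matrix(matrix_path, what = "probe")
  meta <- utils::read.delim(metadata_path, check.names = FALSE,
                            stringsAsFactors = FALSE,
                            colClasses = "character")
  p2g <- NULL
  if (!is.null(gene_map_path)) {
    gm <- utils::read.delim(gene_map_path, stringsAsFactors = FALSE)
    p2g <- stats::setNames(as.character(gm[[2L]]), as.character(gm[[1L]]))
  }
  expression_study(m, meta, p2g)
}

#' Write an expression study to matrix + metadata TSVs
#'
#' Values are written at full precision so that write-then-read round-trips
#' exactly.
#'
#' @param study an [expression_study()].
#' @param matrix_path,metadata_path output paths.
#' @export
write_expression <- function(study, matrix_path, metadata_path) {
  stopifnot(inherits(study, "expression_study"))
  write_feature_matrix(study$values, matrix_path, id_col = "probe_id")
  utils::write.table(study$samples, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a methylation study
#'
#' Either from a beta matrix (`beta_path`), or from paired methylated /
#' unmethylated intensity matrices converted through
#' [beta_from_intensities()] on load.
#'
#' @param beta_path path to a beta TSV (markers x samples), or `NULL`.
#' @param annotation_path marker annotation TSV with columns marker, gene,
#'   functional_group, relation_to_island.
#' @param metadata_path sample metadata TSV.
#' @param methylated_path,unmethylated_path intensity TSVs, used when
#'   `beta_path` is `NULL`.
#' @return a [methylation_study()].
#' @export
read_methylation <- function(beta_path = NULL, annotation_path, metadata_path,
                             methylated_path = NULL, unmethylated_path = NULL) {
  if (is.null(beta_path)) {
    if (is.null(methylated_path) || is.null(unmethylated_path)) {
      stop_invalid("give beta_path or both intensity paths")
    }
    X <- read_feature_matrix(methylated_path, what = "marker")
    Y <- read_feature_matrix(unmethylated_path, what = "marker")
    if (!identical(dimnames(X), dimnames(Y))) {
      stop_invalid("intensity matrices must share dimnames")
    }
    beta <- beta_from_intensities(X, Y)
  } else {
    beta <- read_feature_matrix(beta_path, what = "marker")
  }
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  meta <- utils::read.delim(metadata_path, check.names = FALSE,
                            stringsAsFactors = FALSE,
                            colClasses = "character")
  methylation_study(beta, ann, meta)
}

#' Write a results table at full precision
#'
#' Numeric columns are rendered with 17 significant digits so that reading
#' the file back reproduces the values bit-for-bit; display rounding belongs
#' in reports, not in stored tables.
#'
#' @param df data.frame of results.
#' @param path output path.
#' @export
write_results_table <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- format_full(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a results table written by [write_results_table()]
#' @param path file path.
#' @return data.frame with numeric columns restored.
#' @export
read_results_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
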