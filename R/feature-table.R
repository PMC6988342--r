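#' Feature-by-sample table
#'
#' The universal currency of the pipeline: a non-negative numeric matrix with
#' features (OTUs, genes, taxa, pathways) on rows and samples on columns,
#' plus a flag saying whether entries are raw counts or per-sample relative
#' abundances.
#'
#' @param values numeric matrix, features x samples, with unique row and
#'   column names
#' @param kind "counts" (non-negative, integral) or "relative" (each sample
#'   column sums to 1)
#' @return an object of class `feature_table`
#' @export
feature_table <- function(values, kind = c("counts", "relative")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have feature row names and sample column names")
  }
  ft <- structure(list(values = values, kind = kind), class = "feature_table")
  validate_feature_table(ft)
  ft
}

#' Validate a feature table against its invariants
#'
#' @param ft a `feature_table`
#' @return `ft` invisibly; stops with an informative error on violation
#' @export
validate_feature_table <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  v <- ft$values
  if (anyDuplicated(rownames(v))) {
    stop("duplicate feature IDs: ",
         paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(v))) {
    stop("duplicate sample IDs: ",
         paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", "))
  }
  if (anyNA(v) || any(!is.finite(v))) stop("non-finite values in table")
  neg <- which(v < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative value at feature '%s', sample '%s'",
                 rownames(v)[neg[1L, 1L]], colnames(v)[neg[1L, 2L]]))
  }
  if (ft$kind == "relative") {
    cs <- colSums(v)
    bad <- which(abs(cs - 1) > 1e-9)
    if (length(bad)) {
      stop("relative-abundance columns must sum to 1; offending sample(s): ",
           paste(colnames(v)[utils::head(bad, 5L)], collapse = ", "))
    }
  }
  invisible(ft)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$kind))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Feature IDs of a table
#' @param ft a `feature_table`
#' @return character vector
#' @export
feature_ids <- function(ft) rownames(ft$values)

#' Sample IDs of a table
#' @param ft a `feature_table`
#' @return character vector
#' @export
sample_ids <- function(ft) colnames(ft$values)

#' Subset a feature table by ID
#'
#' Always indexes by string ID, never by position.
#'
#' @param ft a `feature_table`
#' @param features,samples character vectors of IDs to keep (NULL = all)
#' @return a `feature_table`
#' @export
subset_table <- function(ft, features = NULL, samples = NULL) {
  v <- ft$values
  if (!is.null(features)) {
    missing <- setdiff(features, rownames(v))
    if (length(missing)) stop("unknown feature IDs: ", paste(utils::head(missing, 5L), collapse = ", "))
    v <- v[features, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(v))
    if (length(missing)) stop("unknown sample IDs: ", paste(utils::head(missing, 5L), collapse = ", "))
    v <- v[, samples, drop = FALSE]
  }
  structure(list(values = v, kind = ft$kind), class = "feature_table")
}

#' Convert a count table to per-sample relative abundances
#'
#' Normalization is always per sample column; all-zero columns are rejected
#' because they have no defined composition.
#'
#' @param ft a `feature_table` of counts
#' @return a `feature_table` with kind "relative"
#' @export
relative_abundance <- function(ft) {
  if (ft$kind == "relative") return(ft)
  cs <- colSums(ft$values)
  if (any(cs == 0)) {
    stop("all-zero sample column(s): ",
         paste(colnames(ft$values)[cs == 0], collapse = ", "))
  }
  feature_table(sweep(ft$values, 2L, cs, "/"), kind = "relative")
}

#' Read a feature table from disk
#'
#' The canonical on-disk format is a tab-delimited matrix with a
#' `#FeatureID` header cell, feature rows and sample columns. BIOM-style
#' JSON (dense or sparse, format 1.0) is accepted read-only.
#'
#' @param path file path (.tsv/.txt or .biom/.json)
#' @param kind "counts" or "relative"
#' @return a validated `feature_table`
#' @export
read_feature_table <- function(path, kind = c("counts", "relative")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^\\s*\\{", first) || grepl("\\.(biom|json)$", path, ignore.case = TRUE)) {
    return(read_biom_json(path, kind = kind))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty table file: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  ncells <- lengths(cells)
  if (length(unique(ncells)) != 1L) {
    stop(sprintf("ragged rows in %s: line %d has %d fields, expected %d",
                 path, which(ncells != ncells[1L])[1L], ncells[ncells != ncells[1L]][1L],
                 ncells[1L]))
  }
  header <- cells[[1L]]
  samples <- header[-1L]
  body <- cells[-1L]
  if (!length(body)) stop("no feature rows in ", path)
  features <- vapply(body, `[[`, character(1L), 1L)
  num <- suppressWarnings(
    vapply(body, function(r) as.numeric(r[-1L]), numeric(length(samples)))
  )
  # vapply returns samples x features; transpose to features x samples
  m <- if (length(samples) == 1L) matrix(num, nrow = length(features)) else t(num)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at feature '%s', sample '%s' in %s",
                 features[bad[1L]], samples[bad[2L]], path))
  }
  dimnames(m) <- list(features, samples)
  feature_table(m, kind = kind)
}

# BIOM format 1.0 (JSON) reader; dense and sparse matrix_type supported.
read_biom_json <- function(path, kind = "counts") {
  b <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- vapply(b$rows, function(r) as.character(r$id), character(1L))
  cols <- vapply(b$columns, function(cc) as.character(cc$id), character(1L))
  m <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  if (identical(b$matrix_type, "dense")) {
    for (i in seq_along(b$data)) m[i, ] <- as.numeric(unlist(b$data[[i]]))
  } else {
    for (trip in b$data) {
      m[trip[[1L]] + 1L, trip[[2L]] + 1L] <- as.numeric(trip[[3L]])
    }
  }
  feature_table(m, kind = kind)
}

#' Write a feature table as canonical TSV
#'
#' @param ft a `feature_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_feature_table <- function(ft, path) {
  validate_feature_table(ft)
  v <- ft$values
  header <- paste(c("#FeatureID", colnames(v)), collapse = "\t")
  rows <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[i], format(v[i, ], digits = 15L, scientific = FALSE,
                                   trim = TRUE)), collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}
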