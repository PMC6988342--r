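#' Taxonomy map
#'
#' Maps each feature (OTU) ID to an ordered lineage across the ranks
#' kingdom, phylum, class, order, family, genus. Unassigned ranks are empty
#' strings; an assigned rank may never follow an unassigned one (prefix
#' property), matching how closed-reference taxonomies truncate at the last
#' characterized level.
#'
#' @param feature_id character vector
#' @param lineage character matrix or data.frame with columns kingdom,
#'   phylum, class, order, family, genus ("" = unassigned)
#' @return a data.frame of class `taxonomy_map`
#' @export
taxonomy_map <- function(feature_id, lineage) {
  ranks <- taxonomy_ranks()
  lineage <- as.data.frame(lineage, stringsAsFactors = FALSE)
  if (!all(ranks %in% names(lineage))) {
    stop("lineage must have columns: ", paste(ranks, collapse = ", "))
  }
  tm <- cbind(data.frame(feature_id = as.character(feature_id),
                         stringsAsFactors = FALSE),
              lineage[ranks])
  class(tm) <- c("taxonomy_map", "data.frame")
  validate_taxonomy(tm)
  tm
}

#' Ordered taxonomic ranks used throughout the package
#' @return character vector of the six ranks
#' @export
taxonomy_ranks <- function() {
  c("kingdom", "phylum", "class", "order", "family", "genus")
}

#' Validate a taxonomy map (prefix property)
#' @param tm a `taxonomy_map`
#' @return `tm` invisibly
#' @export
validate_taxonomy <- function(tm) {
  ranks <- taxonomy_ranks()
  if (anyDuplicated(tm$feature_id)) stop("duplicate feature IDs in taxonomy")
  lin <- as.matrix(tm[ranks])
  lin[is.na(lin)] <- ""
  assigned <- matrix(nzchar(lin), nrow = nrow(lin))
  # prefix property: once a rank is unassigned, all deeper ranks must be too
  for (i in seq_len(nrow(lin))) {
    a <- assigned[i, ]
    if (any(a) && any(!a) && max(which(a)) > min(which(!a))) {
      stop("taxonomy for '", tm$feature_id[i],
           "' assigns a rank below an unassigned one")
    }
  }
  invisible(tm)
}

#' Read a taxonomy map from TSV
#'
#' Accepts either one column per rank, or a single `lineage` column with
#' GreenGenes-style strings `k__...; p__...; ...; g__...`.
#'
#' @param path file path
#' @return a `taxonomy_map`
#' @export
read_taxonomy <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!"feature_id" %in% names(raw)) stop("taxonomy file needs a feature_id column")
  ranks <- taxonomy_ranks()
  if (all(ranks %in% names(raw))) {
    return(taxonomy_map(raw$feature_id, raw[ranks]))
  }
  if (!"lineage" %in% names(raw)) {
    stop("taxonomy file needs rank columns or a lineage column")
  }
  parts <- strsplit(raw$lineage, ";\\s*")
  lin <- t(vapply(parts, function(p) {
    out <- setNames(rep("", 6L), ranks)
    for (tok in p) {
      pre <- substr(tok, 1L, 3L)
      rk <- switch(pre, "k__" = "kingdom", "p__" = "phylum", "c__" = "class",
                   "o__" = "order", "f__" = "family", "g__" = "genus", NA_character_)
      if (!is.na(rk)) out[[rk]] <- substring(tok, 4L)
    }
    out
  }, character(6L)))
  taxonomy_map(raw$feature_id, as.data.frame(lin, stringsAsFactors = FALSE))
}

#' Write a taxonomy map as TSV
#' @param tm a `taxonomy_map`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_taxonomy <- function(tm, path) {
  utils::write.table(as.data.frame(tm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Label for a feature at `rank`: the rank name if assigned, else the last
# characterized level with its one-letter rank prefix (e.g. "f__Ruminococcaceae").
glom_label <- function(lineage_row, rank) {
  ranks <- taxonomy_ranks()
  idx <- match(rank, ranks)
  prefixes <- c("k", "p", "c", "o", "f", "g")
  vals <- as.character(lineage_row[ranks[seq_len(idx)]])
  assigned <- nzchar(vals) & !is.na(vals)
  if (!any(assigned)) return("unassigned")
  last <- max(which(assigned))
  paste0(prefixes[last], "__", vals[last])
}
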