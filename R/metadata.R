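#' Sample metadata constructor
#'
#' Per-sample study design: disease condition (CF or Healthy), a three-level
#' CFTR genotype category (Healthy = no mutation, CF_df508 = homozygous
#' delta-F508 deletion, CF_other = any other CF mutation status), and a flag
#' marking blank-extraction negative controls. Negative controls carry no
#' condition requirement; for real samples the genotype must be consistent
#' with the condition (genotype Healthy iff condition Healthy).
#'
#' @param sample_id character vector
#' @param condition character, "CF" or "Healthy" (NA allowed for controls)
#' @param genotype character, "Healthy", "CF_df508" or "CF_other"
#' @param is_negative_control logical
#' @return a data.frame of class `sample_metadata`
#' @export
sample_metadata <- function(sample_id, condition, genotype,
                            is_negative_control = FALSE) {
  n <- length(sample_id)
  md <- data.frame(
    sample_id = as.character(sample_id),
    condition = as.character(condition),
    genotype = as.character(genotype),
    is_negative_control = rep_len(as.logical(is_negative_control), n),
    stringsAsFactors = FALSE
  )
  class(md) <- c("sample_metadata", "data.frame")
  validate_metadata(md)
  md
}

#' Validate sample metadata
#' @param md a `sample_metadata` data.frame
#' @return `md` invisibly
#' @export
validate_metadata <- function(md) {
  req <- c("sample_id", "condition", "genotype", "is_negative_control")
  missing <- setdiff(req, names(md))
  if (length(missing)) stop("metadata missing column(s): ", paste(missing, collapse = ", "))
  if (!nrow(md)) stop("no samples in metadata")
  if (anyDuplicated(md$sample_id)) stop("duplicate sample IDs in metadata")
  real <- !md$is_negative_control
  bad_cond <- real & !md$condition %in% c("CF", "Healthy")
  if (any(bad_cond)) {
    stop("unknown condition for sample(s): ",
         paste(md$sample_id[bad_cond], collapse = ", "),
         " (expected CF or Healthy)")
  }
  bad_geno <- real & !md$genotype %in% c("Healthy", "CF_df508", "CF_other")
  if (any(bad_geno)) {
    stop("unknown genotype for sample(s): ", paste(md$sample_id[bad_geno], collapse = ", "))
  }
  incons <- real & ((md$genotype == "Healthy") != (md$condition == "Healthy"))
  if (any(incons)) {
    stop("condition/genotype inconsistency for sample(s): ",
         paste(md$sample_id[incons], collapse = ", "),
         " (genotype is Healthy iff condition is Healthy)")
  }
  invisible(md)
}

#' Read sample metadata from a tab-delimited file
#'
#' Required columns: sample_id, condition, genotype, is_negative_control
#' (true/false, TRUE/FALSE, 1/0).
#'
#' @param path file path
#' @return a validated `sample_metadata` data.frame
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!nrow(raw)) stop("no samples in metadata file: ", path)
  req <- c("sample_id", "condition", "genotype", "is_negative_control")
  missing <- setdiff(req, names(raw))
  if (length(missing)) stop("metadata missing column(s): ", paste(missing, collapse = ", "))
  flag <- tolower(trimws(raw$is_negative_control))
  if (!all(flag %in% c("true", "false", "1", "0"))) {
    stop("is_negative_control must be true/false")
  }
  sample_metadata(raw$sample_id, trimws(raw$condition), trimws(raw$genotype),
                  flag %in% c("true", "1"))
}

#' Write sample metadata as TSV
#' @param md a `sample_metadata` data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_metadata <- function(md, path) {
  validate_metadata(md)
  out <- md
  out$is_negative_control <- ifelse(md$is_negative_control, "true", "false")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Real (non-control) samples shared between a table and the metadata,
# in table order.
real_samples <- function(ft, md) {
  validate_metadata(md)
  keep <- md$sample_id[!md$is_negative_control]
  align_ids(sample_ids(ft), keep, what = "real samples")
}

# Condition vector for the given sample IDs, from metadata.
condition_of <- function(md, ids) {
  m <- match(ids, md$sample_id)
  if (anyNA(m)) stop("samples missing from metadata: ",
                     paste(ids[is.na(m)], collapse = ", "))
  md$condition[m]
}
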