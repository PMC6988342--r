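#' Prevalence-based contaminant scores
#'
#' Scores each taxon by comparing its presence (count > 0, or >= `min_count`)
#' in blank-extraction negative controls against true samples. The score is
#' the one-sided Fisher exact (hypergeometric) p-value for the alternative
#' "prevalence is higher in negative controls", so small scores flag likely
#' reagent contaminants. Features absent everywhere score 1 by convention
#' (absence is no evidence of contamination) and are flagged.
#'
#' @param table a counts `feature_table` containing both true-sample and
#'   control columns
#' @param meta a `sample_metadata` data.frame (needs >= 1 negative control
#'   and >= 1 true sample present in the table)
#' @param threshold classification threshold in (0, 1); features scoring
#'   below it are called contaminants (0.1 is the customary default, 0.2 a
#'   stricter sensitivity setting)
#' @param min_count minimum count for presence (default 1, i.e. count > 0)
#' @return data.frame with one row per feature: feature_id,
#'   present_in_controls, n_controls, present_in_samples, n_samples, score,
#'   is_contaminant, flag
#' @export
prevalence_score <- function(table, meta, threshold = 0.1, min_count = 1L) {
  stopifnot(inherits(table, "feature_table"))
  validate_metadata(meta)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  ids <- sample_ids(table)
  ctrl_ids <- intersect(ids, meta$sample_id[meta$is_negative_control])
  real_ids <- intersect(ids, meta$sample_id[!meta$is_negative_control])
  if (!length(ctrl_ids)) {
    stop("no negative controls in the table; skip contaminant screening")
  }
  if (!length(real_ids)) stop("no true samples in the table")
  present <- table$values >= min_count
  k_ctrl <- rowSums(present[, ctrl_ids, drop = FALSE])
  k_real <- rowSums(present[, real_ids, drop = FALSE])
  n_ctrl <- length(ctrl_ids)
  n_real <- length(real_ids)
  # one-sided Fisher exact on the 2x2 presence table; P(X >= k_ctrl) for
  # hypergeometric X with k_ctrl + k_real successes among n_ctrl + n_real
  score <- stats::phyper(k_ctrl - 1L, k_ctrl + k_real,
                         n_ctrl + n_real - k_ctrl - k_real, n_ctrl,
                         lower.tail = FALSE)
  absent <- (k_ctrl + k_real) == 0L
  score[absent] <- 1.0
  res <- data.frame(
    feature_id = feature_ids(table),
    present_in_controls = as.integer(k_ctrl),
    n_controls = n_ctrl,
    present_in_samples = as.integer(k_real),
    n_samples = n_real,
    score = as.numeric(score),
    is_contaminant = as.numeric(score) < threshold,
    flag = ifelse(absent, "undefined table", ""),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  res
}

#' Remove contaminant features and control columns
#'
#' @param table a counts `feature_table`
#' @param scores result of [prevalence_score()] covering all features
#' @param meta a `sample_metadata` data.frame (identifies control columns)
#' @param threshold classification threshold in (0, 1): features with
#'   score < threshold are removed
#' @return the filtered `feature_table`, restricted to true-sample columns
#' @export
filter_contaminants <- function(table, scores, meta, threshold = 0.1) {
  stopifnot(inherits(table, "feature_table"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  missing <- setdiff(feature_ids(table), scores$feature_id)
  if (length(missing)) {
    stop("scores missing for feature(s): ", paste(utils::head(missing, 5L), collapse = ", "))
  }
  sc <- scores$score[match(feature_ids(table), scores$feature_id)]
  drop <- feature_ids(table)[sc < threshold]
  if (length(drop)) {
    gn_log(sprintf("removing %d contaminant feature(s) at threshold %.2g: %s",
                   length(drop), threshold, paste(drop, collapse = ", ")))
  }
  keep_feat <- setdiff(feature_ids(table), drop)
  ctrl <- meta$sample_id[meta$is_negative_control]
  keep_samp <- setdiff(sample_ids(table), ctrl)
  subset_table(table, features = keep_feat, samples = keep_samp)
}
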