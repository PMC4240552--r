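# Step-5 recruitment rules: a protein joins a seed group only if the
# profile comparison clears both the E-value and the coverage threshold,
# and joins at most one group.

#' Apply the recruitment thresholds and tie-breaks to a hit table
#'
#' A hit is assignable iff `evalue < evalue_threshold` (strict) and
#' `min(seq_coverage, profile_coverage) >= min_coverage`. Among a
#' protein's assignable hits the lowest E-value wins, then the higher
#' minimum coverage, then the lexicographically smallest group id.
#'
#' @param hits data.frame with columns protein, group_id, evalue,
#'   seq_coverage, profile_coverage.
#' @param params a [meta_params] object (or list with the two thresholds).
#' @return named character vector: protein token -> group id.
#' @export
select_assignments <- function(hits, params) {
  if (nrow(hits) == 0L) return(stats::setNames(character(0), character(0)))
  min_cov <- pmin(hits$seq_coverage, hits$profile_coverage)
  ok <- hits$evalue < params$evalue_threshold & min_cov >= params$min_coverage
  hits <- hits[ok, , drop = FALSE]
  if (nrow(hits) == 0L) return(stats::setNames(character(0), character(0)))
  min_cov <- pmin(hits$seq_coverage, hits$profile_coverage)
  ord <- order(hits$protein, hits$evalue, -min_cov, hits$group_id, method = "radix")
  hits <- hits[ord, , drop = FALSE]
  best <- hits[!duplicated(hits$protein), , drop = FALSE]
  stats::setNames(best$group_id, best$protein)
}

#' Assign unassigned proteins to seed-group profiles
#'
#' Scores every unassigned sequence against every calibrated profile and
#' applies [select_assignments]. Profiles are fixed during the pass: an
#' assignment never updates a profile.
#'
#' @param profiles list of calibrated [profile_model]s with group ids.
#' @param unassigned named character vector of sequences.
#' @param params a [meta_params].
#' @return named character vector: protein token -> group id.
#' @export
assign_unassigned <- function(profiles, unassigned, params) {
  if (length(profiles) == 0L || length(unassigned) == 0L) {
    return(stats::setNames(character(0), character(0)))
  }
  for (p in profiles) {
    if (is.null(p$calibration)) stop("uncalibrated profile: ", p$group_id, call. = FALSE)
  }
  hits <- do.call(rbind, lapply(profiles, function(p) {
    codes_hits <- lapply(names(unassigned), function(nm) {
      score_sequence(p, unassigned[[nm]], ref = nm)
    })
    do.call(rbind, codes_hits)
  }))
  select_assignments(hits, params)
}
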