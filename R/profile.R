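# Builtin profile backend: a position-specific log-odds score table over
# the match columns of a seed alignment, searched with affine-gap local
# alignment, with E-values from an empirical Gumbel null fitted to
# shuffled-decoy scores. This plays the role a profile HMM plays in the
# external backend; it is not a full Plan7 model.

SCORE_FLOOR <- -16  # bits; clamp for residues unseen in a column

#' Build a position-specific profile from an alignment
#'
#' Columns with more than 50\% gaps are excluded from the match states.
#' Column residue frequencies use Henikoff position-based sequence
#' weights, mixed with the background by a pseudocount whose weight is
#' `2 * pseudocount_weight / (neff + 1)` (0.5 at one effective sequence
#' with the default, decaying as the effective count grows); `neff` is
#' the mean number of distinct residues per match column. Match scores
#' are `log2(frequency / background)` in bits, clamped below at -16;
#' unknown residues (X) score 0.
#'
#' @param msa an [build_msa] result.
#' @param background named background frequencies over the 20 residues
#'   summing to 1 (default [robinson_frequencies]).
#' @param pseudocount_weight non-negative pseudocount strength.
#' @param gap_open,gap_extend positive local-alignment gap penalties, bits.
#' @param group_id optional id recorded in hits.
#' @return object of class `profile_model`.
#' @export
build_profile <- function(msa, background = robinson_frequencies(),
                          pseudocount_weight = 0.5,
                          gap_open = 4, gap_extend = 1, group_id = NULL) {
  stopifnot(inherits(msa, "msa"))
  background <- background[AA_ALPHABET]
  if (anyNA(background) || abs(sum(background) - 1) > 1e-9) {
    stop("background must cover the 20 residues and sum to 1", call. = FALSE)
  }
  mat <- do.call(rbind, lapply(msa$rows, function(r) encode_aln_row(r)))
  n_rows <- nrow(mat)
  gap_frac <- colMeans(mat == 0L)
  match_cols <- which(gap_frac <= 0.5)
  if (length(match_cols) == 0L) {
    stop("no match columns: every column is more than 50% gaps", call. = FALSE)
  }
  # Henikoff position-based weights over match columns
  w <- numeric(n_rows)
  distinct_per_col <- numeric(length(match_cols))
  for (k in seq_along(match_cols)) {
    col <- mat[, match_cols[k]]
    res <- col[col > 0L & col <= 20L]
    if (length(res) == 0L) next
    counts <- table(res)
    distinct_per_col[k] <- length(counts)
    idx <- which(col > 0L & col <= 20L)
    w[idx] <- w[idx] + 1 / (length(counts) * as.numeric(counts[as.character(col[idx])]))
  }
  if (sum(w) == 0) w <- rep(1, n_rows)
  w <- w / sum(w)
  neff <- mean(distinct_per_col[distinct_per_col > 0])
  bg_w <- min(1, 2 * pseudocount_weight / (neff + 1))
  L <- length(match_cols)
  scores <- matrix(0, nrow = L, ncol = 21L,
                   dimnames = list(NULL, AA_X))
  consensus <- character(L)
  for (k in seq_len(L)) {
    col <- mat[, match_cols[k]]
    obs <- numeric(20L)
    sel <- which(col > 0L & col <= 20L)
    for (i in sel) obs[col[i]] <- obs[col[i]] + w[i]
    if (sum(obs) > 0) obs <- obs / sum(obs)
    freq <- (1 - bg_w) * obs + bg_w * background
    sc <- ifelse(freq > 0, log2(freq / background), SCORE_FLOOR)
    scores[k, 1:20] <- pmax(sc, SCORE_FLOOR)
    consensus[k] <- AA_ALPHABET[which.max(obs)]
  }
  structure(list(group_id = group_id, length = L,
                 match_scores = scores, background = background,
                 gap_open = gap_open, gap_extend = gap_extend,
                 neff = neff, consensus = paste(consensus, collapse = ""),
                 calibration = NULL),
            class = "profile_model")
}

encode_aln_row <- function(r) {
  ch <- strsplit(r, "", fixed = TRUE)[[1L]]
  out <- match(ch, AA_X)
  out[ch == "-"] <- 0L
  if (anyNA(out)) stop("alignment row contains invalid characters", call. = FALSE)
  out
}

#' @export
print.profile_model <- function(x, ...) {
  cat(sprintf("profile_model%s: %d match columns, neff %.2f, %s\n",
              if (is.null(x$group_id)) "" else paste0(" ", x$group_id),
              x$length, x$neff,
              if (is.null(x$calibration)) "uncalibrated"
              else sprintf("Gumbel(mu=%.2f, lambda=%.3f), D=%d",
                           x$calibration$mu, x$calibration$lambda,
                           x$calibration$db_size)))
  invisible(x)
}

EULER_GAMMA <- 0.57721566490153286

#' Calibrate a profile's E-value null model
#'
#' Draws `n_decoys` sequences (with replacement) from `decoy_pool`,
#' shuffles the residues of each, scores them against the profile, and
#' fits a Gumbel by the method of moments: `lambda = pi / (sd * sqrt(6))`
#' and `mu = mean - gamma / lambda`. E-values are then
#' `E(s) = D * (1 - exp(-exp(-lambda (s - mu))))` with `D = db_size`.
#'
#' @param profile a [build_profile] result.
#' @param decoy_pool named character vector of sequences to shuffle.
#' @param n_decoys number of decoys (>= 50).
#' @param db_size effective database size D (defaults to the pool size).
#' @param seed optional seed; if NULL the current RNG state is used.
#' @return the profile with its `calibration` field filled.
#' @export
calibrate_profile <- function(profile, decoy_pool, n_decoys = 200L,
                              db_size = length(decoy_pool), seed = NULL) {
  stopifnot(inherits(profile, "profile_model"))
  if (length(decoy_pool) == 0L) stop("empty decoy pool", call. = FALSE)
  if (n_decoys < 50L) stop("n_decoys must be at least 50", call. = FALSE)
  run <- function() {
    picks <- sample.int(length(decoy_pool), n_decoys, replace = TRUE)
    decoys <- lapply(picks, function(k) {
      codes <- encode_seq(decoy_pool[[k]])
      codes[sample.int(length(codes))]
    })
    .sw_profile_scores(profile$match_scores, decoys,
                       profile$gap_open, profile$gap_extend)
  }
  scores <- if (is.null(seed)) run() else with_rng(seed, run())
  s <- stats::sd(scores)
  if (!is.finite(s) || s <= 0) {
    stop("decoy scores have zero variance; cannot calibrate", call. = FALSE)
  }
  lambda <- pi / (s * sqrt(6))
  mu <- mean(scores) - EULER_GAMMA / lambda
  profile$calibration <- list(mu = mu, lambda = lambda,
                              db_size = as.integer(db_size),
                              n_decoys = as.integer(n_decoys))
  profile
}

#' E-value of a raw profile score
#' @param profile calibrated profile.
#' @param score raw score(s), bits.
#' @return E-value(s) in `[0, D]`.
#' @export
profile_evalue <- function(profile, score) {
  cal <- profile$calibration
  if (is.null(cal)) stop("profile is not calibrated", call. = FALSE)
  x <- exp(-cal$lambda * (score - cal$mu))
  cal$db_size * (-expm1(-x))
}

#' Score one sequence against a calibrated profile
#'
#' Local (Smith-Waterman-style) alignment of the sequence against the
#' profile's match columns, affine gaps, deterministic traceback.
#'
#' @param profile calibrated [profile_model].
#' @param seq residue string.
#' @param ref protein token of the sequence.
#' @return one-row data.frame: protein, group_id, raw_score, evalue,
#'   seq_coverage, profile_coverage.
#' @export
score_sequence <- function(profile, seq, ref = names(seq) %||% NA_character_) {
  if (is.null(profile$calibration)) stop("profile is not calibrated", call. = FALSE)
  codes <- encode_seq(seq[[1L]])
  hit <- .sw_profile(profile$match_scores, codes,
                     profile$gap_open, profile$gap_extend)
  if (hit$score <= 0) {
    seq_cov <- 0; prof_cov <- 0
  } else {
    seq_cov <- (hit$seq_end - hit$seq_start + 1) / length(codes)
    prof_cov <- (hit$prof_end - hit$prof_start + 1) / profile$length
  }
  data.frame(protein = ref %||% NA_character_,
             group_id = profile$group_id %||% NA_character_,
             raw_score = hit$score,
             evalue = profile_evalue(profile, hit$score),
             seq_coverage = seq_cov,
             profile_coverage = prof_cov,
             stringsAsFactors = FALSE)
}
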