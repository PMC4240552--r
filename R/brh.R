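# Modified best-reciprocal-hit input method: cross-species hits are
# filtered by the score ratio against both self-scores and by alignment
# length relative to the shorter sequence; mutual best hits are ortholog
# pairs, grouped as fully connected cliques (at most one protein per
# species per group).

#' Best-reciprocal-hit ortholog pairs
#'
#' A hit (q,s) passes the filters iff `raw_score/self_score(q)` and
#' `raw_score/self_score(s)` are both >= `min_score_ratio` and the
#' alignment length is >= `min_len_ratio * min(len(q), len(s))`. For
#' each protein and foreign species the best passing hit is kept
#' (highest raw score, ties to the lexicographically smaller subject);
#' (q,s) is a pair iff each is the other's best hit. The two thresholds
#' have no published reference values; the defaults of 0.5 are this
#' package's own choice.
#'
#' @param table a [similarity_table].
#' @param seq_lengths named integer vector of sequence lengths.
#' @param min_score_ratio,min_len_ratio thresholds in [0,1].
#' @return character vector of canonical pair keys (class `pair_set`).
#' @export
brh_pairs <- function(table, seq_lengths, min_score_ratio = 0.5,
                      min_len_ratio = 0.5) {
  stopifnot(inherits(table, "similarity_table"),
            min_score_ratio >= 0, min_score_ratio <= 1,
            min_len_ratio >= 0, min_len_ratio <= 1)
  h <- table$hits
  h <- h[h$query != h$subject, , drop = FALSE]
  h <- h[ref_species(h$query) != ref_species(h$subject), , drop = FALSE]
  if (nrow(h) == 0L) return(structure(character(0), class = "pair_set"))
  involved <- unique(c(h$query, h$subject))
  no_self <- setdiff(involved, names(table$self_scores))
  if (length(no_self)) {
    stop("missing self-score(s): ", paste(utils::head(no_self, 3L), collapse = ", "),
         call. = FALSE)
  }
  no_len <- setdiff(involved, names(seq_lengths))
  if (length(no_len)) {
    stop("missing sequence length(s): ", paste(utils::head(no_len, 3L), collapse = ", "),
         call. = FALSE)
  }
  rq <- h$raw_score / table$self_scores[h$query]
  rs <- h$raw_score / table$self_scores[h$subject]
  lmin <- pmin(seq_lengths[h$query], seq_lengths[h$subject])
  h <- h[rq >= min_score_ratio & rs >= min_score_ratio &
           h$alignment_length >= min_len_ratio * lmin, , drop = FALSE]
  if (nrow(h) == 0L) return(structure(character(0), class = "pair_set"))
  # best passing hit per (query, foreign species)
  key <- paste(h$query, ref_species(h$subject))
  h <- h[order(key, -h$raw_score, h$subject, method = "radix"), , drop = FALSE]
  best <- h[!duplicated(paste(h$query, ref_species(h$subject))), , drop = FALSE]
  fwd <- stats::setNames(best$subject, paste(best$query, ref_species(best$subject)))
  pairs <- character(0)
  for (k in seq_len(nrow(best))) {
    q <- best$query[k]; s <- best$subject[k]
    back <- fwd[paste(s, ref_species(q))]
    if (!is.na(back) && back == q) {
      key2 <- paste(ref_sort(c(q, s)), collapse = " ")
      pairs <- c(pairs, key2)
    }
  }
  structure(sort(unique(pairs)), class = "pair_set")
}

#' Fully connected ortholog groups from BRH pairs
#'
#' Enumerates the maximal cliques of the pair graph (Bron-Kerbosch via
#' igraph); since each protein has at most one partner per foreign
#' species, every clique has at most one protein per species. Each
#' protein is assigned to the largest maximal clique containing it (ties
#' to the lexicographically smallest member set); cliques reduced below
#' size 2 by those assignments are dropped, so the output is a partition.
#'
#' @param pairs a `pair_set` of cross-species pairs.
#' @param method_name name for the resulting [group_set].
#' @return a [group_set].
#' @export
clique_groups <- function(pairs, method_name = "BRH") {
  pairs <- unclass(pairs)
  if (length(pairs) == 0L) return(group_set(method_name, list()))
  ends <- do.call(rbind, strsplit(pairs, " ", fixed = TRUE))
  if (any(ref_species(ends[, 1L]) == ref_species(ends[, 2L]))) {
    stop("same-species pair(s) in input", call. = FALSE)
  }
  g <- igraph::graph_from_edgelist(ends, directed = FALSE)
  cls <- igraph::max_cliques(g, min = 2L)
  cls <- lapply(cls, function(cl) ref_sort(igraph::V(g)$name[cl]))
  cls <- cls[order_groups(cls)]  # descending size, then lexicographic members
  # the canonical order already ranks ties by smallest first member; for
  # full member-set lexicographic comparison among equal-size cliques,
  # refine by the whole joined key
  sizes <- lengths(cls)
  keys <- vapply(cls, paste, "", collapse = " ")
  cls <- cls[order(-sizes, keys, method = "radix")]
  groups <- list()
  taken <- character(0)
  for (cl in cls) {
    # each protein is assigned to its first clique in this order; a
    # clique reduced below size 2 is dropped and its members with it
    mem <- setdiff(cl, taken)
    taken <- c(taken, mem)
    if (length(mem) >= 2L) groups[[length(groups) + 1L]] <- mem
  }
  group_set(method_name, groups)
}
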