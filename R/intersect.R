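# Seed groups: common refinement of the partitions of a subset of
# methods, restricted to the currently unassigned pool, with a minimum
# cell size and deterministic conflict resolution across method subsets.

#' Common-refinement cells of a method subset
#'
#' Two proteins fall in the same cell iff they are in the same group in
#' every method of `subset`. A protein absent from any of those methods'
#' universes (no prediction) belongs to no cell. Cells of size 1 are
#' discarded. Cells are returned in canonical order (descending size,
#' then lexicographically smallest member).
#'
#' @param groupsets list of [group_set].
#' @param subset character vector of method names.
#' @param pool character vector of tokens to restrict to.
#' @return list of `list(members, subset)`.
#' @export
comembership_cells <- function(groupsets, subset, pool) {
  names(groupsets) <- vapply(groupsets, `[[`, "", "method_name")
  unknown <- setdiff(subset, names(groupsets))
  if (length(unknown)) stop("unknown method(s): ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  present <- pool
  keys <- NULL
  for (m in subset) {
    idx <- membership_index(groupsets[[m]])
    present <- present[present %in% names(idx)]
  }
  if (length(present) == 0L) return(list())
  keymat <- vapply(subset, function(m) {
    membership_index(groupsets[[m]])[present]
  }, integer(length(present)))
  if (length(present) == 1L) keymat <- matrix(keymat, nrow = 1L)
  key <- apply(keymat, 1L, paste, collapse = ".")
  cells <- split(present, key)
  cells <- cells[lengths(cells) >= 2L]
  cells <- lapply(cells, ref_sort)
  cells <- unname(cells[order_groups(cells)])
  lapply(cells, function(cl) list(members = cl, subset = sort(subset)))
}

#' Seed groups at one intersection level
#'
#' Evaluates [comembership_cells] for every size-`level` subset of the
#' methods. Cells of size >= `min_size` are candidate seeds; identical
#' cells arising from different subsets are kept once (all contributing
#' subsets recorded). A protein claimed by candidate cells of different
#' subsets stays in the largest cell; a genuine size tie is broken
#' uniformly at random (the caller owns the RNG state). After a removal
#' the losing cell is re-checked against `min_size`. With `level == 2`,
#' cells of size 2..`min_size - 1` (including demoted candidates) are
#' returned as `rejected` for the final leftover step.
#'
#' @param groupsets list of [group_set].
#' @param level integer number of methods to intersect (2..N).
#' @param pool tokens to restrict to.
#' @param min_size minimum seed size.
#' @return list with `seeds` (list of `list(members, level, method_subset,
#'   all_subsets)`), `rejected` (as in [comembership_cells]) and
#'   `tie_log` (data.frame of random tie-breaks).
#' @export
intersect_level <- function(groupsets, level, pool, min_size = 4L) {
  n <- length(groupsets)
  if (level < 2L || level > n) {
    stop(sprintf("level must be between 2 and the number of methods (%d)", n),
         call. = FALSE)
  }
  methods <- vapply(groupsets, `[[`, "", "method_name")
  subsets <- utils::combn(sort(methods), level, simplify = FALSE)
  cand <- list(); small <- list()
  for (ss in subsets) {
    for (cl in comembership_cells(groupsets, ss, pool)) {
      if (length(cl$members) >= min_size) cand[[length(cand) + 1L]] <- cl
      else small[[length(small) + 1L]] <- cl
    }
  }
  # deduplicate identical member sets from different subsets
  if (length(cand)) {
    key <- vapply(cand, function(cl) paste(cl$members, collapse = " "), "")
    first <- !duplicated(key)
    merged <- lapply(which(first), function(k) {
      same <- which(key == key[k])
      list(members = cand[[k]]$members,
           subset = cand[[k]]$subset,
           all_subsets = lapply(cand[same], `[[`, "subset"))
    })
    cand <- merged
  }
  tie_log <- data.frame(protein = character(0), chosen = character(0),
                        stringsAsFactors = FALSE)
  repeat {
    if (length(cand) <= 1L) break
    cand <- cand[order_groups(lapply(cand, `[[`, "members"))]
    sizes <- vapply(cand, function(cl) length(cl$members), 0L)
    holders <- tabulate_holders(cand)
    conflicted <- names(holders)[lengths(holders) > 1L]
    if (length(conflicted) == 0L) break
    p <- ref_sort(conflicted)[1L]
    h <- holders[[p]]
    top <- h[sizes[h] == max(sizes[h])]
    keep <- if (length(top) == 1L) top else top[sample.int(length(top), 1L)]
    if (length(top) > 1L) {
      tie_log <- rbind(tie_log, data.frame(
        protein = p,
        chosen = paste(cand[[keep]]$members[1:2], collapse = " "),
        stringsAsFactors = FALSE))
    }
    drop_idx <- integer(0)
    for (k in setdiff(h, keep)) {
      cand[[k]]$members <- setdiff(cand[[k]]$members, p)
      if (length(cand[[k]]$members) < min_size) {
        if (length(cand[[k]]$members) >= 2L) {
          small[[length(small) + 1L]] <- list(members = cand[[k]]$members,
                                              subset = cand[[k]]$subset)
        }
        drop_idx <- c(drop_idx, k)
      }
    }
    if (length(drop_idx)) cand <- cand[-drop_idx]
  }
  cand <- cand[order_groups(lapply(cand, `[[`, "members"))]
  seeds <- lapply(cand, function(cl) {
    list(members = cl$members, level = level,
         method_subset = cl$subset,
         all_subsets = cl$all_subsets %||% list(cl$subset))
  })
  rejected <- list()
  if (level == 2L && length(small)) {
    key <- vapply(small, function(cl) paste(cl$members, collapse = " "), "")
    small <- small[!duplicated(key)]
    small <- small[order_groups(lapply(small, `[[`, "members"))]
    rejected <- small
  }
  list(seeds = seeds, rejected = rejected, tie_log = tie_log)
}

# protein -> integer indices of candidate cells containing it
tabulate_holders <- function(cand) {
  idx <- rep.int(seq_along(cand), vapply(cand, function(cl) length(cl$members), 0L))
  members <- unlist(lapply(cand, `[[`, "members"), use.names = FALSE)
  split(idx, members)
}
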