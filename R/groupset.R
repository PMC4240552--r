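# One method's prediction: a partition of its universe into disjoint
# ortholog groups of size >= 2. Groups are stored as character vectors of
# `species|protein` tokens, in canonical order (descending size, then
# lexicographically smallest member).

#' Construct a group set (one method's ortholog groups)
#'
#' @param method_name single string naming the method.
#' @param groups list of character vectors of `species|protein` tokens.
#' @param resolve_overlaps if TRUE, a protein occurring in several groups
#'   is kept only in the largest (ties broken by the earliest group in
#'   the input order) and a warning reports the count; if FALSE any
#'   overlap is an error. Singleton groups are always dropped.
#' @return object of class `group_set` with elements `method_name`,
#'   `groups` and `universe`.
#' @export
group_set <- function(method_name, groups, resolve_overlaps = FALSE) {
  stopifnot(is.character(method_name), length(method_name) == 1L, nzchar(method_name))
  groups <- lapply(groups, function(g) unique(as.character(g)))
  all_refs <- as.character(unlist(groups, use.names = FALSE) %||% character(0))
  if (length(all_refs)) split_refs(all_refs)  # validates token shape
  dup <- unique(all_refs[duplicated(all_refs)])
  n_moved <- 0L
  if (length(dup)) {
    if (!resolve_overlaps) {
      stop(sprintf("method '%s': protein(s) in more than one group: %s",
                   method_name, paste(utils::head(dup, 3L), collapse = ", ")),
           call. = FALSE)
    }
    sizes <- lengths(groups)
    for (p in dup) {
      holders <- which(vapply(groups, function(g) p %in% g, NA))
      keep <- holders[which.max(sizes[holders])]  # first largest = earliest line
      for (h in setdiff(holders, keep)) {
        groups[[h]] <- setdiff(groups[[h]], p)
        n_moved <- n_moved + 1L
      }
      sizes <- lengths(groups)
    }
    warning(sprintf("method '%s': resolved %d overlapping membership(s); kept largest group",
                    method_name, n_moved), call. = FALSE)
  }
  n_singletons <- sum(lengths(groups) <= 1L)
  groups <- groups[lengths(groups) >= 2L]
  groups <- lapply(groups, ref_sort)
  groups <- groups[order_groups(groups)]
  structure(list(method_name = method_name,
                 groups = groups,
                 universe = ref_sort(unique(unlist(groups, use.names = FALSE)))),
            n_singletons_dropped = n_singletons,
            n_overlaps_resolved = n_moved,
            class = "group_set")
}

#' @export
print.group_set <- function(x, ...) {
  cat(sprintf("group_set '%s': %d groups, %d proteins, %d species\n",
              x$method_name, length(x$groups), length(x$universe),
              length(unique(ref_species(x$universe)))))
  invisible(x)
}

# group id of each protein (named integer), NA-free by construction
membership_index <- function(gs) {
  idx <- rep.int(seq_along(gs$groups), lengths(gs$groups))
  stats::setNames(idx, unlist(gs$groups, use.names = FALSE))
}

#' Coerce a meta result or group set to a plain group set
#'
#' @param x a `group_set` or `meta_result`.
#' @param method_name name of the resulting group set.
#' @return a `group_set`.
#' @export
as_group_set <- function(x, method_name = NULL) {
  if (inherits(x, "group_set")) {
    if (!is.null(method_name)) x$method_name <- method_name
    return(x)
  }
  if (inherits(x, "meta_result")) {
    return(group_set(method_name %||% "meta",
                     lapply(x$final_groups, `[[`, "members")))
  }
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to group_set", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
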