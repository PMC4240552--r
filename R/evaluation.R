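# Evaluation suite: pairwise Jaccard of co-grouped protein pairs,
# fusion/fission accounting against curated reference groups, and
# information-content (relevance) similarity of GO/EC annotations within
# predicted groups, plus the parameter-impact sweep.

#' Co-grouped protein pairs of a clustering
#'
#' @param x a [group_set] or [meta_result].
#' @return character vector of canonical `tokenA tokenB` pair keys
#'   (class `pair_set`); a group of size k yields k(k-1)/2 pairs.
#' @export
ortholog_pairs <- function(x) {
  gs <- as_group_set(x)
  out <- unlist(lapply(gs$groups, function(g) {
    g <- ref_sort(g)
    if (length(g) < 2L) return(character(0))
    cmb <- utils::combn(g, 2L)
    paste(cmb[1L, ], cmb[2L, ])
  }), use.names = FALSE)
  structure(sort(unique(out)), class = "pair_set")
}

#' Jaccard coefficient of two pair sets
#'
#' Shared co-grouped pairs divided by the union of co-grouped pairs,
#' in [0,1]; two empty pair sets give 1 by convention.
#'
#' @param a,b `pair_set` objects (or plain pair-key vectors).
#' @return numeric scalar.
#' @export
jaccard_index <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  if (length(a) == 0L && length(b) == 0L) return(1.0)
  length(intersect(a, b)) / length(union(a, b))
}

#' Number of identical groups between two clusterings
#'
#' @param a,b [group_set] (or coercible) objects.
#' @return integer count of groups of `a` whose member set equals a
#'   group of `b`.
#' @export
count_identical_groups <- function(a, b) {
  ka <- vapply(as_group_set(a)$groups, function(g) paste(ref_sort(g), collapse = " "), "")
  kb <- vapply(as_group_set(b)$groups, function(g) paste(ref_sort(g), collapse = " "), "")
  sum(ka %in% kb)
}

#' Fusion/fission accounting against reference groups
#'
#' Predicted groups are first restricted to the benchmark universe. For
#' each reference group R, the predicted groups overlapping R are
#' collected: a split over n groups counts n - 1 fissions; the
#' best-matching group (largest overlap, ties to the larger group then
#' lexicographic) causes a fusion when it contains more than 3 proteins
#' outside R. A reference group is accurately predicted when it has no
#' fission, no fusion, and at least one overlapping predicted group.
#'
#' @param predicted a [group_set] or [meta_result].
#' @param refs a [reference_groups] object.
#' @return object of class `refog_report`: `per_refog` data.frame and
#'   `aggregates` list (percentages over all reference groups).
#' @export
fusion_fission <- function(predicted, refs) {
  stopifnot(inherits(refs, "reference_groups"))
  if (length(refs$refogs) == 0L) stop("empty reference groups", call. = FALSE)
  gs <- as_group_set(predicted)
  restricted <- lapply(gs$groups, function(g) intersect(g, refs$universe))
  restricted <- restricted[lengths(restricted) >= 1L]
  per <- data.frame(refog_id = names(refs$refogs),
                    fissions = 0L, fusion = FALSE, covered = FALSE,
                    accurate = FALSE, stringsAsFactors = FALSE)
  for (k in seq_along(refs$refogs)) {
    R <- refs$refogs[[k]]
    ov <- vapply(restricted, function(g) length(intersect(g, R)), 0L)
    holders <- which(ov > 0L)
    per$covered[k] <- length(holders) > 0L
    per$fissions[k] <- max(length(holders) - 1L, 0L)
    if (length(holders)) {
      sizes <- lengths(restricted[holders])
      first <- vapply(restricted[holders], function(g) ref_sort(g)[1L], "")
      sp <- split_refs(first)
      best <- holders[order(-ov[holders], -sizes, sp$species, sp$protein,
                            method = "radix")][1L]
      foreign <- length(setdiff(restricted[[best]], R))
      per$fusion[k] <- foreign > 3L
    }
  }
  per$accurate <- per$fissions == 0L & !per$fusion & per$covered
  n <- nrow(per)
  agg <- list(pct_accurate = 100 * mean(per$accurate),
              total_fusions = sum(per$fusion),
              total_fissions = sum(per$fissions),
              pct_fusion_affected = 100 * mean(per$fusion),
              pct_fission_affected = 100 * mean(per$fissions > 0L),
              pct_both = 100 * mean(per$fusion & per$fissions > 0L),
              pct_affected = 100 * mean(per$fusion | per$fissions > 0L))
  structure(list(per_refog = per, aggregates = agg), class = "refog_report")
}

#' @export
print.refog_report <- function(x, ...) {
  a <- x$aggregates
  cat(sprintf("refog_report over %d reference groups\n", nrow(x$per_refog)))
  cat(sprintf("  accurate: %.1f%%  fusions: %d (%.1f%%)  fissions: %d (%.1f%%)  both: %.1f%%\n",
              a$pct_accurate, a$total_fusions, a$pct_fusion_affected,
              a$total_fissions, a$pct_fission_affected, a$pct_both))
  invisible(x)
}

# Information content ---------------------------------------------------

# exclusive ancestor sets for every term of a parent-list DAG
dag_ancestors <- function(dag) {
  anc <- stats::setNames(vector("list", length(dag)), names(dag))
  done <- stats::setNames(logical(length(dag)), names(dag))
  get <- function(t) {
    if (done[[t]]) return(anc[[t]])
    parents <- dag[[t]]
    res <- character(0)
    for (p in parents) res <- c(res, p, get(p))
    res <- sort(unique(res))
    anc[[t]] <<- res; done[[t]] <<- TRUE
    res
  }
  for (t in names(dag)) get(t)
  anc
}

#' Information-content table for one annotation namespace
#'
#' `p(term)` is the fraction of the namespace's annotations falling on
#' the term or any descendant; `ic = -ln p`. Terms with zero annotation
#' count are excluded; the root has p = 1 and ic = 0.
#'
#' @param store an annotation store from [read_annotation_store].
#' @param namespace a GO namespace present in the store, or `"EC"`.
#' @return object of class `ic_table`: `p`, `ic` (named vectors),
#'   `ancestors` (named list, exclusive), `n_annotations`.
#' @export
ic_table <- function(store, namespace) {
  if (identical(namespace, "EC")) {
    ann <- store$ec_annotations
    if (nrow(ann) == 0L) stop("no EC annotations in store", call. = FALSE)
    terms <- vapply(ann$ec, ec_node, "")
    dag <- ec_dag(unique(terms))
  } else {
    ann <- store$go_annotations
    ns_of <- store$go_namespace
    keep <- ns_of[ann$term] == namespace
    ann <- ann[!is.na(keep) & keep, , drop = FALSE]
    if (nrow(ann) == 0L) stop("no annotations in namespace ", namespace, call. = FALSE)
    terms <- ann$term
    dag <- store$go_dag[names(store$go_dag) %in% names(ns_of)[ns_of == namespace]]
    # keep parents within the namespace closure
    dag <- lapply(dag, function(p) p[p %in% names(dag) | !(p %in% names(store$go_dag))])
  }
  anc <- dag_ancestors(dag)
  counts <- stats::setNames(numeric(length(dag)), names(dag))
  for (t in terms) {
    counts[t] <- counts[t] + 1
    for (a in anc[[t]]) counts[a] <- counts[a] + 1
  }
  total <- length(terms)
  p <- counts[counts > 0] / total
  structure(list(p = p, ic = -log(p), ancestors = anc,
                 n_annotations = total, namespace = namespace),
            class = "ic_table")
}

# EC helpers: prefix tree rooted at a virtual root
EC_ROOT <- "EC"

ec_node <- function(ec) {
  parts <- strsplit(ec, ".", fixed = TRUE)[[1L]]
  parts <- parts[parts != "-"]
  if (length(parts) == 0L) return(EC_ROOT)
  paste(parts, collapse = ".")
}

ec_dag <- function(nodes) {
  all_nodes <- EC_ROOT
  for (nd in nodes) {
    parts <- strsplit(nd, ".", fixed = TRUE)[[1L]]
    for (k in seq_along(parts)) {
      all_nodes <- c(all_nodes, paste(parts[1:k], collapse = "."))
    }
  }
  all_nodes <- unique(all_nodes)
  dag <- stats::setNames(vector("list", length(all_nodes)), all_nodes)
  for (nd in all_nodes) {
    if (nd == EC_ROOT) { dag[[nd]] <- character(0); next }
    parts <- strsplit(nd, ".", fixed = TRUE)[[1L]]
    dag[[nd]] <- if (length(parts) == 1L) EC_ROOT
                 else paste(parts[-length(parts)], collapse = ".")
  }
  dag
}

#' Relevance similarity of two annotation terms
#'
#' Over the common ancestors a of the two terms (each term counting as
#' its own ancestor), the maximum of
#' `(2 ic(a) / (ic(c1) + ic(c2))) * (1 - p(a))`. Zero when the only
#' common ancestor is the root or both terms are roots.
#'
#' @param c1,c2 term ids present in `tab`.
#' @param tab an [ic_table].
#' @return numeric in [0,1].
#' @export
sim_rel <- function(c1, c2, tab) {
  if (!(c1 %in% names(tab$p)) || !(c2 %in% names(tab$p))) {
    stop("term(s) absent from the information-content table", call. = FALSE)
  }
  denom <- tab$ic[[c1]] + tab$ic[[c2]]
  if (denom <= 0) return(0)
  common <- intersect(c(c1, tab$ancestors[[c1]]), c(c2, tab$ancestors[[c2]]))
  common <- common[common %in% names(tab$p)]
  if (length(common) == 0L) return(0)
  max((2 * tab$ic[common] / denom) * (1 - tab$p[common]))
}

# best-match average of the pairwise sim_rel matrix of two term sets
bma_similarity <- function(terms1, terms2, tab) {
  m <- matrix(0, length(terms1), length(terms2))
  for (i in seq_along(terms1)) {
    for (j in seq_along(terms2)) m[i, j] <- sim_rel(terms1[i], terms2[j], tab)
  }
  (mean(apply(m, 1L, max)) + mean(apply(m, 2L, max))) / 2
}

#' Precompute the similarity context for a store
#'
#' @param store annotation store.
#' @param mode `"GO"` or `"EC"`.
#' @return list of per-namespace ic tables plus per-protein term sets.
#' @export
similarity_context <- function(store, mode = c("GO", "EC")) {
  mode <- match.arg(mode)
  if (mode == "EC") {
    if (nrow(store$ec_annotations) == 0L) {
      return(structure(list(mode = "EC", tabs = list(), terms = list()),
                       class = "similarity_context"))
    }
    tab <- ic_table(store, "EC")
    nodes <- vapply(store$ec_annotations$ec, ec_node, "")
    terms <- lapply(split(nodes, store$ec_annotations$protein), unique)
    return(structure(list(mode = "EC", tabs = list(EC = tab), terms = list(EC = terms)),
                     class = "similarity_context"))
  }
  ann <- store$go_annotations
  if (nrow(ann) == 0L) {
    return(structure(list(mode = "GO", tabs = list(), terms = list()),
                     class = "similarity_context"))
  }
  ns_of <- store$go_namespace[ann$term]
  tabs <- list(); terms <- list()
  for (ns in sort(unique(ns_of))) {
    sel <- ann[!is.na(ns_of) & ns_of == ns, , drop = FALSE]
    tabs[[ns]] <- ic_table(store, ns)
    terms[[ns]] <- lapply(split(sel$term, sel$protein), unique)
  }
  structure(list(mode = mode, tabs = tabs, terms = terms),
            class = "similarity_context")
}

#' Functional similarity of a protein pair
#'
#' Skipped (NA) when either protein lacks annotation in scope. For GO,
#' the best-match average similarity is computed per namespace annotated
#' on both proteins and averaged over those namespaces; for EC, the
#' best-match average on the EC prefix tree.
#'
#' @param p1,p2 protein tokens.
#' @param store annotation store (ignored if `ctx` given).
#' @param mode `"GO"` or `"EC"`.
#' @param ctx optional precomputed [similarity_context].
#' @return numeric in [0,1], or NA when the pair is skipped.
#' @export
pair_functional_similarity <- function(p1, p2, store = NULL, mode = c("GO", "EC"),
                                       ctx = NULL) {
  mode <- match.arg(mode)
  if (is.null(ctx)) ctx <- similarity_context(store, mode)
  scores <- numeric(0)
  for (ns in names(ctx$tabs)) {
    t1 <- ctx$terms[[ns]][[p1]]; t2 <- ctx$terms[[ns]][[p2]]
    if (is.null(t1) || is.null(t2)) next
    scores <- c(scores, bma_similarity(t1, t2, ctx$tabs[[ns]]))
  }
  if (length(scores) == 0L) return(NA_real_)
  mean(scores)
}

#' Annotation-conservation benchmark of a clustering
#'
#' Enumerates co-grouped pairs, scores those with annotations on both
#' sides, and returns the two axes of the conservation test: the number
#' of annotated pairs and the mean (and sd) of their similarities.
#'
#' @param clustering [group_set] or [meta_result].
#' @param store annotation store.
#' @param mode `"GO"` or `"EC"`.
#' @return list(n_annotated_pairs, mean_similarity, sd_similarity).
#' @export
function_benchmark <- function(clustering, store, mode = c("GO", "EC")) {
  mode <- match.arg(mode)
  ctx <- similarity_context(store, mode)
  pairs <- unclass(ortholog_pairs(clustering))
  scores <- numeric(0)
  if (length(ctx$tabs)) {
    annotated <- unique(unlist(lapply(ctx$terms, names), use.names = FALSE))
    for (pk in pairs) {
      pp <- strsplit(pk, " ", fixed = TRUE)[[1L]]
      if (!(pp[1L] %in% annotated) || !(pp[2L] %in% annotated)) next
      s <- pair_functional_similarity(pp[1L], pp[2L], mode = mode, ctx = ctx)
      if (!is.na(s)) scores <- c(scores, s)
    }
  }
  list(n_annotated_pairs = length(scores),
       mean_similarity = if (length(scores)) mean(scores) else NA_real_,
       sd_similarity = if (length(scores) > 1L) stats::sd(scores) else NA_real_)
}

#' Parameter-impact sweep
#'
#' Runs the consensus over the cartesian grid of thresholds (same seed
#' for every point) and tabulates the reference-group aggregates.
#'
#' @param groupsets list of [group_set].
#' @param proteome named sequence vector (or NULL).
#' @param refs [reference_groups].
#' @param grid list with numeric vectors `evalue`, `coverage`, `min_size`.
#' @param seed RNG seed shared by all grid points.
#' @return data.frame, one row per parameter combination.
#' @export
parameter_sweep <- function(groupsets, proteome, refs, grid, seed = 1L) {
  stopifnot(all(c("evalue", "coverage", "min_size") %in% names(grid)),
            all(lengths(grid[c("evalue", "coverage", "min_size")]) >= 1L))
  pts <- expand.grid(evalue = grid$evalue, coverage = grid$coverage,
                     min_size = grid$min_size, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(pts)), function(k) {
    params <- meta_params(evalue_threshold = pts$evalue[k],
                          min_coverage = pts$coverage[k],
                          min_size = pts$min_size[k],
                          rng_seed = seed)
    res <- tryCatch(run_meta(groupsets, proteome, params),
                    error = function(e) {
                      stop(sprintf("grid point (%g, %g, %d): %s",
                                   pts$evalue[k], pts$coverage[k],
                                   pts$min_size[k], conditionMessage(e)),
                           call. = FALSE)
                    })
    rep <- fusion_fission(res, refs)
    cbind(pts[k, , drop = FALSE], as.data.frame(rep$aggregates))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
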