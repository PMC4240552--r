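# Independent brute-force oracles and random-instance generators.
# These deliberately re-derive every quantity by the most literal route
# (double loops, exhaustive enumeration, plain DP) so they share no code
# with the package internals they check.

# --- alignment oracles -------------------------------------------------

# Gotoh affine-gap global alignment, score only
oracle_nw_score <- function(s1, s2, sub, go, ge) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b); NEG <- -1e30
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -go - ge * (i - 2)
  for (j in 2:(m + 1)) Y[1, j] <- -go - ge * (j - 2)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- sub[a[i - 1], b[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - go, X[i - 1, j] - ge)
    Y[i, j] <- max(M[i, j - 1] - go, Y[i, j - 1] - ge)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# local alignment of a residue string against a profile score table,
# affine gaps, score only (0-floored)
oracle_sw_profile_score <- function(scores, seq, go, ge) {
  b <- strsplit(seq, "")[[1]]
  L <- nrow(scores); m <- length(b); NEG <- -1e30
  M <- matrix(0, L + 1, m + 1); X <- matrix(NEG, L + 1, m + 1); Y <- X
  best <- 0
  for (i in 2:(L + 1)) for (j in 2:(m + 1)) {
    s <- scores[i - 1, b[j - 1]]
    M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s)
    X[i, j] <- max(M[i - 1, j] - go, X[i - 1, j] - ge)
    Y[i, j] <- max(M[i, j - 1] - go, Y[i, j - 1] - ge)
    best <- max(best, M[i, j])
  }
  best
}

# --- clustering oracles ------------------------------------------------

# all unordered co-grouped pairs by double loop
oracle_pairs <- function(groups) {
  out <- character(0)
  for (g in groups) {
    g <- sort(g)
    if (length(g) < 2) next
    for (i in seq_len(length(g) - 1)) for (j in (i + 1):length(g)) {
      out <- c(out, paste(g[i], g[j]))
    }
  }
  sort(unique(out))
}

# cells of "co-grouped in every method of subset": O(n^2) pairwise
# relation, then connected components by breadth-first search. The
# relation is an equivalence, so components are exactly the cells.
oracle_cells <- function(groupsets, subset, pool, min_cell = 2L) {
  names(groupsets) <- sapply(groupsets, `[[`, "method_name")
  in_all <- Filter(function(p) {
    all(sapply(subset, function(m) p %in% groupsets[[m]]$universe))
  }, pool)
  n <- length(in_all)
  if (n == 0) return(list())
  # literal per-method group lookup by scanning the group lists
  idx <- lapply(subset, function(m) {
    gs <- groupsets[[m]]$groups
    sapply(in_all, function(p) which(sapply(gs, function(g) p %in% g)))
  })
  same <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    same[i, j] <- all(sapply(idx, function(v) v[i] == v[j]))
  }
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    frontier <- s; comp <- integer(0)
    while (length(frontier)) {
      v <- frontier[1]; frontier <- frontier[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      comp <- c(comp, v)
      frontier <- c(frontier, which(same[v, ] & !seen))
    }
    comps[[length(comps) + 1]] <- in_all[comp]
  }
  comps <- Filter(function(cl) length(cl) >= min_cell, comps)
  lapply(comps, function(cl) sort(unlist(cl), method = "radix"))
}

# random partition-style group set over n proteins and s species
random_group_set <- function(name, n = 30, s = 3, k = 5, keep = 0.9) {
  refs <- protein_ref(paste0("s", ((seq_len(n) - 1) %% s) + 1),
                      sprintf("p%02d", seq_len(n)))
  refs <- refs[runif(n) < keep]
  if (length(refs) < 4) refs <- protein_ref("s1", sprintf("p%02d", 1:4))
  lab <- sample(seq_len(k), length(refs), replace = TRUE)
  group_set(name, unname(split(refs, lab)))
}

# --- ontology oracles --------------------------------------------------

# random DAG: terms t1..tn, each non-root picks 1-2 parents among
# earlier terms; returns the parent-list representation
random_dag <- function(n_terms = 15) {
  terms <- sprintf("t%02d", seq_len(n_terms))
  dag <- setNames(vector("list", n_terms), terms)
  dag[[1]] <- character(0)
  for (k in 2:n_terms) {
    dag[[terms[k]]] <- sample(terms[seq_len(k - 1)], sample(1:min(2, k - 1), 1))
  }
  dag
}

# exhaustive ancestor closure (self included)
oracle_ancestors <- function(dag, t) {
  out <- t
  frontier <- t
  while (length(frontier)) {
    nxt <- unique(unlist(dag[frontier]))
    nxt <- setdiff(nxt, out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  sort(out)
}

oracle_sim_rel <- function(c1, c2, tab, dag) {
  common <- intersect(oracle_ancestors(dag, c1), oracle_ancestors(dag, c2))
  common <- common[common %in% names(tab$p)]
  denom <- tab$ic[[c1]] + tab$ic[[c2]]
  if (denom <= 0 || length(common) == 0) return(0)
  max(sapply(common, function(a) (2 * tab$ic[[a]] / denom) * (1 - tab$p[[a]])))
}

# --- clique oracle -----------------------------------------------------

# exhaustive maximal-clique enumeration over <= 15 vertices, then the
# assignment rule: every protein keeps its largest clique (ties by the
# lexicographically smallest member set); cliques left with < 2 members
# are dropped
oracle_clique_groups <- function(pair_keys) {
  if (length(pair_keys) == 0) return(list())
  ends <- do.call(rbind, strsplit(pair_keys, " "))
  verts <- sort(unique(c(ends)))
  stopifnot(length(verts) <= 15)
  adj <- matrix(FALSE, length(verts), length(verts),
                dimnames = list(verts, verts))
  for (r in seq_len(nrow(ends))) {
    adj[ends[r, 1], ends[r, 2]] <- TRUE
    adj[ends[r, 2], ends[r, 1]] <- TRUE
  }
  is_clique <- function(v) all(adj[v, v] | diag(length(v)) == 1)
  subsets <- unlist(lapply(2:length(verts), function(k) {
    combn(verts, k, simplify = FALSE)
  }), recursive = FALSE)
  cliques <- Filter(is_clique, subsets)
  maximal <- Filter(function(cl) {
    !any(sapply(setdiff(verts, cl), function(v) is_clique(c(cl, v))))
  }, cliques)
  key <- sapply(maximal, paste, collapse = " ")
  ord <- order(-lengths(maximal), key, method = "radix")
  maximal <- maximal[ord]
  taken <- character(0); groups <- list()
  for (cl in maximal) {
    mem <- setdiff(cl, taken)
    taken <- c(taken, mem)
    if (length(mem) >= 2) groups[[length(groups) + 1]] <- sort(mem, method = "radix")
  }
  groups
}

# canonical key for a list of member vectors (order-insensitive compare)
group_keys <- function(groups) {
  if (length(groups) == 0) return(character(0))
  sort(unname(sapply(groups, function(g) {
    paste(sort(g, method = "radix"), collapse = " ")
  })), method = "radix")
}
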