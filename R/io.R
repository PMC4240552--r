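# Readers and writers for the plain-text formats the tool touches:
# OrthoMCL-style groups files, FASTA proteomes, GAF 2.x annotations,
# edge-list ontology files, EC and reference-group TSVs, and the JSON
# provenance report. All writes are UTF-8 with LF endings.

#' Read ortholog group predictions
#'
#' Each file holds one method's groups, one group per line: an optional
#' `GROUPID:` prefix followed by whitespace-separated `species|protein`
#' tokens. Proteins occurring in several groups of one file are kept only
#' in the largest group (warning); singleton groups are dropped.
#'
#' @param paths character vector of file paths.
#' @param method_names optional method names; defaults to file base names
#'   without extension.
#' @return list of [group_set] objects in input order.
#' @export
read_group_sets <- function(paths, method_names = NULL) {
  if (is.null(method_names)) {
    method_names <- sub("\\.[^.]*$", "", basename(paths))
  }
  stopifnot(length(method_names) == length(paths))
  if (anyDuplicated(method_names)) {
    stop("duplicate method names: ",
         paste(unique(method_names[duplicated(method_names)]), collapse = ", "),
         call. = FALSE)
  }
  Map(read_group_file, paths, method_names, USE.NAMES = FALSE)
}

read_group_file <- function(path, method_name) {
  if (!file.exists(path)) stop("no such groups file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty groups file: ", path, call. = FALSE)
  groups <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    ln <- trimws(lines[[k]])
    ln <- sub("^[^[:space:]|]+:[[:space:]]*", "", ln)  # optional GROUPID: prefix
    toks <- strsplit(ln, "[[:space:]]+")[[1L]]
    bad <- !grepl("^[^|[:space:]]+\\|[^|[:space:]]+$", toks)
    if (any(bad)) {
      stop(sprintf("%s:%d: malformed token '%s' (expected species|protein)",
                   path, k, toks[bad][1L]), call. = FALSE)
    }
    groups[[k]] <- toks
  }
  group_set(method_name, groups, resolve_overlaps = TRUE)
}

#' Write a group set in the groups-file dialect
#'
#' Group ids are regenerated deterministically as `G1..Gk` in canonical
#' order (descending size, then lexicographically smallest member), so a
#' write/read round trip preserves co-membership exactly.
#'
#' @param gs a [group_set] (or [meta_result], coerced).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_group_set <- function(gs, path) {
  gs <- as_group_set(gs)
  lines <- vapply(seq_along(gs$groups), function(k) {
    paste0("G", k, ": ", paste(gs$groups[[k]], collapse = " "))
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a proteome from FASTA
#'
#' Header first tokens must parse as `species|protein`. Sequences are
#' uppercased; residues outside the 20 standard letters are an error by
#' default, or masked to `X`.
#'
#' @param path FASTA file.
#' @param nonstandard `"error"` or `"mask"`.
#' @return named character vector of residue strings; names are tokens.
#' @export
read_proteome_fasta <- function(path, nonstandard = c("error", "mask")) {
  nonstandard <- match.arg(nonstandard)
  aa <- Biostrings::readAAStringSet(path)
  nm <- vapply(strsplit(names(aa), "[[:space:]]+"), `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA header(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  split_refs(nm)
  seqs <- toupper(as.character(aa))
  if (any(!nzchar(seqs))) {
    stop("empty sequence(s): ", paste(nm[!nzchar(seqs)], collapse = ", "),
         call. = FALSE)
  }
  pat <- sprintf("[^%s]", paste(AA_X, collapse = ""))
  has_bad <- grepl(pat, seqs)
  if (any(has_bad)) {
    if (nonstandard == "error") {
      stop("non-standard residues in: ",
           paste(utils::head(nm[has_bad], 3L), collapse = ", "),
           " (use nonstandard = \"mask\")", call. = FALSE)
    }
    seqs[has_bad] <- gsub(pat, "X", seqs[has_bad])
  }
  stats::setNames(seqs, nm)
}

#' Write a proteome to FASTA
#' @param proteome named character vector of residue strings.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(proteome, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteome), path)
  invisible(path)
}

# Annotations -----------------------------------------------------------

EXPERIMENTAL_EVIDENCE <- c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP")

#' Read GO/EC annotations into an annotation store
#'
#' GO annotations come from a GAF 2.x file (protein token in column 2, GO
#' id in column 5, evidence code in column 7, aspect in column 9); only
#' rows with experimental evidence codes (EXP, IDA, IPI, IMP, IGI, IEP)
#' are kept. The ontology is an edge TSV (child, parent, namespace);
#' roots are terms that never appear as a child. EC annotations are a TSV
#' (protein token, EC string; `-` allowed as suffix wildcard).
#'
#' @param gaf_path,dag_path,ec_path file paths; `gaf_path`/`dag_path`
#'   must be given together; `ec_path` optional.
#' @return object of class `annotation_store` with `go_dag` (named list
#'   term -> character vector of parents), `go_namespace` (named vector),
#'   `go_annotations` (data.frame protein/term/evidence), and
#'   `ec_annotations` (data.frame protein/ec).
#' @export
read_annotation_store <- function(gaf_path = NULL, dag_path = NULL, ec_path = NULL) {
  go_dag <- list(); go_ns <- character(0)
  go_ann <- data.frame(protein = character(0), term = character(0),
                       evidence = character(0), stringsAsFactors = FALSE)
  if (!is.null(dag_path)) {
    edges <- utils::read.delim(dag_path, header = FALSE, comment.char = "#",
                               stringsAsFactors = FALSE)
    if (ncol(edges) < 3L) stop("ontology file needs columns child, parent, namespace",
                               call. = FALSE)
    names(edges)[1:3] <- c("child", "parent", "namespace")
    terms <- unique(c(edges$child, edges$parent))
    go_dag <- stats::setNames(vector("list", length(terms)), terms)
    for (k in seq_len(nrow(edges))) {
      go_dag[[edges$child[k]]] <- c(go_dag[[edges$child[k]]], edges$parent[k])
    }
    go_dag <- lapply(go_dag, function(p) sort(unique(p %||% character(0))))
    assert_acyclic(go_dag)
    go_ns <- stats::setNames(edges$namespace, edges$child)
    roots <- setdiff(edges$parent, edges$child)
    for (r in roots) {
      ns <- unique(edges$namespace[edges$parent == r])
      go_ns[r] <- ns[1L]
    }
    go_ns <- go_ns[!duplicated(names(go_ns))]
  }
  if (!is.null(gaf_path)) {
    if (is.null(dag_path)) stop("GO annotations require an ontology file", call. = FALSE)
    raw <- readLines(gaf_path, warn = FALSE)
    raw <- raw[nzchar(raw) & !startsWith(raw, "!")]
    if (length(raw)) {
      f <- strsplit(raw, "\t", fixed = TRUE)
      short <- lengths(f) < 9L
      if (any(short)) stop("GAF row(s) with fewer than 9 columns", call. = FALSE)
      ann <- data.frame(protein  = vapply(f, `[[`, "", 2L),
                        term     = vapply(f, `[[`, "", 5L),
                        evidence = vapply(f, `[[`, "", 7L),
                        stringsAsFactors = FALSE)
      missing_terms <- setdiff(ann$term, names(go_dag))
      if (length(missing_terms)) {
        stop("GO term(s) absent from the ontology: ",
             paste(utils::head(missing_terms, 5L), collapse = ", "), call. = FALSE)
      }
      n0 <- nrow(ann)
      ann <- ann[ann$evidence %in% EXPERIMENTAL_EVIDENCE, , drop = FALSE]
      ann <- unique(ann)
      message(sprintf("GO annotations: kept %d, dropped %d without experimental evidence",
                      nrow(ann), n0 - nrow(ann)))
      go_ann <- ann
    }
  }
  ec_ann <- data.frame(protein = character(0), ec = character(0),
                       stringsAsFactors = FALSE)
  if (!is.null(ec_path)) {
    tab <- utils::read.delim(ec_path, header = FALSE, comment.char = "#",
                             stringsAsFactors = FALSE)
    names(tab)[1:2] <- c("protein", "ec")
    bad <- !grepl("^[0-9]+(\\.([0-9]+|-)){3}$", tab$ec)
    if (any(bad)) stop("malformed EC number(s): ",
                       paste(utils::head(tab$ec[bad], 3L), collapse = ", "),
                       call. = FALSE)
    ec_ann <- unique(tab[, c("protein", "ec")])
  }
  structure(list(go_dag = go_dag, go_namespace = go_ns,
                 go_annotations = go_ann, ec_annotations = ec_ann),
            class = "annotation_store")
}

# topological check; stops on a cycle
assert_acyclic <- function(dag) {
  state <- stats::setNames(integer(length(dag)), names(dag))  # 0 new, 1 open, 2 done
  visit <- function(t) {
    stack <- list(list(term = t, i = 0L))
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      if (fr$i == 0L) {
        if (state[[fr$term]] == 1L) stop("ontology contains a cycle through ",
                                         fr$term, call. = FALSE)
        if (state[[fr$term]] == 2L) { stack[[length(stack)]] <- NULL; next }
        state[[fr$term]] <<- 1L
      }
      parents <- dag[[fr$term]]
      if (fr$i < length(parents)) {
        stack[[length(stack)]]$i <- fr$i + 1L
        p <- parents[fr$i + 1L]
        if (state[[p]] == 1L) stop("ontology contains a cycle through ", p,
                                   call. = FALSE)
        if (state[[p]] == 0L) stack[[length(stack) + 1L]] <- list(term = p, i = 0L)
      } else {
        state[[fr$term]] <<- 2L
        stack[[length(stack)]] <- NULL
      }
    }
  }
  for (t in names(dag)) if (state[[t]] == 0L) visit(t)
  invisible(TRUE)
}

#' Read reference ortholog groups (RefOG-style TSV)
#'
#' @param path TSV with columns refog_id, protein token.
#' @return object of class `reference_groups`: `refogs` (named list of
#'   token vectors) and `universe`.
#' @export
read_reference_groups <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  names(tab)[1:2] <- c("refog_id", "protein")
  split_refs(tab$protein)
  if (anyDuplicated(tab$protein)) {
    stop("protein(s) in more than one reference group: ",
         paste(unique(tab$protein[duplicated(tab$protein)]), collapse = ", "),
         call. = FALSE)
  }
  refogs <- lapply(split(tab$protein, tab$refog_id), ref_sort)
  reference_groups(refogs)
}

#' Construct reference groups
#' @param refogs named list of disjoint token vectors.
#' @param universe optional benchmark universe (defaults to the union).
#' @return a `reference_groups` object.
#' @export
reference_groups <- function(refogs, universe = NULL) {
  members <- as.character(unlist(refogs, use.names = FALSE) %||% character(0))
  if (anyDuplicated(members)) stop("reference groups overlap", call. = FALSE)
  if (is.null(universe)) universe <- ref_sort(members)
  if (!all(members %in% universe)) stop("reference member outside universe", call. = FALSE)
  structure(list(refogs = refogs, universe = universe), class = "reference_groups")
}

#' Read an all-vs-all similarity table
#'
#' @param hits_path TSV with columns query, subject, raw_score,
#'   alignment_length (BLAST `-outfmt 6`-like subset); the best-scoring
#'   record per ordered (query, subject) pair is kept.
#' @param self_path TSV with columns protein, self_score.
#' @return object of class `similarity_table`.
#' @export
read_similarity_table <- function(hits_path, self_path) {
  hits <- utils::read.delim(hits_path, header = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE)
  names(hits)[1:4] <- c("query", "subject", "raw_score", "alignment_length")
  selfs <- utils::read.delim(self_path, header = FALSE, comment.char = "#",
                             stringsAsFactors = FALSE)
  names(selfs)[1:2] <- c("protein", "self_score")
  similarity_table(hits[, 1:4], stats::setNames(selfs$self_score, selfs$protein))
}

#' Construct a similarity table
#' @param hits data.frame(query, subject, raw_score, alignment_length).
#' @param self_scores named numeric vector of self-alignment scores.
#' @return a `similarity_table`.
#' @export
similarity_table <- function(hits, self_scores) {
  stopifnot(all(c("query", "subject", "raw_score", "alignment_length") %in% names(hits)))
  if (any(self_scores <= 0)) stop("self scores must be positive", call. = FALSE)
  hits <- hits[order(hits$query, hits$subject, -hits$raw_score, method = "radix"), ]
  hits <- hits[!duplicated(hits[, c("query", "subject")]), , drop = FALSE]
  rownames(hits) <- NULL
  structure(list(hits = hits, self_scores = self_scores),
            class = "similarity_table")
}

#' Write a meta result to a directory
#'
#' Writes the final groups in the groups-file dialect (round-trip safe),
#' the unassigned-protein list, and a JSON provenance report carrying the
#' parameters, seed and per-group provenance.
#'
#' @param result a [meta_result].
#' @param out_dir output directory (created if absent).
#' @return named character vector of the three paths, invisibly.
#' @export
write_meta_result <- function(result, out_dir) {
  stopifnot(inherits(result, "meta_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir,
                                 call. = FALSE)
  groups_path <- file.path(out_dir, "meta_groups.txt")
  lines <- vapply(result$final_groups, function(g) {
    paste0(g$group_id, ": ", paste(g$members, collapse = " "))
  }, "")
  writeLines(lines, groups_path, useBytes = TRUE)
  unassigned_path <- file.path(out_dir, "unassigned.txt")
  writeLines(result$unassigned, unassigned_path, useBytes = TRUE)
  prov_path <- file.path(out_dir, "provenance.json")
  prov <- list(
    params = result$params[c("evalue_threshold", "min_coverage", "min_size",
                             "backend")],
    rng_seed = result$rng_seed,
    n_final_groups = length(result$final_groups),
    n_unassigned = length(result$unassigned),
    groups = lapply(result$final_groups, function(g) {
      list(group_id = g$group_id, level = g$level,
           method_subset = as.list(g$method_subset),
           seed_members = as.list(g$seed_members),
           profile_added_members = as.list(g$profile_added_members),
           leftover = g$leftover_flag)
    })
  )
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(groups = groups_path, unassigned = unassigned_path,
              provenance = prov_path))
}
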