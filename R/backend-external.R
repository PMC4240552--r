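# External profile backend: shells out to a multiple aligner and to
# HMMER (hmmbuild/hmmsearch). Exposes the same hit semantics as the
# builtin backend (full-sequence E-value, sequence and profile coverage
# from the best-scoring domain); only the scores differ.

default_external_tools <- function() {
  list(aligner_cmd = "mafft --quiet --auto {in} > {out}",
       hmmbuild = "hmmbuild",
       hmmsearch = "hmmsearch")
}

#' Check that the external backend's binaries are available
#' @param tools list as in [meta_params]'s `external_tools`.
#' @return TRUE/FALSE.
#' @export
external_backend_available <- function(tools = NULL) {
  tools <- tools %||% default_external_tools()
  aligner <- strsplit(tools$aligner_cmd, "[[:space:]]+")[[1L]][1L]
  all(nzchar(Sys.which(c(aligner, tools$hmmbuild, tools$hmmsearch))))
}

external_msa <- function(seqs, tools = NULL) {
  tools <- tools %||% default_external_tools()
  fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".afa")
  on.exit(unlink(c(fin, fout)))
  write_proteome_fasta(seqs, fin)
  cmd <- sub("{out}", shQuote(fout), sub("{in}", shQuote(fin),
             tools$aligner_cmd, fixed = TRUE), fixed = TRUE)
  status <- system(cmd, ignore.stderr = TRUE)
  if (status != 0L || !file.exists(fout)) {
    stop("external aligner failed: ", cmd, call. = FALSE)
  }
  aa <- Biostrings::readAAStringSet(fout)
  rows <- toupper(as.character(aa))
  names(rows) <- vapply(strsplit(names(aa), "[[:space:]]+"), `[[`, "", 1L)
  rows <- rows[ref_order(names(rows))]
  structure(list(rows = rows, column_count = nchar(rows[[1L]])), class = "msa")
}

external_assign <- function(profiles, unassigned, params) {
  tools <- params$external_tools %||% default_external_tools()
  dir <- tempfile("hmm"); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  dbfa <- file.path(dir, "unassigned.fa")
  write_proteome_fasta(unassigned, dbfa)
  hits <- list()
  for (p in profiles) {
    msafa <- file.path(dir, paste0(p$group_id, ".afa"))
    rows <- p$msa$rows
    writeLines(paste0(">", names(rows), "\n", rows), msafa)
    hmm <- file.path(dir, paste0(p$group_id, ".hmm"))
    st <- system2(tools$hmmbuild, c("--amino", shQuote(hmm), shQuote(msafa)),
                  stdout = FALSE, stderr = FALSE)
    if (st != 0L) stop("hmmbuild failed for ", p$group_id, call. = FALSE)
    dtbl <- file.path(dir, paste0(p$group_id, ".domtbl"))
    st <- system2(tools$hmmsearch,
                  c("--domtblout", shQuote(dtbl), "-Z",
                    as.character(p$calibration$db_size), "--max",
                    shQuote(hmm), shQuote(dbfa)),
                  stdout = FALSE, stderr = FALSE)
    if (st != 0L) stop("hmmsearch failed for ", p$group_id, call. = FALSE)
    tab <- parse_domtblout(dtbl)
    if (nrow(tab)) {
      tab$group_id <- p$group_id
      hits[[length(hits) + 1L]] <- tab
    }
  }
  if (length(hits) == 0L) return(stats::setNames(character(0), character(0)))
  select_assignments(do.call(rbind, hits), params)
}

# best-domain coverage, full-sequence E-value, one row per target
parse_domtblout <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(protein = character(0), raw_score = numeric(0),
                      evalue = numeric(0), seq_coverage = numeric(0),
                      profile_coverage = numeric(0), stringsAsFactors = FALSE))
  }
  f <- strsplit(trimws(lines), "[[:space:]]+")
  tab <- data.frame(
    protein = vapply(f, `[[`, "", 1L),
    tlen    = as.numeric(vapply(f, `[[`, "", 3L)),
    qlen    = as.numeric(vapply(f, `[[`, "", 6L)),
    evalue  = as.numeric(vapply(f, `[[`, "", 7L)),
    raw_score = as.numeric(vapply(f, `[[`, "", 8L)),
    dom_ie  = as.numeric(vapply(f, `[[`, "", 13L)),
    hmm_from = as.numeric(vapply(f, `[[`, "", 16L)),
    hmm_to   = as.numeric(vapply(f, `[[`, "", 17L)),
    ali_from = as.numeric(vapply(f, `[[`, "", 18L)),
    ali_to   = as.numeric(vapply(f, `[[`, "", 19L)),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$protein, tab$dom_ie, method = "radix"), , drop = FALSE]
  tab <- tab[!duplicated(tab$protein), , drop = FALSE]
  data.frame(protein = tab$protein,
             raw_score = tab$raw_score,
             evalue = tab$evalue,
             seq_coverage = (tab$ali_to - tab$ali_from + 1) / tab$tlen,
             profile_coverage = (tab$hmm_to - tab$hmm_from + 1) / tab$qlen,
             stringsAsFactors = FALSE)
}
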