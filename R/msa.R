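# Builtin multiple aligner: center-star progressive alignment under
# BLOSUM62 with affine gaps (open 11, extend 1). The center is the
# sequence maximising the summed pairwise global-alignment score
# (equivalently minimising summed alignment distance); other sequences
# are merged against it under "once a gap, always a gap". Fully
# deterministic: ties are broken by protein token order.

#' Multiple alignment of a seed group (center-star)
#'
#' @param seqs named character vector of residue strings (names are
#'   `species|protein` tokens); at least two.
#' @param gap_open,gap_extend positive gap penalties (BLOSUM62 units).
#' @return object of class `msa`: `rows` (named character vector of
#'   aligned strings with `-` gaps, in token order) and `column_count`.
#' @export
build_msa <- function(seqs, gap_open = 11, gap_extend = 1) {
  if (length(seqs) < 2L) stop("an alignment needs at least 2 sequences", call. = FALSE)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must carry unique protein tokens as names", call. = FALSE)
  }
  seqs <- seqs[ref_order(names(seqs))]
  codes <- lapply(seqs, encode_seq)
  sub <- blosum62_matrix()
  if (length(seqs) == 2L) {
    aln <- .nw_align(codes[[1L]], codes[[2L]], sub, gap_open, gap_extend)
    rows <- stats::setNames(c(decode_aln(aln$aligned1), decode_aln(aln$aligned2)),
                            names(seqs))
    return(structure(list(rows = rows, column_count = length(aln$aligned1)),
                     class = "msa"))
  }
  scores <- .nw_score_matrix(unname(codes), sub, gap_open, gap_extend)
  totals <- rowSums(scores)
  center <- which(totals == max(totals))[1L]   # names already token-sorted
  others <- setdiff(seq_along(seqs), center)
  # master alignment state: each row an integer vector (0 = gap);
  # master_map marks which master columns hold center residues
  master <- list(codes[[center]])
  master_map <- seq_along(codes[[center]])     # >0: center position, 0: insertion
  row_ids <- center
  for (o in others) {
    aln <- .nw_align(codes[[center]], codes[[o]], sub, gap_open, gap_extend)
    pw_map <- ifelse(aln$aligned1 > 0L, cumsum(aln$aligned1 > 0L), 0L)
    merged <- merge_into_master(master, master_map, aln$aligned2, pw_map)
    master <- merged$rows
    master_map <- merged$map
    row_ids <- c(row_ids, o)
  }
  ord <- order(row_ids)
  rows <- vapply(master[ord], decode_aln, "")
  names(rows) <- names(seqs)[row_ids[ord]]
  structure(list(rows = rows, column_count = length(master_map)), class = "msa")
}

decode_aln <- function(codes) {
  paste(ifelse(codes == 0L, "-", AA_X[pmax(codes, 1L)]), collapse = "")
}

# merge one pairwise (center, new) alignment into the master alignment;
# master insertion columns are emitted before new insertion columns at
# the same center position (deterministic)
merge_into_master <- function(rows, map, new_row, pw_map) {
  n_master <- length(map); n_pw <- length(pw_map)
  out_src_master <- integer(0); out_src_pw <- integer(0); out_map <- integer(0)
  i <- 1L; j <- 1L
  while (i <= n_master || j <= n_pw) {
    if (i <= n_master && map[i] == 0L) {
      out_src_master <- c(out_src_master, i); out_src_pw <- c(out_src_pw, 0L)
      out_map <- c(out_map, 0L); i <- i + 1L
    } else if (j <= n_pw && pw_map[j] == 0L) {
      out_src_master <- c(out_src_master, 0L); out_src_pw <- c(out_src_pw, j)
      out_map <- c(out_map, 0L); j <- j + 1L
    } else {
      # both at the same center residue
      out_src_master <- c(out_src_master, i); out_src_pw <- c(out_src_pw, j)
      out_map <- c(out_map, map[i]); i <- i + 1L; j <- j + 1L
    }
  }
  new_rows <- lapply(rows, function(r) {
    ifelse(out_src_master > 0L, r[pmax(out_src_master, 1L)], 0L)
  })
  added <- ifelse(out_src_pw > 0L, new_row[pmax(out_src_pw, 1L)], 0L)
  new_rows[[length(new_rows) + 1L]] <- added
  list(rows = new_rows, map = out_map)
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns\n", length(x$rows), x$column_count))
  invisible(x)
}
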