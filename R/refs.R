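#' @useDynLib metaortho, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats sd setNames rnorm runif
#' @importFrom utils combn head
NULL

# Protein identifiers ---------------------------------------------------
#
# A protein is identified throughout the package by its `species|protein`
# token (e.g. "HUMAN|P53"). Both fields must be non-empty and free of
# whitespace and the `|` delimiter. Ordering is lexicographic on
# (species, protein) in the C locale; it is total and stable and is the
# tie-break order used everywhere randomness must be avoided.

#' Build protein reference tokens
#'
#' @param species,protein character vectors of equal length.
#' @return character vector of `species|protein` tokens.
#' @export
protein_ref <- function(species, protein) {
  check_ref_field(species, "species")
  check_ref_field(protein, "protein")
  paste(species, protein, sep = "|")
}

check_ref_field <- function(x, what) {
  bad <- !nzchar(x) | grepl("[|[:space:]]", x)
  if (any(bad)) {
    stop(sprintf("invalid %s field(s): %s", what,
                 paste(utils::head(x[bad], 3L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

#' Split reference tokens into species and protein
#'
#' @param refs character vector of `species|protein` tokens.
#' @return data.frame with columns `species` and `protein`.
#' @export
split_refs <- function(refs) {
  bad <- !grepl("^[^|[:space:]]+\\|[^|[:space:]]+$", refs)
  if (any(bad)) {
    stop("malformed protein token(s): ",
         paste(utils::head(refs[bad], 3L), collapse = ", "), call. = FALSE)
  }
  parts <- strsplit(refs, "|", fixed = TRUE)
  data.frame(species = vapply(parts, `[[`, "", 1L),
             protein = vapply(parts, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Species labels of reference tokens
#' @param refs character vector of tokens.
#' @return character vector of species labels.
#' @export
ref_species <- function(refs) sub("\\|.*$", "", refs)

# total, locale-independent order on (species, protein)
ref_order <- function(refs) {
  if (length(refs) == 0L) return(integer(0))
  s <- split_refs(refs)
  order(s$species, s$protein, method = "radix")
}

ref_sort <- function(refs) {
  refs <- as.character(refs %||% character(0))
  refs[ref_order(refs)]
}

# canonical group order: descending size, ties by lexicographically
# smallest member; used for deterministic ids and processing order
order_groups <- function(groups) {
  if (length(groups) == 0L) return(integer(0))
  sizes <- lengths(groups)
  first <- vapply(groups, function(g) ref_sort(g)[1L], "")
  s <- split_refs(first)
  order(-sizes, s$species, s$protein, method = "radix")
}

# derive a child RNG seed from a master seed (kept below 2^31)
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483647
}

# evaluate expr under a temporary RNG seed, restoring global RNG state
with_rng <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Amino-acid alphabet and background -----------------------------------

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_X <- c(AA_ALPHABET, "X")

#' Background amino-acid frequencies
#'
#' Robinson-Robinson residue frequencies, normalised to sum to one; the
#' default null model of the builtin profile backend.
#' @return named numeric vector over the 20 standard residues.
#' @export
robinson_frequencies <- function() {
  f <- c(A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
         Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
         L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
         S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)
  f <- f[AA_ALPHABET]
  f / sum(f)
}

# integer residue codes (1..21, X = 21); residues outside the alphabet
# are an error at this level -- io normalises first
encode_seq <- function(x) {
  codes <- match(strsplit(x, "", fixed = TRUE)[[1L]], AA_X)
  if (anyNA(codes)) stop("sequence contains non-amino-acid characters", call. = FALSE)
  codes
}

decode_seq <- function(codes) paste(AA_X[codes], collapse = "")

# BLOSUM62 over the package alphabet (incl. X), from Biostrings
blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62[AA_X, AA_X]
    }
    cache
  }
})
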