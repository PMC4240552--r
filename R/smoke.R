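# The 12-protein smoke fixture: two sequence families plus three decoy
# proteins, and three simulated method predictions whose level-by-level
# consensus can be traced by hand. Used as the golden end-to-end test
# and emitted by the `simulate` command's smoke preset.

#' The golden 12-protein smoke fixture
#'
#' Three methods over 9 grouped proteins plus 3 decoys. At level 3 the
#' only intersection cell of size >= 4 is the first family's core
#' {A|p1, A|p4, B|p2, C|p3}; its profile recruits the fifth family
#' member B|p5. At level 2 the second family {A|p6, A|p9, B|p7, C|p8}
#' is a seed; the small two-method cells left over are already
#' finalized, so the decoys remain unassigned.
#'
#' @return list: `groupsets` (3 [group_set]s), `proteome`, `expected`
#'   (list of final member sets in canonical order and the unassigned
#'   tokens).
#' @export
smoke_fixture <- function() {
  bg <- robinson_frequencies()
  with_rng(7L, {
    anc1 <- random_sequence(60L, bg)
    anc2 <- random_sequence(60L, bg)
    fam1 <- vapply(1:5, function(k) diverge_sequence(anc1, 0.08, bg), "")
    fam2 <- vapply(1:4, function(k) diverge_sequence(anc2, 0.08, bg), "")
    decoys <- vapply(1:3, function(k) random_sequence(60L, bg), "")
    a <- "A|p1"; b <- "B|p2"; cc <- "C|p3"; d <- "A|p4"; e <- "B|p5"
    f <- "A|p6"; g <- "B|p7"; h <- "C|p8"; i <- "A|p9"
    x <- c("C|x1", "A|x2", "B|x3")
    proteome <- stats::setNames(c(fam1, fam2, decoys),
                                c(a, b, cc, d, e, f, g, h, i, x))
    groupsets <- list(
      group_set("M1", list(c(a, b, cc, d, e), c(f, g, h, i))),
      group_set("M2", list(c(a, b, cc, d), c(e, f, g, h, i))),
      group_set("M3", list(c(a, b, cc, d, f), c(e, g, h, i))))
    expected <- list(
      final_members = list(ref_sort(c(a, b, cc, d, e)),
                           ref_sort(c(f, g, h, i))),
      unassigned = ref_sort(x))
    list(groupsets = groupsets, proteome = proteome, expected = expected)
  })
}
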