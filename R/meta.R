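# The consensus driver: iterate intersection levels from i = N down to
# 2, build/calibrate one profile per seed group, recruit unassigned
# proteins, finalize, and append the small two-method leftover cells.

#' Parameters of the consensus run
#'
#' Defaults are the method's standard operating point: E-value threshold
#' 1e-10, minimum alignment coverage 40\% (enforced against both the
#' sequence and the profile length), minimum intersection size 4.
#'
#' @param evalue_threshold strict upper bound on the profile-hit E-value.
#' @param min_coverage minimum of sequence and profile coverage, in (0,1].
#' @param min_size minimum seed-group size (>= 2).
#' @param rng_seed integer seed owned by the run.
#' @param backend `"builtin"` (position-specific profile, offline) or
#'   `"external"` (aligner + HMMER binaries).
#' @param n_decoys decoys per profile for Gumbel calibration (builtin).
#' @param missing_sequences `"error"` or `"skip"`: what to do when a
#'   grouped protein has no sequence in the proteome.
#' @param external_tools list(aligner_cmd, hmmbuild, hmmsearch) for the
#'   external backend; `aligner_cmd` is a template with `{in}`/`{out}`.
#' @return object of class `meta_params`.
#' @export
meta_params <- function(evalue_threshold = 1e-10, min_coverage = 0.40,
                        min_size = 4L, rng_seed = 1L,
                        backend = c("builtin", "external"),
                        n_decoys = 200L,
                        missing_sequences = c("error", "skip"),
                        external_tools = NULL) {
  backend <- match.arg(backend)
  missing_sequences <- match.arg(missing_sequences)
  stopifnot(evalue_threshold > 0, min_coverage > 0, min_coverage <= 1,
            min_size >= 2)
  structure(list(evalue_threshold = evalue_threshold,
                 min_coverage = min_coverage,
                 min_size = as.integer(min_size),
                 rng_seed = as.integer(rng_seed),
                 backend = backend,
                 n_decoys = as.integer(n_decoys),
                 missing_sequences = missing_sequences,
                 external_tools = external_tools),
            class = "meta_params")
}

#' Consensus ortholog groups from several methods' predictions
#'
#' Starting from the predictions of N >= 2 methods, seed groups are
#' formed at level i = N as exact intersections of i methods' groups
#' (cells of the partitions' common refinement) of size >= `min_size`.
#' Each seed is aligned, turned into a profile, and unassigned proteins
#' clearing the E-value and coverage thresholds are recruited (at most
#' one group per protein). The resulting groups are final: their
#' proteins leave the pool. The level then drops by one and the loop
#' repeats while i > 2 and unassigned proteins remain. After the i = 2
#' pass, two-method intersection cells of size 2..`min_size`-1 whose
#' members are still unassigned are appended as leftover final groups.
#'
#' @param groupsets list of >= 2 [group_set] objects.
#' @param proteome named character vector of sequences, or NULL to skip
#'   the profile-expansion stage (pure intersection).
#' @param params a [meta_params].
#' @return object of class `meta_result`: `final_groups` (each with
#'   members, level, method_subset, seed vs profile-added members and a
#'   leftover flag), `unassigned`, `params`, `rng_seed`.
#' @export
run_meta <- function(groupsets, proteome = NULL, params = meta_params()) {
  if (length(groupsets) < 2L) {
    stop("the consensus needs N >= 2 input methods", call. = FALSE)
  }
  stopifnot(inherits(params, "meta_params"))
  method_universe <- ref_sort(unique(unlist(lapply(groupsets, `[[`, "universe"),
                                            use.names = FALSE)))
  expand <- !is.null(proteome)
  if (expand) {
    missing <- setdiff(method_universe, names(proteome))
    if (length(missing)) {
      if (params$missing_sequences == "error") {
        stop("grouped protein(s) missing from the proteome: ",
             paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
      }
      warning(sprintf("%d grouped protein(s) have no sequence; they can seed but not be recruited",
                      length(missing)), call. = FALSE)
    }
    pool <- ref_sort(unique(c(method_universe, names(proteome))))
  } else {
    pool <- method_universe
  }
  n <- length(groupsets)
  final <- list()
  tie_log <- NULL
  with_rng(params$rng_seed, {
    i <- n
    repeat {
      lev <- intersect_level(groupsets, i, pool, params$min_size)
      tie_log <- rbind(tie_log, lev$tie_log)
      seeds <- lev$seeds
      assigned <- stats::setNames(character(0), character(0))
      if (expand && length(seeds)) {
        seed_members <- unlist(lapply(seeds, `[[`, "members"), use.names = FALSE)
        unassigned_now <- setdiff(pool, seed_members)
        unassigned_now <- unassigned_now[unassigned_now %in% names(proteome)]
        if (length(unassigned_now)) {
          ids <- sprintf("L%d_S%03d", i, seq_along(seeds))
          profiles <- vector("list", length(seeds))
          for (k in seq_along(seeds)) {
            mem <- seeds[[k]]$members
            mem <- mem[mem %in% names(proteome)]
            if (length(mem) < 2L) next
            msa <- backend_msa(proteome[mem], params)
            prof <- backend_profile(msa, params, group_id = ids[k])
            profiles[[k]] <- backend_calibrate(prof, proteome[unassigned_now],
                                               params,
                                               db_size = length(unassigned_now))
          }
          keep <- !vapply(profiles, is.null, NA)
          if (any(keep)) {
            assigned <- backend_assign(profiles[keep],
                                       proteome[unassigned_now], params,
                                       msas = lapply(seeds[keep], function(s)
                                         proteome[s$members[s$members %in% names(proteome)]]))
            names(ids) <- NULL
            assigned_group <- match(assigned, ids)
            assigned <- assigned[!is.na(assigned_group)]
          }
        }
      }
      for (k in seq_along(seeds)) {
        sd_mem <- seeds[[k]]$members
        added <- if (length(assigned)) {
          names(assigned)[assigned == sprintf("L%d_S%03d", i, k)]
        } else character(0)
        final[[length(final) + 1L]] <- list(
          members = ref_sort(c(sd_mem, added)),
          level = i,
          method_subset = seeds[[k]]$method_subset,
          seed_members = sd_mem,
          profile_added_members = ref_sort(added),
          leftover_flag = FALSE)
      }
      finalized <- unlist(lapply(final, `[[`, "members"), use.names = FALSE)
      pool <- setdiff(pool, finalized)
      still_predicted <- intersect(pool, method_universe)
      if (i == 2L) {
        # leftover two-method cells, restricted to what is still free
        for (cl in lev$rejected) {
          mem <- intersect(cl$members, pool)
          if (length(mem) >= 2L && length(mem) < params$min_size) {
            final[[length(final) + 1L]] <- list(
              members = ref_sort(mem), level = 2L,
              method_subset = cl$subset,
              seed_members = ref_sort(mem),
              profile_added_members = character(0),
              leftover_flag = TRUE)
            pool <- setdiff(pool, mem)
          }
        }
        break
      }
      if (length(still_predicted) == 0L) break
      i <- i - 1L
    }
  })
  # deterministic ids over the finalized set
  ord <- order_groups(lapply(final, `[[`, "members"))
  final <- final[ord]
  for (k in seq_along(final)) final[[k]]$group_id <- paste0("G", k)
  structure(list(final_groups = final,
                 unassigned = ref_sort(pool),
                 params = params,
                 rng_seed = params$rng_seed,
                 n_methods = n,
                 tie_log = tie_log),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("meta_result: %d final groups (%d proteins), %d unassigned\n",
              length(x$final_groups),
              sum(lengths(lapply(x$final_groups, `[[`, "members"))),
              length(x$unassigned)))
  invisible(x)
}

#' @method summary meta_result
#' @export
summary.meta_result <- function(object, ...) {
  lv <- vapply(object$final_groups, `[[`, 0L, "level")
  lo <- vapply(object$final_groups, `[[`, NA, "leftover_flag")
  added <- sum(lengths(lapply(object$final_groups, `[[`, "profile_added_members")))
  cat("Consensus ortholog groups\n")
  cat(sprintf("  input methods: %d\n", object$n_methods))
  cat(sprintf("  thresholds: E < %g, coverage >= %.2f, min size %d, seed %d\n",
              object$params$evalue_threshold, object$params$min_coverage,
              object$params$min_size, object$rng_seed))
  cat(sprintf("  final groups: %d (%d leftover cells)\n",
              length(object$final_groups), sum(lo)))
  for (l in sort(unique(lv), decreasing = TRUE)) {
    cat(sprintf("    level %d: %d groups\n", l, sum(lv == l & !lo)))
  }
  cat(sprintf("  profile-recruited proteins: %d\n", added))
  cat(sprintf("  unassigned proteins: %d\n", length(object$unassigned)))
  invisible(object)
}

# backend dispatch ------------------------------------------------------

backend_msa <- function(seqs, params, ...) {
  if (params$backend == "builtin") build_msa(seqs)
  else external_msa(seqs, params$external_tools)
}

backend_profile <- function(msa, params, group_id) {
  if (params$backend == "builtin") build_profile(msa, group_id = group_id)
  else structure(list(group_id = group_id, msa = msa, calibration = NULL),
                 class = "external_profile")
}

backend_calibrate <- function(profile, decoy_pool, params, db_size) {
  if (params$backend == "builtin") {
    calibrate_profile(profile, decoy_pool,
                      n_decoys = max(50L, params$n_decoys), db_size = db_size)
  } else {
    profile$calibration <- list(db_size = as.integer(db_size))
    profile
  }
}

backend_assign <- function(profiles, unassigned, params, msas = NULL) {
  if (params$backend == "builtin") {
    assign_unassigned(profiles, unassigned, params)
  } else {
    external_assign(profiles, unassigned, params)
  }
}
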