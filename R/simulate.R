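# Seeded synthetic-data generator: ground-truth ortholog groups with
# diverged member sequences, GO/EC annotations concentrated within
# groups, and error-perturbed "method predictions" with controlled
# fission/fusion/dropout/relocation rates. Substitution-only sequence
# evolution (no indels) so alignment oracles stay exact; the GO DAG is a
# balanced three-level tree. Not a phylogenetically realistic simulator.

#' Parameters of the synthetic study
#'
#' @param n_species number of species (>= 2).
#' @param n_groups number of true ortholog groups.
#' @param group_size_range per-species member-count range (min, max).
#' @param seq_length_mean,seq_length_sd ancestor length distribution.
#' @param divergence_range per-group per-site substitution probability
#'   interval.
#' @param n_decoy_proteins unrelated random sequences added to the
#'   proteome.
#' @param annotation_fidelity probability a member inherits its group's
#'   GO/EC term (else a random term).
#' @param error_model list(p_fission, p_fusion, p_dropout, p_relocate)
#'   applied by [perturb_prediction].
#' @param rng_seed master seed.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(n_species = 6L, n_groups = 40L,
                       group_size_range = c(1L, 2L),
                       seq_length_mean = 120, seq_length_sd = 15,
                       divergence_range = c(0.05, 0.5),
                       n_decoy_proteins = 30L,
                       annotation_fidelity = 0.9,
                       error_model = list(p_fission = 0.1, p_fusion = 0.1,
                                          p_dropout = 0.05, p_relocate = 0.02),
                       rng_seed = 1L) {
  stopifnot(n_species >= 2L, n_groups >= 1L,
            length(group_size_range) == 2L,
            group_size_range[1L] >= 1L,
            group_size_range[2L] >= group_size_range[1L],
            divergence_range[1L] >= 0, divergence_range[2L] <= 1,
            divergence_range[2L] >= divergence_range[1L],
            annotation_fidelity >= 0, annotation_fidelity <= 1,
            all(unlist(error_model) >= 0), all(unlist(error_model) <= 1))
  structure(list(n_species = as.integer(n_species),
                 n_groups = as.integer(n_groups),
                 group_size_range = as.integer(group_size_range),
                 seq_length_mean = seq_length_mean,
                 seq_length_sd = seq_length_sd,
                 divergence_range = divergence_range,
                 n_decoy_proteins = as.integer(n_decoy_proteins),
                 annotation_fidelity = annotation_fidelity,
                 error_model = error_model,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_params")
}

random_sequence <- function(len, bg) {
  paste(sample(AA_ALPHABET, len, replace = TRUE, prob = bg), collapse = "")
}

diverge_sequence <- function(anc, rate, bg) {
  codes <- strsplit(anc, "", fixed = TRUE)[[1L]]
  hit <- runif(length(codes)) < rate
  if (any(hit)) {
    repl <- vapply(which(hit), function(k) {
      pool <- setdiff(AA_ALPHABET, codes[k])
      sample(pool, 1L, prob = bg[pool] / sum(bg[pool]))
    }, "")
    codes[hit] <- repl
  }
  paste(codes, collapse = "")
}

#' Simulate ground truth: proteome, reference groups, annotations
#'
#' Each group descends from an ancestor sequence drawn i.i.d. from the
#' background; members are per-site substituted copies at the group's
#' divergence rate. Each group carries a distinct leaf term of a
#' balanced three-level GO tree (root, 5 internal nodes, one leaf per
#' group) and a synthetic EC serial under a shared three-level prefix,
#' inherited by members with probability `annotation_fidelity`.
#'
#' @param params a [sim_params].
#' @return list: `proteome` (named sequences), `truth`
#'   ([reference_groups]), `store` (annotation store), `divergences`.
#' @export
simulate_truth <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  bg <- robinson_frequencies()
  with_rng(params$rng_seed, {
    proteome <- character(0)
    refogs <- list()
    divergences <- numeric(params$n_groups)
    go_rows <- list(); ec_rows <- list()
    leaves <- sprintf("GO:L%03d", seq_len(params$n_groups))
    for (k in seq_len(params$n_groups)) {
      len <- max(30L, round(rnorm(1, params$seq_length_mean, params$seq_length_sd)))
      anc <- random_sequence(len, bg)
      d <- runif(1, params$divergence_range[1L], params$divergence_range[2L])
      divergences[k] <- d
      members <- character(0)
      for (s in seq_len(params$n_species)) {
        n_mem <- sample(seq(params$group_size_range[1L],
                            params$group_size_range[2L]), 1L)
        for (m in seq_len(n_mem)) {
          tok <- sprintf("sp%d|g%03dm%d", s, k, m)
          proteome[tok] <- diverge_sequence(anc, d, bg)
          members <- c(members, tok)
        }
      }
      refogs[[sprintf("OG%03d", k)]] <- ref_sort(members)
      for (tok in members) {
        go_term <- if (runif(1) < params$annotation_fidelity) leaves[k]
                   else sample(leaves, 1L)
        go_rows[[length(go_rows) + 1L]] <- c(tok, go_term)
        ec_k <- if (runif(1) < params$annotation_fidelity) k
                else sample.int(params$n_groups, 1L)
        ec_rows[[length(ec_rows) + 1L]] <- c(tok, sprintf("1.1.1.%d", ec_k))
      }
    }
    for (j in seq_len(params$n_decoy_proteins)) {
      s <- ((j - 1L) %% params$n_species) + 1L
      len <- max(30L, round(rnorm(1, params$seq_length_mean, params$seq_length_sd)))
      proteome[sprintf("sp%d|decoy%03d", s, j)] <- random_sequence(len, bg)
    }
    # balanced 3-level DAG: root -> 5 internal -> one leaf per group
    internal <- sprintf("GO:I%d", 1:5)
    dag <- stats::setNames(vector("list", 1L + 5L + params$n_groups),
                           c("GO:ROOT", internal, leaves))
    dag[["GO:ROOT"]] <- character(0)
    for (i in 1:5) dag[[internal[i]]] <- "GO:ROOT"
    for (k in seq_len(params$n_groups)) {
      dag[[leaves[k]]] <- internal[((k - 1L) %% 5L) + 1L]
    }
    ns <- stats::setNames(rep("synthetic_process", length(dag)), names(dag))
    go_ann <- as.data.frame(do.call(rbind, go_rows), stringsAsFactors = FALSE)
    names(go_ann) <- c("protein", "term")
    go_ann$evidence <- "IDA"
    ec_ann <- as.data.frame(do.call(rbind, ec_rows), stringsAsFactors = FALSE)
    names(ec_ann) <- c("protein", "ec")
    store <- structure(list(go_dag = dag, go_namespace = ns,
                            go_annotations = unique(go_ann),
                            ec_annotations = unique(ec_ann)),
                       class = "annotation_store")
    list(proteome = proteome,
         truth = reference_groups(refogs, universe = ref_sort(names(proteome))),
         store = store,
         divergences = divergences,
         params = params)
  })
}

#' Perturb the truth into one method's prediction
#'
#' Per group: with `p_fission` split at a uniform point into two groups;
#' with `p_fusion` merge with another randomly chosen group. Per
#' protein: with `p_dropout` remove from the output; with `p_relocate`
#' move to a random other group. Singletons are dropped, so the output
#' is a valid partition.
#'
#' @param truth [reference_groups].
#' @param error_model list(p_fission, p_fusion, p_dropout, p_relocate).
#' @param method_name name of the output [group_set].
#' @param seed optional seed; NULL uses the current RNG state.
#' @return a [group_set].
#' @export
perturb_prediction <- function(truth, error_model, method_name = "perturbed",
                               seed = NULL) {
  em <- error_model
  run <- function() {
    glist <- unname(lapply(truth$refogs, ref_sort))
    # fissions
    out <- list()
    for (g in glist) {
      if (length(g) >= 2L && runif(1) < em$p_fission) {
        cut <- sample.int(length(g) - 1L, 1L)
        out <- c(out, list(g[seq_len(cut)], g[-seq_len(cut)]))
      } else out <- c(out, list(g))
    }
    glist <- out
    # fusions
    i <- 1L
    while (i <= length(glist)) {
      if (length(glist) > 1L && runif(1) < em$p_fusion) {
        j <- setdiff(seq_along(glist), i)[sample.int(length(glist) - 1L, 1L)]
        glist[[i]] <- ref_sort(c(glist[[i]], glist[[j]]))
        glist[[j]] <- NULL
        if (j < i) i <- i - 1L
      }
      i <- i + 1L
    }
    # per-protein dropout and relocation
    n_g <- length(glist)
    for (gi in seq_len(n_g)) {
      for (p in glist[[gi]]) {
        u <- runif(1)
        if (u < em$p_dropout) {
          glist[[gi]] <- setdiff(glist[[gi]], p)
        } else if (n_g > 1L && runif(1) < em$p_relocate) {
          gj <- setdiff(seq_len(n_g), gi)[sample.int(n_g - 1L, 1L)]
          glist[[gi]] <- setdiff(glist[[gi]], p)
          glist[[gj]] <- c(glist[[gj]], p)
        }
      }
    }
    group_set(method_name, glist)
  }
  if (is.null(seed)) run() else with_rng(seed, run())
}

#' Simulate a suite of input methods
#'
#' One perturbed prediction per method, each with its own error model
#' and a seed derived from the master seed.
#'
#' @param truth [reference_groups].
#' @param n_methods number of methods (>= 2).
#' @param error_models single error-model list, or one per method.
#' @param seed master seed.
#' @return list of [group_set]s named `sim_m1` ...
#' @export
make_method_suite <- function(truth, n_methods = 4L,
                              error_models = sim_params()$error_model,
                              seed = 1L) {
  stopifnot(n_methods >= 2L)
  if (!is.null(names(error_models)) && "p_fission" %in% names(error_models)) {
    error_models <- rep(list(error_models), n_methods)
  }
  stopifnot(length(error_models) == n_methods)
  lapply(seq_len(n_methods), function(m) {
    perturb_prediction(truth, error_models[[m]],
                       method_name = sprintf("sim_m%d", m),
                       seed = derive_seed(seed, m))
  })
}

#' Write a simulated study to disk
#'
#' Emits the FASTA proteome, one groups file per method, the
#' reference-group TSV and the GAF/ontology/EC annotation files that the
#' package readers consume.
#'
#' @param sim a [simulate_truth] result.
#' @param methods list of [group_set]s (optional).
#' @param dir output directory.
#' @return named vector of paths, invisibly.
#' @export
write_simulation <- function(sim, methods = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "proteome.fa"))
  write_proteome_fasta(sim$proteome, paths[["fasta"]])
  ref_path <- file.path(dir, "refogs.tsv")
  rows <- unlist(lapply(names(sim$truth$refogs), function(id) {
    paste(id, sim$truth$refogs[[id]], sep = "\t")
  }))
  writeLines(rows, ref_path, useBytes = TRUE)
  paths["refogs"] <- ref_path
  dag_path <- file.path(dir, "ontology.tsv")
  dag <- sim$store$go_dag
  edges <- unlist(lapply(names(dag), function(ch) {
    if (length(dag[[ch]]) == 0L) return(character(0))
    paste(ch, dag[[ch]], sim$store$go_namespace[[ch]], sep = "\t")
  }))
  writeLines(edges, dag_path, useBytes = TRUE)
  paths["ontology"] <- dag_path
  gaf_path <- file.path(dir, "annotations.gaf")
  ann <- sim$store$go_annotations
  gaf <- paste("SIM", ann$protein, "-", "", ann$term, "SIM:ref", ann$evidence,
               "", "P", sep = "\t")
  writeLines(c("!gaf-version: 2.2", gaf), gaf_path, useBytes = TRUE)
  paths["gaf"] <- gaf_path
  ec_path <- file.path(dir, "ec.tsv")
  writeLines(paste(sim$store$ec_annotations$protein,
                   sim$store$ec_annotations$ec, sep = "\t"),
             ec_path, useBytes = TRUE)
  paths["ec"] <- ec_path
  if (!is.null(methods)) {
    for (gs in methods) {
      p <- file.path(dir, paste0(gs$method_name, ".groups"))
      write_group_set(gs, p)
      paths[gs$method_name] <- p
    }
  }
  invisible(paths)
}
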