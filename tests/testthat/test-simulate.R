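test_that("the generator is a pure function of its seed", {
  sp <- sim_params(n_groups = 6, n_species = 3, n_decoy_proteins = 4,
                   rng_seed = 33)
  a <- simulate_truth(sp); b <- simulate_truth(sp)
  expect_identical(a$proteome, b$proteome)
  expect_identical(a$truth$refogs, b$truth$refogs)
  expect_identical(a$store$go_annotations, b$store$go_annotations)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(a, dir = d1); write_simulation(b, dir = d2)
  expect_identical(readLines(file.path(d1, "proteome.fa")),
                   readLines(file.path(d2, "proteome.fa")))
  # a different seed changes the output
  c2 <- simulate_truth(sim_params(n_groups = 6, n_species = 3,
                                  n_decoy_proteins = 4, rng_seed = 34))
  expect_false(identical(a$proteome, c2$proteome))
})

test_that("zero divergence copies the ancestor; identity decays with divergence", {
  sp0 <- sim_params(n_groups = 4, n_species = 3,
                    divergence_range = c(0, 1e-12), rng_seed = 5)
  sim0 <- simulate_truth(sp0)
  for (og in sim0$truth$refogs) {
    expect_length(unique(unname(sim0$proteome[og])), 1L)
  }
  pct_ident <- function(sim) {
    mean(sapply(sim$truth$refogs, function(og) {
      s <- sim$proteome[og]
      a <- strsplit(s[[1]], "")[[1]]; b <- strsplit(s[[length(s)]], "")[[1]]
      mean(a == b)
    }))
  }
  lo <- mean(sapply(1:5, function(k) {
    pct_ident(simulate_truth(sim_params(n_groups = 8, n_species = 3,
                                        divergence_range = c(0.05, 0.08),
                                        rng_seed = 40 + k)))
  }))
  hi <- mean(sapply(1:5, function(k) {
    pct_ident(simulate_truth(sim_params(n_groups = 8, n_species = 3,
                                        divergence_range = c(0.45, 0.5),
                                        rng_seed = 60 + k)))
  }))
  expect_gt(lo, hi)
})

test_that("annotations concentrate within groups at high fidelity", {
  sim <- simulate_truth(sim_params(n_groups = 10, n_species = 4,
                                   annotation_fidelity = 1, rng_seed = 8))
  ann <- sim$store$go_annotations
  for (k in seq_along(sim$truth$refogs)) {
    og <- sim$truth$refogs[[k]]
    terms <- ann$term[ann$protein %in% og]
    expect_length(unique(terms), 1L)
  }
  expect_true(all(ann$evidence %in% c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP")))
})

test_that("a zero-error perturbation is the identity on co-membership", {
  sim <- simulate_truth(sim_params(n_groups = 8, n_species = 4, rng_seed = 9))
  em0 <- list(p_fission = 0, p_fusion = 0, p_dropout = 0, p_relocate = 0)
  gs <- perturb_prediction(sim$truth, em0, seed = 1)
  truth_gs <- group_set("truth", unname(sim$truth$refogs))
  expect_identical(unclass(ortholog_pairs(gs)), unclass(ortholog_pairs(truth_gs)))
  # and run_meta on identical zero-error methods returns the truth exactly
  methods <- make_method_suite(sim$truth, 3, em0, seed = 2)
  res <- run_meta(methods, sim$proteome, meta_params(rng_seed = 3))
  expect_identical(group_keys(lapply(res$final_groups, `[[`, "members")),
                   group_keys(sim$truth$refogs))
})

test_that("pure fission perturbation shows up as fissions, never fusions", {
  sim <- simulate_truth(sim_params(n_groups = 10, n_species = 4,
                                   group_size_range = c(1L, 2L), rng_seed = 11))
  em <- list(p_fission = 1, p_fusion = 0, p_dropout = 0, p_relocate = 0)
  gs <- perturb_prediction(sim$truth, em, seed = 4)
  rep <- fusion_fission(gs, sim$truth)
  expect_identical(rep$aggregates$total_fusions, 0L)
  expect_gt(rep$aggregates$total_fissions, 0)
  # every group that split into two parts of size >= 2 yields a fission
  n_split <- sum(sapply(sim$truth$refogs, function(og) {
    parts <- sapply(gs$groups, function(g) length(intersect(g, og)))
    sum(parts > 0) == 2
  }))
  expect_gte(rep$aggregates$total_fissions, n_split)
  # fixed seed reproduces the perturbation
  expect_identical(perturb_prediction(sim$truth, em, seed = 4)$groups, gs$groups)
})

test_that("a method suite is reproducible and its methods differ", {
  sim <- simulate_truth(sim_params(n_groups = 12, n_species = 4, rng_seed = 21))
  suite <- make_method_suite(sim$truth, 4, seed = 22)
  expect_identical(sapply(suite, `[[`, "method_name"),
                   c("sim_m1", "sim_m2", "sim_m3", "sim_m4"))
  suite2 <- make_method_suite(sim$truth, 4, seed = 22)
  expect_identical(lapply(suite, `[[`, "groups"), lapply(suite2, `[[`, "groups"))
  jac <- sapply(2:4, function(k) {
    jaccard_index(ortholog_pairs(suite[[1]]), ortholog_pairs(suite[[k]]))
  })
  expect_true(all(jac < 1))
})

test_that("simulated studies survive a disk round trip through the readers", {
  sim <- simulate_truth(sim_params(n_groups = 5, n_species = 3,
                                   n_decoy_proteins = 3, rng_seed = 13))
  methods <- make_method_suite(sim$truth, 2, seed = 14)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, methods, dir)
  prot <- read_proteome_fasta(paths[["fasta"]])
  expect_identical(prot[order(names(prot))],
                   sim$proteome[order(names(sim$proteome))])
  refs <- read_reference_groups(paths[["refogs"]])
  expect_identical(group_keys(refs$refogs), group_keys(sim$truth$refogs))
  store <- suppressMessages(read_annotation_store(paths[["gaf"]],
                                                  paths[["ontology"]],
                                                  paths[["ec"]]))
  expect_setequal(store$go_annotations$term, sim$store$go_annotations$term)
  back <- read_group_sets(paths[["sim_m1"]], "sim_m1")[[1]]
  expect_identical(unclass(ortholog_pairs(back)),
                   unclass(ortholog_pairs(methods[[1]])))
})
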