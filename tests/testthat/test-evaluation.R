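test_that("pair expansion and Jaccard match hand counts and brute force", {
  g1 <- group_set("a", list(c("s|a", "s|b", "s|c")))
  expect_identical(length(unclass(ortholog_pairs(g1))), 3L)
  g2 <- group_set("b", list(c("s|a", "s|b"), c("s|c", "s|d")))
  expect_identical(length(unclass(ortholog_pairs(g2))), 2L)

  # worked example: {{a,b},{c,d}} vs {{a,b,c,d}} -> 2/6
  g3 <- group_set("c", list(c("s|a", "s|b", "s|c", "s|d")))
  expect_equal(jaccard_index(ortholog_pairs(g2), ortholog_pairs(g3)), 2 / 6)
  expect_equal(jaccard_index(ortholog_pairs(g2), ortholog_pairs(g2)), 1.0)
  g4 <- group_set("d", list(c("s|x", "s|y")))
  expect_equal(jaccard_index(ortholog_pairs(g2), ortholog_pairs(g4)), 0.0)
  expect_equal(jaccard_index(character(0), character(0)), 1.0)

  set.seed(121)
  for (rep in 1:40) {
    ga <- random_group_set("a", n = sample(10:40, 1), k = sample(2:8, 1))
    gb <- random_group_set("b", n = sample(10:40, 1), k = sample(2:8, 1))
    pa <- unclass(ortholog_pairs(ga)); pb <- unclass(ortholog_pairs(gb))
    expect_identical(pa, oracle_pairs(ga$groups))
    expect_identical(length(pa), as.integer(sum(sapply(lengths(ga$groups),
                                                       function(k) k * (k - 1) / 2))))
    want <- if (length(pa) + length(pb) == 0) 1 else
      length(intersect(pa, pb)) / length(union(pa, pb))
    expect_equal(jaccard_index(ortholog_pairs(ga), ortholog_pairs(gb)), want)
    expect_equal(jaccard_index(ortholog_pairs(gb), ortholog_pairs(ga)), want)
  }
})

test_that("identical-group counting is an exact set-equality scan", {
  ga <- group_set("a", list(c("s|a", "s|b", "s|c"), c("s|d", "s|e")))
  expect_identical(count_identical_groups(ga, ga), 2L)
  gb <- group_set("b", list(c("s|a", "s|b")))
  expect_identical(count_identical_groups(ga, gb), 0L)
  set.seed(122)
  for (rep in 1:20) {
    gx <- random_group_set("x", n = 20, k = 4)
    gy <- random_group_set("y", n = 20, k = 4)
    want <- sum(sapply(gx$groups, function(g) {
      any(sapply(gy$groups, function(h) setequal(g, h)))
    }))
    expect_identical(count_identical_groups(gx, gy), as.integer(want))
  }
})

test_that("fusion and fission counting follows the benchmark definitions", {
  toks <- protein_ref("s1", sprintf("r%02d", 1:20))
  refs <- reference_groups(list(R1 = toks[1:8]), universe = toks)
  # RefOG split across 3 predicted groups: 2 fissions
  pred <- group_set("p", list(toks[1:3], toks[4:6], toks[7:8]))
  rep1 <- fusion_fission(pred, refs)
  expect_identical(rep1$per_refog$fissions, 2L)
  expect_false(rep1$per_refog$fusion)
  expect_false(rep1$per_refog$accurate)

  # fusion boundary: >3 foreign proteins in the best-match group
  pred4 <- group_set("p", list(c(toks[1:8], toks[9:12])))  # 4 foreign
  expect_true(fusion_fission(pred4, refs)$per_refog$fusion)
  pred3 <- group_set("p", list(c(toks[1:8], toks[9:11])))  # 3 foreign
  expect_false(fusion_fission(pred3, refs)$per_refog$fusion)
  expect_true(fusion_fission(pred3, refs)$per_refog$accurate)

  # proteins outside the benchmark universe are ignored
  out <- protein_ref("zz", c("q1", "q2", "q3", "q4"))
  pred_out <- group_set("p", list(c(toks[1:8], out)))
  expect_false(fusion_fission(pred_out, refs)$per_refog$fusion)

  # perfect prediction: 100% accurate, no events
  refs2 <- reference_groups(list(R1 = toks[1:5], R2 = toks[6:9]),
                            universe = toks)
  perfect <- group_set("p", list(toks[1:5], toks[6:9]))
  agg <- fusion_fission(perfect, refs2)$aggregates
  expect_equal(agg$pct_accurate, 100)
  expect_identical(agg$total_fusions, 0L)
  expect_identical(agg$total_fissions, 0L)

  # merging everything: fusions everywhere, no fissions
  merged <- group_set("p", list(toks[1:20]))
  repm <- fusion_fission(merged, refs2)
  expect_identical(repm$per_refog$fissions, c(0L, 0L))
  expect_true(all(repm$per_refog$fusion))

  # an entirely unassigned RefOG is not accurate (coverage rule)
  refs3 <- reference_groups(list(R1 = toks[1:4], R2 = toks[5:8]),
                            universe = toks)
  partial <- group_set("p", list(toks[1:4]))
  repp <- fusion_fission(partial, refs3)
  expect_identical(repp$per_refog$accurate, c(TRUE, FALSE))
  expect_identical(repp$per_refog$fissions, c(0L, 0L))
  expect_error(fusion_fission(perfect, reference_groups(list())), "empty")
})

test_that("information content propagates to ancestors with the root at ic 0", {
  dag_lines <- c("c1\troot\tns", "c2\troot\tns", "d1\tc1\tns")
  dag_path <- withr::local_tempfile(lines = dag_lines)
  gaf_row <- function(p, t) paste("DB", p, "-", "", t, "ref", "IDA", "", "P",
                                  sep = "\t")
  # 10 annotations, 2 on d1 (descendant of c1), so p(c1) counts them
  ann <- c(mapply(gaf_row, paste0("x|p", 1:6), rep("c2", 6)),
           mapply(gaf_row, paste0("x|q", 1:2), rep("c1", 2)),
           mapply(gaf_row, paste0("x|r", 1:2), rep("d1", 2)))
  gaf_path <- withr::local_tempfile(lines = unname(ann))
  store <- suppressMessages(read_annotation_store(gaf_path, dag_path))
  tab <- ic_table(store, "ns")
  expect_equal(unname(tab$p["root"]), 1)
  expect_equal(unname(tab$ic["root"]), 0)
  expect_equal(unname(tab$p["d1"]), 0.2)
  expect_equal(unname(tab$ic["d1"]), -log(0.2), tolerance = 1e-9)
  expect_equal(unname(tab$p["c1"]), 0.4)   # own 2 + descendant 2
  # monotone along every edge
  for (ch in names(store$go_dag)) {
    for (pa in store$go_dag[[ch]]) {
      if (ch %in% names(tab$p) && pa %in% names(tab$p)) {
        expect_gte(tab$p[[pa]], tab$p[[ch]])
      }
    }
  }
  expect_error(ic_table(store, "nope"), "no annotations")
})

test_that("relevance similarity matches its closed forms and the ancestor oracle", {
  dag_path <- withr::local_tempfile(lines = c("c1\troot\tns", "c2\troot\tns",
                                              "d1\tc1\tns"))
  gaf_row <- function(p, t) paste("DB", p, "-", "", t, "ref", "IDA", "", "P",
                                  sep = "\t")
  ann <- c(mapply(gaf_row, paste0("x|p", 1:8), rep("c2", 8)),
           mapply(gaf_row, paste0("x|q", 1:2), rep("c1", 2)))
  gaf_path <- withr::local_tempfile(lines = unname(ann))
  store <- suppressMessages(read_annotation_store(gaf_path, dag_path))
  tab <- ic_table(store, "ns")
  # self-similarity: 1 * (1 - p); p(c1) = 0.2
  expect_equal(sim_rel("c1", "c1", tab), 0.8, tolerance = 1e-9)
  # only common ancestor is the root: 0
  expect_equal(sim_rel("c1", "c2", tab), 0)
  expect_equal(sim_rel("root", "root", tab), 0)

  set.seed(131)
  for (rep in 1:8) {
    dag <- random_dag(12)
    terms <- names(dag)
    prot <- protein_ref("x", sprintf("p%03d", 1:40))
    ann_terms <- sample(terms[-1], 40, replace = TRUE)
    store2 <- structure(list(
      go_dag = dag,
      go_namespace = setNames(rep("ns", length(dag)), names(dag)),
      go_annotations = data.frame(protein = prot, term = ann_terms,
                                  evidence = "IDA"),
      ec_annotations = data.frame(protein = character(0), ec = character(0))),
      class = "annotation_store")
    tab2 <- ic_table(store2, "ns")
    present <- names(tab2$p)
    for (k in 1:25) {
      cc <- sample(present, 2, replace = TRUE)
      expect_equal(sim_rel(cc[1], cc[2], tab2),
                   oracle_sim_rel(cc[1], cc[2], tab2, dag), tolerance = 1e-12)
      v <- sim_rel(cc[1], cc[2], tab2)
      expect_gte(v, 0); expect_lte(v, 1)
    }
  }
})

test_that("pair similarity skips unannotated proteins and handles EC trees", {
  # EC corpus: 1.1.1.1 unique among 4 annotations -> self-similarity 0.75
  store <- structure(list(
    go_dag = list(), go_namespace = character(0),
    go_annotations = data.frame(protein = character(0), term = character(0),
                                evidence = character(0)),
    ec_annotations = data.frame(
      protein = protein_ref("x", c("p1", "p2", "p3", "p4")),
      ec = c("1.1.1.1", "1.1.1.1", "2.1.1.1", "3.1.1.1"))),
    class = "annotation_store")
  # corpus of 4 rows with 1.1.1.1 appearing twice: p = 0.5
  expect_equal(pair_functional_similarity("x|p1", "x|p2", store, mode = "EC"),
               0.5, tolerance = 1e-9)
  # term-level: an EC unique in a corpus of 4 scores 1 - 1/4 against itself
  store_u <- store
  store_u$ec_annotations$ec <- c("1.1.1.1", "2.1.1.1", "3.1.1.1", "4.1.1.1")
  tab_u <- ic_table(store_u, "EC")
  expect_equal(sim_rel("1.1.1.1", "1.1.1.1", tab_u), 0.75, tolerance = 1e-9)
  # unannotated partner: skipped, not zero
  expect_true(is.na(pair_functional_similarity("x|p1", "x|nope", store,
                                               mode = "EC")))
  # wildcard ECs annotate internal nodes
  store$ec_annotations$ec[4] <- "3.1.-.-"
  ctx <- similarity_context(store, "EC")
  expect_true("3.1" %in% names(ctx$tabs$EC$p))

  # GO identical single-term sets reduce to self-similarity
  dag_path <- withr::local_tempfile(lines = c("c1\troot\tns", "c2\troot\tns"))
  gaf_row <- function(p, t) paste("DB", p, "-", "", t, "ref", "IDA", "", "P",
                                  sep = "\t")
  ann <- c(mapply(gaf_row, paste0("x|p", 1:2), rep("c1", 2)),
           mapply(gaf_row, paste0("x|q", 1:8), rep("c2", 8)))
  gaf_path <- withr::local_tempfile(lines = unname(ann))
  store2 <- suppressMessages(read_annotation_store(gaf_path, dag_path))
  expect_equal(pair_functional_similarity("x|p1", "x|p2", store2, mode = "GO"),
               0.8, tolerance = 1e-9)
})

test_that("the conservation benchmark counts annotated pairs only", {
  toks <- protein_ref("x", paste0("p", 1:6))
  gs <- group_set("m", list(toks[1:4], toks[5:6]))
  store <- structure(list(
    go_dag = list(), go_namespace = character(0),
    go_annotations = data.frame(protein = character(0), term = character(0),
                                evidence = character(0)),
    ec_annotations = data.frame(protein = toks[1:3], ec = "1.1.1.1")),
    class = "annotation_store")
  r <- function_benchmark(gs, store, "EC")
  expect_identical(r$n_annotated_pairs, 3L)  # pairs among p1..p3 only
  # identical annotation sets: mean = 1 - p(term) with p = 1 here -> 0
  expect_equal(r$mean_similarity, 0)
  # no annotations at all
  store0 <- store
  store0$ec_annotations <- store0$ec_annotations[0, ]
  r0 <- function_benchmark(gs, store0, "EC")
  expect_identical(r0$n_annotated_pairs, 0L)
  expect_true(is.na(r0$mean_similarity))
  # splitting a group reduces the pair count, not the per-pair scores
  gs2 <- group_set("m", list(toks[1:2], toks[3:4], toks[5:6]))
  r2 <- function_benchmark(gs2, store, "EC")
  expect_lt(r2$n_annotated_pairs, r$n_annotated_pairs)
})

test_that("the parameter sweep tabulates the full grid deterministically", {
  fx <- smoke_fixture()
  refs <- reference_groups(fx$expected$final_members |>
                             setNames(c("R1", "R2")),
                           universe = names(fx$proteome))
  grid <- list(evalue = c(1e-10, 1e-5), coverage = c(0.4, 0.8), min_size = 4L)
  tab <- parameter_sweep(fx$groupsets, fx$proteome, refs, grid, seed = 42)
  expect_identical(nrow(tab), 4L)
  expect_setequal(tab$evalue, c(1e-10, 1e-5))
  expect_true(all(tab$min_size == 4L))
  # duplicated grid point gives an identical row
  grid2 <- list(evalue = c(1e-10, 1e-10), coverage = 0.4, min_size = 4L)
  tab2 <- parameter_sweep(fx$groupsets, fx$proteome, refs, grid2, seed = 42)
  r1 <- tab2[1, -1]; r2 <- tab2[2, -1]
  rownames(r1) <- rownames(r2) <- NULL
  expect_identical(r1, r2)
  expect_identical(tab2$pct_accurate[1], tab2$pct_accurate[2])
  # the smoke consensus recovers both reference groups at defaults
  expect_equal(tab$pct_accurate[tab$evalue == 1e-10 & tab$coverage == 0.4], 100)
})
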