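test_that("ingroup monophyly reads the topology under the clade root", {
  # focal leaves form one clade nested among outgroups -> monophyletic
  at1 <- ann("((q,s1)1.0,(o1,(o2,o3)1.0)1.0);",
             c(q = "query", s1 = "sister",
               o1 = "outgroup:Bacteria", o2 = "outgroup:Bacteria",
               o3 = "outgroup:Bacteria"))
  root1 <- length(at1$tree$tip.label) + 1L
  expect_true(is_ingroup_monophyletic(at1, root1))

  # focal leaves split across the clade -> not monophyletic
  at2 <- ann("((q,o1)1.0,(s1,(o2,o3)1.0)1.0);",
             c(q = "query", s1 = "sister",
               o1 = "outgroup:Bacteria", o2 = "outgroup:Bacteria",
               o3 = "outgroup:Bacteria"))
  expect_false(is_ingroup_monophyletic(at2, length(at2$tree$tip.label) + 1L))

  # a singleton focal leaf is trivially monophyletic
  at3 <- ann("(q,(o1,o2,o3)1.0);",
             c(q = "query", o1 = "outgroup:Bacteria",
               o2 = "outgroup:Bacteria", o3 = "outgroup:Bacteria"))
  expect_true(is_ingroup_monophyletic(at3, length(at3$tree$tip.label) + 1L))

  # undefined without outgroup leaves in the clade
  at4 <- ann("(q,(s1,s2)1.0);", c(q = "query", s1 = "sister", s2 = "sister"))
  expect_error(is_ingroup_monophyletic(at4, length(at4$tree$tip.label) + 1L),
               "no outgroup")
})

test_that("monophyly is invariant to branch lengths and child order", {
  base <- c(q = "query", s1 = "sister",
            o1 = "outgroup:Bacteria", o2 = "outgroup:Bacteria",
            o3 = "outgroup:Bacteria")
  shapes <- c("((q:9,s1:0.01)1.0:5,(o1:2,(o2:1,o3:4)1.0:1)1.0:0.1);",
              "(((o3,o2)1.0,o1)1.0,(s1,q)1.0);")
  vals <- vapply(shapes, function(nwk) {
    at <- ann(nwk, base)
    is_ingroup_monophyletic(at, length(at$tree$tip.label) + 1L)
  }, logical(1))
  expect_true(all(vals))
})

test_that("direction is acceptor exactly when the stopping clade is ingroup-monophyletic", {
  r <- walk_query(example_hgt_tree(), "q1")
  expect_identical(infer_direction(r), "acceptor")

  # paraphyletic focal placement: q and s1 separated by outgroups inside the
  # stopping clade
  at <- ann("(((q1:1,o1:1)1.0:1,(s1:1,(o2:1,o3:1)1.0:1)1.0:1)1.0:1,(x1:1,x2:1)1.0:1);",
            c(q1 = "query", s1 = "sister",
              o1 = "outgroup:Stramenopila", o2 = "outgroup:Stramenopila",
              o3 = "outgroup:Stramenopila",
              x1 = "outgroup:Alveolata", x2 = "outgroup:Alveolata"))
  r2 <- walk_query(at, "q1")
  expect_true(r2$category %in% c("ancestral_hgt", "single_hgt", "multi_hgt"))
  expect_identical(infer_direction(r2), "unresolved")

  r_anc <- walk_query(ann("((q,(s1,s2)1.0)1.0,((s3,s4)1.0,s5)1.0);",
                          c(q = "query", s1 = "sister", s2 = "sister",
                            s3 = "sister", s4 = "sister", s5 = "sister")), "q")
  expect_identical(r_anc$category, "ancestral")
  expect_error(infer_direction(r_anc), "HGT categories")
})

test_that("events group queries by stopping clade and conserve genes", {
  # two queries in the same transferred clade -> one event with two genes
  at <- ann("(((q1,q2)1.0,(o1,o2,o3)1.0)1.0,(x1,x2)1.0);",
            c(q1 = "query", q2 = "query",
              o1 = "outgroup:Stramenopila", o2 = "outgroup:Stramenopila",
              o3 = "outgroup:Stramenopila",
              x1 = "outgroup:Alveolata", x2 = "outgroup:Alveolata"))
  ev <- aggregate_events(classify_tree(at))
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$n_genes, 2L)
  expect_identical(ev$gene_ids, "q1,q2")
  expect_identical(ev$direction, "acceptor")

  # three queries, two sharing a clade -> two events totaling three genes
  at2 <- ann(paste0("((((q1,q2)1.0,(o1,o2,o3)1.0)1.0,((q3,(y1,(y2,y3)1.0)1.0))1.0)1.0,",
                    "(x1,x2)1.0);"),
             c(q1 = "query", q2 = "query", q3 = "query",
               o1 = "outgroup:Stramenopila", o2 = "outgroup:Stramenopila",
               o3 = "outgroup:Stramenopila",
               y1 = "outgroup:Opisthokonta", y2 = "outgroup:Opisthokonta",
               y3 = "outgroup:Opisthokonta",
               x1 = "outgroup:Alveolata", x2 = "outgroup:Alveolata"))
  res2 <- classify_tree(at2)
  ev2 <- aggregate_events(res2)
  expect_identical(nrow(ev2), 2L)
  expect_identical(sum(ev2$n_genes), 3L)
  n_hgt_calls <- sum(vapply(res2, `[[`, character(1), "category") %in%
                       c("ancestral_hgt", "single_hgt", "multi_hgt"))
  expect_identical(sum(ev2$n_genes), n_hgt_calls)
})

test_that("gene conservation and events <= genes hold on a simulated corpus", {
  co <- simulate_corpus(default_mixture(6), seed = 99)
  sc <- classify_corpus(co)
  n_hgt_calls <- sum(sc$calls$category %in%
                       c("ancestral_hgt", "single_hgt", "multi_hgt"))
  expect_identical(sum(sc$events$n_genes), n_hgt_calls)
  expect_lte(nrow(sc$events), sum(sc$events$n_genes))
  # per-orthogroup conservation
  for (og in unique(sc$events$og_id)) {
    calls_og <- sc$calls[sc$calls$og_id == og, ]
    expect_identical(sum(sc$events$n_genes[sc$events$og_id == og]),
                     sum(calls_og$category %in%
                           c("ancestral_hgt", "single_hgt", "multi_hgt")))
  }
})

test_that("mixed-orthogroup aggregation is refused", {
  r1 <- classify_tree(example_hgt_tree())
  at2 <- example_hgt_tree()
  at2$og_id <- "OG2"
  r2 <- classify_tree(at2)
  mixed <- c(unclass(r1), unclass(r2))
  attr(mixed, "tree") <- attr(r1, "tree")
  class(mixed) <- "walk_result_list"
  expect_error(aggregate_events(mixed), "mixed orthogroups")
})

test_that("planted acceptor scenarios are recovered as acceptor on clean trees", {
  for (scen in c("ancient_hgt", "recent_hgt_single", "recent_hgt_multi")) {
    for (s in 1:5) {
      sim <- simulate_tree(scenario_spec(scen, seed = s), og_id = "OGD")
      res <- classify_tree(sim$tree)
      expect_identical(infer_direction(res[[1]], attr(res, "tree")), "acceptor",
                       label = sprintf("%s seed %d", scen, s))
    }
  }
})
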