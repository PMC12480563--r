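test_that("farthest-leaf rooting picks the leaf with maximal path length from the query", {
  at <- ann("(((q:1,a:1):1,b:1):1,c:1);",
            c(q = "query", a = "sister", b = "sister", c = "outgroup:Bacteria"))
  rt <- root_tree(at, "farthest_leaf")
  phy <- rt$tree
  root_kids <- phy$edge[phy$edge[, 1] == length(phy$tip.label) + 1L, 2]
  # c is the unique farthest leaf (path length 3 from q vs 2 for a and b)
  expect_true(match("c", phy$tip.label) %in% root_kids)
})

test_that("farthest-leaf ties break lexicographically", {
  at <- ann("((q:1,a:1):1,(zz:1,aa:1):1);",
            c(q = "query", a = "sister", zz = "outgroup:Bacteria",
              aa = "outgroup:Bacteria"))
  rt <- root_tree(at, "farthest_leaf")
  phy <- rt$tree
  root_kids <- phy$edge[phy$edge[, 1] == length(phy$tip.label) + 1L, 2]
  expect_true(match("aa", phy$tip.label) %in% root_kids)
})

test_that("midpoint rooting splits the longest leaf-to-leaf path", {
  at <- ann("(A:1,B:1);", c(A = "query", B = "sister"))
  rt <- root_tree(at, "midpoint")
  d <- ape::dist.nodes(rt$tree)
  n <- length(rt$tree$tip.label)
  expect_equal(unname(d[1, n + 1]), 1, tolerance = 1e-9)
  expect_equal(unname(d[2, n + 1]), 1, tolerance = 1e-9)
})

test_that("as_is rooting refuses an unrooted tree", {
  at <- ann("(a,b,q);", c(a = "sister", b = "sister", q = "query"))
  expect_error(root_tree(at, "as_is"), "unrooted")
})

test_that("re-rooting preserves supports on the bipartitions they describe", {
  set.seed(7)
  for (rep in 1:5) {
    sim <- simulate_tree(scenario_spec("ancient_hgt", n_leaves = 15,
                                       support_model = list(type = "beta", shape1 = 8, shape2 = 2),
                                       seed = rep), og_id = "OGB")
    before <- bipartition_supports(sim$tree$tree)
    after <- bipartition_supports(root_tree(sim$tree, "farthest_leaf")$tree)
    shared <- intersect(names(before), names(after))
    expect_gt(length(shared), 0)
    expect_identical(before[shared], after[shared])
  }
})

test_that("collapse contracts edges at or below the threshold and is idempotent", {
  at_low <- ann("((A,B)0.5:1,C);", c(A = "query", B = "sister", C = "sister"))
  col <- collapse_low_support(at_low)
  expect_identical(col$tree$Nnode, 1L)  # star

  at_high <- ann("((A,B)0.95:1,C);", c(A = "query", B = "sister", C = "sister"))
  col2 <- collapse_low_support(at_high)
  expect_identical(col2$tree$Nnode, 2L)  # unchanged

  # boundary: strictly greater means 0.85 itself collapses
  at_eq <- ann("((A,B)0.85:1,C);", c(A = "query", B = "sister", C = "sister"))
  expect_identical(collapse_low_support(at_eq)$tree$Nnode, 1L)

  set.seed(11)
  for (rep in 1:5) {
    sim <- simulate_tree(scenario_spec("vertical",
                                       support_model = list(type = "beta", shape1 = 2, shape2 = 2),
                                       seed = rep), og_id = "OGC")
    once <- collapse_low_support(root_tree(sim$tree))
    twice <- collapse_low_support(once)
    expect_identical(ape::write.tree(twice$tree), ape::write.tree(once$tree))
    # absent-support edges are never contracted
    expect_true(all(is.na(node_supports(once$tree)) |
                      node_supports(once$tree) > 0.85))
  }
})

test_that("nested_clades returns cumulative counts from parent to root", {
  at <- ann("(((q,s1)1.0,(o1,o2,o3)1.0)1.0,(s2,s3)1.0);",
            c(q = "query", s1 = "sister", s2 = "sister", s3 = "sister",
              o1 = "outgroup:Stramenopila", o2 = "outgroup:Stramenopila",
              o3 = "outgroup:Stramenopila"))
  tr <- nested_clades(root_tree(at, "as_is"), "q")
  expect_length(tr, 3L)
  expect_identical(vapply(tr, `[[`, integer(1), "n_sister"), c(1L, 1L, 3L))
  expect_identical(vapply(tr, function(x) sum(x$outgroup), integer(1)),
                   c(0L, 3L, 3L))
  expect_setequal(tr[[1]]$leaves, c("q", "s1"))
  expect_error(nested_clades(root_tree(at, "as_is"), "nope"), "not found")
})

test_that("a star tree yields a single trace entry covering all leaves", {
  at <- ann("(q,a,b);", c(q = "query", a = "sister", b = "sister"))
  expect_error(root_tree(at, "as_is"), "unrooted")
  tr <- nested_clades(at, "q")
  expect_length(tr, 1L)
  expect_setequal(tr[[1]]$leaves, c("q", "a", "b"))
})

test_that("trace counts are component-wise non-decreasing on random trees", {
  set.seed(3)
  for (rep in 1:10) {
    inst <- rand_oracle_instance(sample(6:12, 1))
    q <- names(inst$roles)[inst$roles == "query"][1]
    tr <- nested_clades(collapse_low_support(inst), q)
    mat <- t(vapply(tr, function(x)
      c(x$n_query, x$n_ingroup, x$n_sister, sum(x$outgroup)), numeric(4)))
    if (nrow(mat) > 1) expect_true(all(diff(mat) >= 0))
  }
})

test_that("classify_counts applies the stopping criteria with the documented precedence", {
  p <- walk_params()
  expect_identical(
    classify_counts(list(clade_counts(n_sister = 5)), p),
    list(category = "ancestral", stop_index = 1L))
  expect_identical(
    classify_counts(list(clade_counts(n_sister = 1),
                         clade_counts(n_sister = 1, outgroup = c(Stramenopila = 3L))), p),
    list(category = "ancestral_hgt", stop_index = 2L))
  expect_identical(
    classify_counts(list(clade_counts(outgroup = c(Stramenopila = 3L, Alveolata = 3L))), p)$category,
    "multi_hgt")
  expect_identical(
    classify_counts(list(clade_counts(n_query = 2, n_ingroup = 3)), p)$category,
    "ingroup_only")
  # precedence: enough sisters beats a qualifying outgroup lineage
  expect_identical(
    classify_counts(list(clade_counts(n_sister = 5, outgroup = c(Opisthokonta = 3L))), p)$category,
    "ancestral")
  # mixed composition that never fires ends undetermined
  expect_identical(
    classify_counts(list(clade_counts(n_sister = 1, outgroup = c(Stramenopila = 1L))), p)$category,
    "undetermined")
  expect_error(
    classify_counts(list(clade_counts(n_sister = 3), clade_counts(n_sister = 1)), p),
    "cumulative")
})

test_that("walk_query matches hand-traced calls on the worked examples", {
  at <- example_hgt_tree()
  r1 <- walk_query(at, "q1")
  expect_identical(r1$category, "ancestral_hgt")
  expect_setequal(r1$stop$leaves, c("q1", "s1", "o1", "o2", "o3"))
  expect_identical(r1$donor_lineages, "Stramenopila")

  # relabeling the sister as a 4th Stramenopila makes it single-HGT
  at2 <- example_hgt_tree(sister_role = "outgroup:Stramenopila")
  r2 <- walk_query(at2, "q1")
  expect_identical(r2$category, "single_hgt")
  expect_identical(r2$donor_lineages, "Stramenopila")

  # with every internal support at 0.5 the tree collapses to a star and the
  # whole-tree composition decides in one step
  at3 <- ann("(((q1:1,s1:1)0.5:1,(o1:1,o2:1,o3:1)0.5:1)0.5:1,(x1:1,x2:1)0.5:1);",
             c(q1 = "query", s1 = "sister",
               o1 = "outgroup:Stramenopila", o2 = "outgroup:Stramenopila",
               o3 = "outgroup:Stramenopila",
               x1 = "outgroup:Alveolata", x2 = "outgroup:Alveolata"))
  r3 <- walk_query(at3, "q1")
  # rooted on the farthest leaf x1, everything else collapses to one polytomy
  expect_identical(r3$trace_depth, 2L)
  expect_identical(r3$category, "ancestral_hgt")  # 1 sister + 3 Stramenopila
  expect_setequal(r3$stop$leaves, setdiff(names(at3$roles), "x1"))
})

test_that("classify_tree walks every query deterministically", {
  at <- ann("(((q2,q1)1.0,(o1,o2,o3)1.0)1.0,(x1,x2)1.0);",
            c(q1 = "query", q2 = "query",
              o1 = "outgroup:Stramenopila", o2 = "outgroup:Stramenopila",
              o3 = "outgroup:Stramenopila",
              x1 = "outgroup:Alveolata", x2 = "outgroup:Alveolata"))
  res <- classify_tree(at)
  expect_length(res, 2L)
  expect_identical(vapply(res, `[[`, character(1), "query"), c("q1", "q2"))
  expect_identical(res[[1]]$category, res[[2]]$category)
  expect_setequal(res[[1]]$stop$leaves, res[[2]]$stop$leaves)
  tab <- walk_results_table(res)
  expect_identical(nrow(tab), 2L)
})

test_that("walk results are invariant to child order in the newick text", {
  r1 <- walk_query(example_hgt_tree(), "q1")
  at_rot <- ann("((x2:1,x1:1)1.0:1,((o3:1,o1:1,o2:1)1.0:1,(s1:1,q1:1)1.0:1)1.0:1);",
                c(q1 = "query", s1 = "sister",
                  o1 = "outgroup:Stramenopila", o2 = "outgroup:Stramenopila",
                  o3 = "outgroup:Stramenopila",
                  x1 = "outgroup:Alveolata", x2 = "outgroup:Alveolata"))
  r2 <- walk_query(at_rot, "q1")
  expect_identical(r1$category, r2$category)
  expect_identical(sort(r1$stop$leaves), sort(r2$stop$leaves))
  expect_identical(r1$donor_lineages, r2$donor_lineages)
})

test_that("with threshold 0 and full resolution the trace spans the query's root distance", {
  at <- ann("((((q:1,a:1)0.9:1,b:1)0.9:1,c:1)0.9:1,d:1);",
            c(q = "query", a = "sister", b = "sister", c = "sister",
              d = "outgroup:Bacteria"))
  p0 <- walk_params(support_threshold = 0, min_sisters = 99)
  r <- walk_query(at, "q", p0)
  # rooted on d (farthest): ancestors = 4 internal nodes
  expect_identical(r$trace_depth, 4L)
  # raising the threshold can only shorten the trace
  p85 <- walk_params(min_sisters = 99)
  expect_lte(walk_query(at, "q", p85)$trace_depth, r$trace_depth)
})
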