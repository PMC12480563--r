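## Synthetic gene trees with planted evolutionary scenarios and known truth.

.DEFAULT_LINEAGES <- c("Stramenopila", "Alveolata", "Opisthokonta",
                       "Viridiplantae", "Rhizaria", "Bacteria", "Viruses")

.SCENARIOS <- c("vertical", "ancient_hgt", "recent_hgt_single",
                "recent_hgt_multi", "ingroup_only")

.SCENARIO_CATEGORY <- c(vertical = "ancestral",
                        ancient_hgt = "ancestral_hgt",
                        recent_hgt_single = "single_hgt",
                        recent_hgt_multi = "multi_hgt",
                        ingroup_only = "ingroup_only")

## Run code under a fixed seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a planted gene-tree scenario
#'
#' Each scenario plants the defining structure of one classification
#' category into an otherwise random tree:
#' \describe{
#'   \item{vertical}{the focal clade is nested inside a clade of at least
#'     `min_sisters` sister leaves (expected call: `ancestral`).}
#'   \item{ancient_hgt}{the focal + sister clade (with fewer than
#'     `min_sisters` sisters) is nested inside a clade of donor-lineage
#'     outgroup leaves.}
#'   \item{recent_hgt_single}{the focal clade is nested inside a pure
#'     donor-lineage clade; the tree holds no sister leaves at all.}
#'   \item{recent_hgt_multi}{as single, but the enclosing clade mixes two or
#'     more donor lineages (minority-lineage leaves branch closest to the
#'     focal clade so that no pure-lineage sub-clade fires first).}
#'   \item{ingroup_only}{every leaf is query or ingroup.}
#' }
#' HGT scenarios plant the focal leaves as one contiguous clade inside the
#' donor clade, so the planted direction is always `acceptor`.
#'
#' @param scenario One of `"vertical"`, `"ancient_hgt"`,
#'   `"recent_hgt_single"`, `"recent_hgt_multi"`, `"ingroup_only"`.
#' @param n_leaves Total leaves (>= 4); leaves not used by the planted
#'   structure become random-lineage outgroup backbone.
#' @param donor_lineages Donor lineage(s) for HGT scenarios; the first entry
#'   is the majority donor for `recent_hgt_multi`.
#' @param n_donor Donor leaves per donor lineage.
#' @param n_query,n_ingroup,n_sisters Focal composition; `n_sisters` must be
#'   0 for recent-HGT scenarios, between 1 and `min_sisters - 1` for
#'   `ancient_hgt`, and at least `min_sisters` for `vertical`.
#' @param support_model `"ones"` (point mass at 1.0) or
#'   `list(type = "beta", shape1 =, shape2 =)` for i.i.d. Beta supports per
#'   internal edge.
#' @param noise Leaf-label noise rate in `[0, 1)`: each leaf's role/lineage
#'   is redrawn uniformly from the other options with this probability.
#' @param seed Integer seed; the same spec and seed give byte-identical
#'   output.
#' @param lineages Major-lineage vocabulary.
#' @param min_sisters,min_outgroup_per_lineage Classifier thresholds the
#'   scenario is validated against.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario,
                          n_leaves = 40L,
                          donor_lineages = NULL,
                          n_donor = NULL,
                          n_query = 2L,
                          n_ingroup = 2L,
                          n_sisters = NULL,
                          support_model = "ones",
                          noise = 0,
                          seed = 1L,
                          lineages = .DEFAULT_LINEAGES,
                          min_sisters = 5L,
                          min_outgroup_per_lineage = 3L) {
  scenario <- match.arg(scenario, .SCENARIOS)
  if (is.null(n_sisters))
    n_sisters <- switch(scenario, vertical = min_sisters + 1L,
                        ancient_hgt = 2L, 0L)
  if (is.null(donor_lineages))
    donor_lineages <- switch(scenario,
                             ancient_hgt = lineages[1L],
                             recent_hgt_single = lineages[1L],
                             recent_hgt_multi = lineages[1:2],
                             character(0))
  if (is.null(n_donor))
    n_donor <- switch(scenario,
                      ancient_hgt = min_outgroup_per_lineage + 1L,
                      recent_hgt_single = min_outgroup_per_lineage + 1L,
                      recent_hgt_multi = c(min_outgroup_per_lineage, 2L),
                      integer(0))
  n_leaves <- as.integer(n_leaves); n_query <- as.integer(n_query)
  n_ingroup <- as.integer(n_ingroup); n_sisters <- as.integer(n_sisters)
  n_donor <- as.integer(n_donor)
  if (n_leaves < 4L) stop("n_leaves must be at least 4")
  if (n_query < 1L) stop("n_query must be at least 1")
  if (noise < 0 || noise >= 1) stop("noise must be in [0, 1)")
  if (!all(donor_lineages %in% lineages))
    stop("donor lineages must belong to the lineage vocabulary")
  if (length(n_donor) != length(donor_lineages))
    stop("n_donor must match donor_lineages")
  switch(scenario,
    vertical = if (n_sisters < min_sisters)
      stop("vertical requires n_sisters >= min_sisters"),
    ancient_hgt = {
      if (n_sisters < 1L || n_sisters >= min_sisters)
        stop("ancient_hgt requires 1 <= n_sisters < min_sisters")
      if (length(donor_lineages) != 1L || n_donor < min_outgroup_per_lineage)
        stop("ancient_hgt requires one donor lineage with >= min_outgroup_per_lineage leaves")
    },
    recent_hgt_single = {
      if (n_sisters != 0L) stop("recent_hgt_single requires n_sisters = 0")
      if (length(donor_lineages) != 1L || n_donor < min_outgroup_per_lineage)
        stop("recent_hgt_single requires one donor lineage with >= min_outgroup_per_lineage leaves")
    },
    recent_hgt_multi = {
      if (n_sisters != 0L) stop("recent_hgt_multi requires n_sisters = 0")
      if (length(donor_lineages) < 2L)
        stop("recent_hgt_multi requires at least two donor lineages")
      if (n_donor[1L] < min_outgroup_per_lineage)
        stop("the first (majority) donor lineage needs >= min_outgroup_per_lineage leaves")
      if (any(n_donor[-1L] < 1L) || any(n_donor[-1L] >= min_outgroup_per_lineage))
        stop("minority donor lineages need between 1 and min_outgroup_per_lineage - 1 leaves")
    },
    ingroup_only = {
      if (n_sisters != 0L || length(donor_lineages))
        stop("ingroup_only admits no sister or donor leaves")
    })
  core <- n_query + n_ingroup + n_sisters + sum(n_donor)
  anchor <- if (scenario == "ingroup_only") 0L else 1L
  if (n_leaves < core + anchor)
    stop(sprintf("n_leaves = %d too small for the planted structure (%d leaves + %d anchor)",
                 n_leaves, core, anchor))
  if (is.character(support_model)) {
    support_model <- match.arg(support_model, "ones")
    support_model <- list(type = "ones")
  } else {
    stopifnot(is.list(support_model), identical(support_model$type, "beta"),
              support_model$shape1 > 0, support_model$shape2 > 0)
  }
  structure(list(scenario = scenario, n_leaves = n_leaves,
                 donor_lineages = donor_lineages, n_donor = n_donor,
                 n_query = n_query, n_ingroup = n_ingroup,
                 n_sisters = n_sisters, support_model = support_model,
                 noise = noise, seed = as.integer(seed), lineages = lineages,
                 min_sisters = as.integer(min_sisters),
                 min_outgroup_per_lineage = as.integer(min_outgroup_per_lineage)),
            class = "scenario_spec")
}

## ---- topology construction ---------------------------------------------

.leaf_unit <- function(nm) list(leaf = nm)

## Yule-type random joins: repeatedly pick two units uniformly and join.
.random_join <- function(units) {
  while (length(units) > 1L) {
    k <- sample.int(length(units), 2L)
    merged <- list(children = units[k])
    units <- c(units[-k], list(merged))
  }
  units[[1L]]
}

.to_newick <- function(node) {
  if (!is.null(node$leaf)) return(node$leaf)
  paste0("(", paste(vapply(node$children, .to_newick, character(1)),
                    collapse = ","), ")")
}

#' Simulate one gene tree with a planted scenario
#'
#' Grows a random bifurcating topology by seeded random joins, plants the
#' scenario structure (see [scenario_spec()]), draws branch lengths
#' i.i.d. Exp(1), draws supports from the scenario's support model, then applies
#' leaf-label noise. For scenarios other than `ingroup_only` one backbone
#' outgroup leaf is a distal rooting anchor: its terminal branch is extended
#' beyond the longest query-to-leaf path (emulating a distant homolog), so
#' farthest-leaf rooting always falls outside the planted clade and the
#' planted call is recoverable by construction.
#'
#' @param spec A `scenario_spec`.
#' @param og_id Orthogroup id; leaf names are prefixed with it.
#' @return List with elements `tree` (an `annotated_gene_tree`) and `truth`
#'   (one-row data frame: og_id, scenario, category, donor_lineages,
#'   direction, query_ids).
#' @export
simulate_tree <- function(spec, og_id = "OG1") {
  stopifnot(inherits(spec, "scenario_spec"))
  .with_seed(spec$seed, .simulate_tree_impl(spec, og_id))
}

.simulate_tree_impl <- function(spec, og_id) {
  pre <- paste0(og_id, "_")
  vocab <- spec$lineages
  q <- paste0(pre, "q", seq_len(spec$n_query))
  scen <- spec$scenario

  if (scen == "ingroup_only") {
    ing <- paste0(pre, "ing", seq_len(spec$n_leaves - spec$n_query))
    leaves <- c(q, ing)
    roles <- stats::setNames(c(rep("query", length(q)), rep("ingroup", length(ing))), leaves)
    lins <- stats::setNames(rep(NA_character_, length(leaves)), leaves)
    topo <- .random_join(lapply(leaves, .leaf_unit))
    anchor_name <- NULL
  } else {
    ing <- if (spec$n_ingroup) paste0(pre, "ing", seq_len(spec$n_ingroup)) else character(0)
    sis <- if (spec$n_sisters) paste0(pre, "sis", seq_len(spec$n_sisters)) else character(0)
    donors <- unlist(lapply(seq_along(spec$donor_lineages), function(i)
      paste0(pre, "d", i, "_", seq_len(spec$n_donor[i]))), use.names = FALSE)
    donor_lin <- rep(spec$donor_lineages, spec$n_donor)
    n_back <- spec$n_leaves - spec$n_query - length(ing) - length(sis) -
      length(donors) - 1L
    back <- if (n_back > 0L) paste0(pre, "bg", seq_len(n_back)) else character(0)
    anchor_name <- paste0(pre, "anchor")
    back_lin <- sample(vocab, n_back + 1L, replace = TRUE)

    leaves <- c(q, ing, sis, donors, back, anchor_name)
    roles <- stats::setNames(c(rep("query", length(q)),
                               rep("ingroup", length(ing)),
                               rep("sister", length(sis)),
                               rep("outgroup", length(donors)),
                               rep("outgroup", n_back + 1L)), leaves)
    lins <- stats::setNames(c(rep(NA_character_, length(q) + length(ing) + length(sis)),
                              donor_lin, back_lin), leaves)

    focal <- .random_join(lapply(c(q, ing), .leaf_unit))
    planted <- switch(scen,
      vertical = .random_join(c(list(focal), lapply(sis, .leaf_unit))),
      ancient_hgt = {
        inner <- .random_join(c(list(focal), lapply(sis, .leaf_unit)))
        .random_join(c(list(inner), lapply(donors, .leaf_unit)))
      },
      recent_hgt_single = .random_join(c(list(focal), lapply(donors, .leaf_unit))),
      recent_hgt_multi = {
        minority <- donors[donor_lin != spec$donor_lineages[1L]]
        major <- donors[donor_lin == spec$donor_lineages[1L]]
        inner <- .random_join(c(list(focal), lapply(minority, .leaf_unit)))
        .random_join(c(list(inner), lapply(major, .leaf_unit)))
      })
    topo <- .random_join(c(list(planted), lapply(c(back, anchor_name), .leaf_unit)))
  }

  phy <- ape::read.tree(text = paste0(.to_newick(topo), ";"))
  phy$edge.length <- rexp(nrow(phy$edge))
  nn <- phy$Nnode
  sup <- if (identical(spec$support_model$type, "ones")) rep(1, nn - 1L)
         else round(rbeta(nn - 1L, spec$support_model$shape1, spec$support_model$shape2), 4)
  phy$node.label <- c(NA_real_, sup)  # root support absent
  ## both root-child edges describe the same bipartition of a binary-rooted
  ## tree; give them one support so the tree is self-consistent under
  ## re-rooting
  root_kids <- phy$edge[phy$edge[, 1L] == length(phy$tip.label) + 1L, 2L]
  root_kids <- root_kids[root_kids > length(phy$tip.label)] - length(phy$tip.label)
  if (length(root_kids) == 2L)
    phy$node.label[root_kids[2L]] <- phy$node.label[root_kids[1L]]
  class(phy) <- c("gene_tree", "phylo")

  if (!is.null(anchor_name)) {
    d <- .tip_distances(phy, sort(q)[1L])
    others <- setdiff(names(d), c(sort(q)[1L], anchor_name))
    gap <- max(d[others]) - d[anchor_name]
    irow <- which(phy$edge[, 2L] == match(anchor_name, phy$tip.label))
    phy$edge.length[irow] <- phy$edge.length[irow] + max(0, gap) + rexp(1)
  }

  ## label noise: redraw role/lineage jointly from the other options
  options_all <- c("query", "ingroup", "sister", paste0("outgroup:", vocab))
  flip <- runif(length(leaves)) < spec$noise
  for (i in which(flip)) {
    nm <- leaves[i]
    cur <- if (roles[nm] == "outgroup") paste0("outgroup:", lins[nm]) else roles[nm]
    new <- sample(setdiff(options_all, cur), 1L)
    if (startsWith(new, "outgroup:")) {
      roles[nm] <- "outgroup"
      lins[nm] <- sub("^outgroup:", "", new)
    } else {
      roles[nm] <- new
      lins[nm] <- NA_character_
    }
  }

  atree <- structure(list(tree = phy, roles = roles[phy$tip.label],
                          lineages = lins[phy$tip.label], og_id = og_id,
                          vocabulary = vocab),
                     class = "annotated_gene_tree")
  truth <- data.frame(
    og_id = og_id, scenario = scen,
    category = unname(.SCENARIO_CATEGORY[scen]),
    donor_lineages = paste(sort(unique(spec$donor_lineages)), collapse = ","),
    direction = if (scen %in% c("ancient_hgt", "recent_hgt_single", "recent_hgt_multi"))
      "acceptor" else NA_character_,
    query_ids = paste(sort(q), collapse = ","),
    stringsAsFactors = FALSE)
  list(tree = atree, truth = truth)
}

#' Simulate a corpus of gene trees
#'
#' @param mixture List of entries `list(spec = <scenario_spec>, n = <count>)`.
#' @param seed Integer master seed; per-tree seeds are drawn from it, so the
#'   whole corpus is reproducible byte-for-byte.
#' @return An object of class `hgt_corpus`: list with `trees` (named list of
#'   `annotated_gene_tree`), `truth` (data frame, one row per tree) and
#'   `seed`.
#' @export
simulate_corpus <- function(mixture, seed = 1L) {
  if (!length(mixture)) stop("empty mixture")
  for (m in mixture) {
    if (!inherits(m$spec, "scenario_spec") || is.null(m$n) || m$n < 1L)
      stop("each mixture entry needs a scenario_spec and a count n >= 1")
  }
  specs <- unlist(lapply(mixture, function(m) rep(list(m$spec), m$n)),
                  recursive = FALSE)
  total <- length(specs)
  tree_seeds <- .with_seed(seed, sample.int(.Machine$integer.max - 1L, total))
  ogs <- sprintf("OG%07d", seq_len(total))
  out <- vector("list", total)
  truth <- vector("list", total)
  for (i in seq_len(total)) {
    sp <- specs[[i]]
    sp$seed <- tree_seeds[i]
    sim <- simulate_tree(sp, og_id = ogs[i])
    out[[i]] <- sim$tree
    truth[[i]] <- sim$truth
  }
  names(out) <- ogs
  structure(list(trees = out, truth = do.call(rbind, truth), seed = seed),
            class = "hgt_corpus")
}

#' Default five-scenario mixture
#'
#' One entry per scenario with the package's default scenario parameters.
#'
#' @param n_per Trees per scenario.
#' @param ... Passed to every [scenario_spec()] call (e.g. `noise`,
#'   `support_model`, `n_leaves`).
#' @return A mixture list for [simulate_corpus()].
#' @export
default_mixture <- function(n_per = 40L, ...) {
  lapply(.SCENARIOS, function(s) list(spec = scenario_spec(s, ...), n = n_per))
}

#' Write a corpus to disk
#'
#' One newick file per tree under `dir/trees/`, plus a combined taxonomy map
#' (`taxonomy.tsv`) and the planted-truth table (`truth.tsv`).
#'
#' @param corpus An `hgt_corpus`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "hgt_corpus"))
  tdir <- file.path(dir, "trees")
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
  tax <- lapply(corpus$trees, function(at) data.frame(
    seq_id = names(at$roles), role = unname(at$roles),
    lineage = ifelse(is.na(at$lineages), "", unname(at$lineages)),
    stringsAsFactors = FALSE))
  for (og in names(corpus$trees))
    write_gene_tree(corpus$trees[[og]]$tree, file.path(tdir, paste0(og, ".nwk")))
  write.table(do.call(rbind, tax), file.path(dir, "taxonomy.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(corpus$truth, file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Classify every tree of a corpus
#'
#' Runs the tree-walking classifier on each tree and collects per-query
#' calls, per-tree summary calls (the first query's category and direction)
#' and deduplicated events. Trees left without query leaves (possible under
#' label noise) are reported with `NA` category.
#'
#' @param corpus An `hgt_corpus` or named list of `annotated_gene_tree`.
#' @param params A `walk_params`.
#' @return An object of class `corpus_scan`: list with `per_tree`, `calls`,
#'   `events` and `trees` (the processed trees, for [lineage_enrichment()]).
#' @export
classify_corpus <- function(corpus, params = walk_params()) {
  trees <- if (inherits(corpus, "hgt_corpus")) corpus$trees else corpus
  per_tree <- vector("list", length(trees))
  calls <- vector("list", length(trees))
  events <- vector("list", length(trees))
  processed <- vector("list", length(trees))
  names(processed) <- names(trees)
  for (i in seq_along(trees)) {
    at <- trees[[i]]
    og <- at$og_id
    if (!any(at$roles == "query")) {
      per_tree[[i]] <- data.frame(og_id = og, category = NA_character_,
                                  direction = NA_character_, n_queries = 0L,
                                  stringsAsFactors = FALSE)
      next
    }
    res <- classify_tree(at, params)
    ev <- aggregate_events(res, params = params)
    first <- res[[1L]]
    dir1 <- if (first$category %in% .HGT_CATEGORIES)
      infer_direction(first, attr(res, "tree")) else NA_character_
    per_tree[[i]] <- data.frame(og_id = og, category = first$category,
                                direction = dir1, n_queries = length(res),
                                stringsAsFactors = FALSE)
    calls[[i]] <- walk_results_table(res)
    if (nrow(ev)) events[[i]] <- ev
    processed[[og]] <- attr(res, "tree")
  }
  ev_all <- do.call(rbind, events[!vapply(events, is.null, logical(1))])
  structure(list(per_tree = do.call(rbind, per_tree),
                 calls = do.call(rbind, calls),
                 events = if (is.null(ev_all)) .empty_events() else ev_all,
                 trees = processed[!vapply(processed, is.null, logical(1))]),
            class = "corpus_scan")
}

#' Score recovery of planted scenarios
#'
#' @param predictions A `corpus_scan` or its `per_tree` data frame (og_id,
#'   category, direction).
#' @param truth The corpus truth table.
#' @return An object of class `recovery_summary`: confusion matrix (rows =
#'   planted categories, columns = predicted, `NA` predictions counted as
#'   "unclassified"), per-category sensitivity and precision, overall
#'   category accuracy, direction accuracy on planted-HGT trees, and
#'   `n_trees`.
#' @export
evaluate_recovery <- function(predictions, truth) {
  if (inherits(predictions, "corpus_scan")) predictions <- predictions$per_tree
  if (inherits(truth, "hgt_corpus")) truth <- truth$truth
  miss_p <- setdiff(truth$og_id, predictions$og_id)
  miss_t <- setdiff(predictions$og_id, truth$og_id)
  if (length(miss_p) || length(miss_t))
    stop("og_id mismatch between predictions and truth: ",
         paste(head(c(miss_p, miss_t), 5L), collapse = ", "))
  idx <- match(truth$og_id, predictions$og_id)
  pred_cat <- predictions$category[idx]
  pred_cat[is.na(pred_cat)] <- "unclassified"
  levs <- unique(c(.CATEGORIES, "unclassified", truth$category, pred_cat))
  confusion <- table(planted = factor(truth$category, levels = levs),
                     predicted = factor(pred_cat, levels = levs))
  confusion <- confusion[rowSums(confusion) > 0, , drop = FALSE]
  acc <- mean(pred_cat == truth$category)
  present <- rownames(confusion)
  sens <- vapply(present, function(k) confusion[k, k] / sum(confusion[k, ]), numeric(1))
  prec <- vapply(present, function(k) {
    tot <- sum(pred_cat == k)
    if (tot) confusion[k, k] / tot else NA_real_
  }, numeric(1))
  is_hgt_truth <- !is.na(truth$direction) & truth$direction == "acceptor"
  dir_acc <- if (any(is_hgt_truth)) {
    pd <- predictions$direction[idx][is_hgt_truth]
    mean(!is.na(pd) & pd == truth$direction[is_hgt_truth])
  } else NA_real_
  structure(list(confusion = confusion, sensitivity = sens, precision = prec,
                 category_accuracy = acc, direction_accuracy = dir_acc,
                 n_trees = nrow(truth)),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("Recovery over %d trees: category accuracy %.3f, direction accuracy %s\n",
              x$n_trees, x$category_accuracy,
              if (is.na(x$direction_accuracy)) "NA" else sprintf("%.3f", x$direction_accuracy)))
  print(x$confusion)
  invisible(x)
}
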