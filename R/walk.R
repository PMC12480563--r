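## The tree-walking classifier: rooting, support-collapse, nested-clade
## counting and the stopping criteria.

.CATEGORIES <- c("ancestral", "ancestral_hgt", "single_hgt", "multi_hgt",
                 "ingroup_only", "undetermined")
.HGT_CATEGORIES <- c("ancestral_hgt", "single_hgt", "multi_hgt")

#' Classifier parameters
#'
#' Defaults reproduce the reference analysis: an edge is "highly supported"
#' iff its support is strictly greater than 0.85; a clade is called
#' `ancestral` at 5 accumulated sister sequences; HGT calls require at least
#' 3 outgroup sequences from one major lineage.
#'
#' @param support_threshold Support cutoff in `[0, 1]`. With
#'   `strict_greater = TRUE` an internal edge is retained iff
#'   `support > support_threshold`; edges with absent support (leaf edges,
#'   the root) are always treated as resolved.
#' @param min_sisters Sister-sequence count that fires the `ancestral`
#'   criterion.
#' @param min_outgroup_per_lineage Per-lineage outgroup count required for an
#'   HGT call.
#' @param rooting_strategy `"farthest_leaf"` (default; deterministic, roots
#'   on the terminal edge of the leaf farthest from the first query, ties
#'   broken lexicographically), `"midpoint"`, or `"as_is"`.
#' @param strict_greater Logical; see `support_threshold`.
#' @param single_lineage_rule How single-HGT reads "a single lineage":
#'   `"all"` (default; every outgroup leaf in the stopping clade shares one
#'   lineage) or `"majority"` (the dominant lineage holds at least
#'   `majority_frac` of outgroup leaves).
#' @param majority_frac Fraction used by `single_lineage_rule = "majority"`.
#' @param event_key Leaf set used to deduplicate events:
#'   `"focal_sister"` (default; query + ingroup + sister leaves of the
#'   stopping clade, so calls differing only in outgroup resolution merge)
#'   or `"full"` (complete stopping-clade leaf set).
#' @return An object of class `walk_params`.
#' @export
walk_params <- function(support_threshold = 0.85,
                        min_sisters = 5L,
                        min_outgroup_per_lineage = 3L,
                        rooting_strategy = c("farthest_leaf", "midpoint", "as_is"),
                        strict_greater = TRUE,
                        single_lineage_rule = c("all", "majority"),
                        majority_frac = 0.9,
                        event_key = c("focal_sister", "full")) {
  rooting_strategy <- match.arg(rooting_strategy)
  single_lineage_rule <- match.arg(single_lineage_rule)
  event_key <- match.arg(event_key)
  stopifnot(is.numeric(support_threshold), length(support_threshold) == 1L,
            support_threshold >= 0, support_threshold <= 1,
            min_sisters >= 1L, min_outgroup_per_lineage >= 1L,
            is.logical(strict_greater),
            majority_frac > 0.5, majority_frac <= 1)
  structure(list(support_threshold = support_threshold,
                 min_sisters = as.integer(min_sisters),
                 min_outgroup_per_lineage = as.integer(min_outgroup_per_lineage),
                 rooting_strategy = rooting_strategy,
                 strict_greater = isTRUE(strict_greater),
                 single_lineage_rule = single_lineage_rule,
                 majority_frac = majority_frac,
                 event_key = event_key),
            class = "walk_params")
}

## Path-length distances from one tip to all tips, by BFS on the undirected
## tree; absent branch lengths count as 1 per edge.
.tip_distances <- function(phy, from) {
  n <- length(phy$tip.label)
  m <- phy$Nnode
  el <- phy$edge.length
  if (is.null(el)) el <- rep(1, nrow(phy$edge))
  nb <- vector("list", n + m)
  e <- phy$edge
  for (i in seq_len(nrow(e))) {
    a <- e[i, 1L]; b <- e[i, 2L]
    nb[[a]] <- rbind(nb[[a]], c(b, el[i]))
    nb[[b]] <- rbind(nb[[b]], c(a, el[i]))
  }
  start <- match(from, phy$tip.label)
  if (is.na(start)) stop("leaf not found: ", from)
  dist <- rep(NA_real_, n + m)
  dist[start] <- 0
  queue <- start
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (k in seq_len(NROW(nb[[v]]))) {
      w <- nb[[v]][k, 1L]
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + nb[[v]][k, 2L]
        queue <- c(queue, w)
      }
    }
  }
  stats::setNames(dist[seq_len(n)], phy$tip.label)
}

#' Root an annotated gene tree
#'
#' `farthest_leaf` roots on the terminal edge of the leaf with maximal path
#' length from the first (lexicographically smallest) query leaf, ties broken
#' lexicographically by leaf name; `midpoint` roots at the midpoint of the
#' longest leaf-to-leaf path; `as_is` keeps the input rooting and errors on
#' an unrooted (basal polytomy) tree. Re-rooting never relabels a
#' bipartition's support: supports stay attached to the splits they describe.
#'
#' @param atree An `annotated_gene_tree`.
#' @param strategy Rooting strategy; defaults to the strategy in `params`.
#' @param params A `walk_params` (used only for its `rooting_strategy`
#'   default).
#' @return A rooted `annotated_gene_tree`.
#' @export
root_tree <- function(atree, strategy = NULL, params = walk_params()) {
  stopifnot(inherits(atree, "annotated_gene_tree"))
  if (is.null(strategy)) strategy <- params$rooting_strategy
  strategy <- match.arg(strategy, c("farthest_leaf", "midpoint", "as_is"))
  phy <- atree$tree
  n <- length(phy$tip.label)
  if (n < 2L) stop("cannot root a tree with fewer than 2 leaves")
  if (strategy == "as_is") {
    if (!ape::is.rooted(phy))
      stop("tree is unrooted (basal polytomy); pick rooting strategy farthest_leaf or midpoint")
    return(atree)
  }
  if (strategy == "midpoint") {
    if (is.null(phy$edge.length)) {
      warning("tree has no branch lengths; midpoint rooting with unit lengths")
      phy$edge.length <- rep(1, nrow(phy$edge))
    }
    phy2 <- phangorn::midpoint(phy, node.labels = "support")
  } else {
    queries <- sort(names(atree$roles)[atree$roles == "query"])
    if (!length(queries))
      stop("farthest_leaf rooting requires at least one query leaf")
    q <- queries[1L]
    d <- .tip_distances(phy, q)
    cand <- setdiff(names(d), q)
    if (!length(cand)) stop("no leaf to root on")
    target <- cand[order(-d[cand], cand)][1L]
    phy2 <- .root_on_tip(phy, target)
  }
  if (!is.null(phy2$node.label)) phy2$node.label[1L] <- NA  # root support is absent
  phy2$node.label <- .normalise_supports(phy2$node.label, phy2$Nnode)
  class(phy2) <- c("gene_tree", "phylo")
  atree$tree <- phy2
  atree
}

## Root so that `tip` becomes one of the two children of a binary root,
## treating node labels as edge (support) labels.
.root_on_tip <- function(phy, tip) {
  root <- length(phy$tip.label) + 1L
  tipn <- match(tip, phy$tip.label)
  kids <- phy$edge[phy$edge[, 1L] == root, 2L]
  if (ape::is.rooted(phy) && tipn %in% kids) return(phy)
  ape::root(phy, outgroup = tip, resolve.root = TRUE, edgelabel = TRUE)
}

#' Collapse poorly supported edges into polytomies
#'
#' Every internal edge whose support fails the cutoff (with
#' `strict_greater = TRUE`: `support <= support_threshold`) is contracted;
#' edges with absent support are retained. Contraction only removes internal
#' nodes, so the leaf set under every retained node is unchanged. Idempotent.
#'
#' @param atree A rooted `annotated_gene_tree`.
#' @param params A `walk_params`.
#' @return The collapsed `annotated_gene_tree` (possibly with polytomies).
#' @export
collapse_low_support <- function(atree, params = walk_params()) {
  stopifnot(inherits(atree, "annotated_gene_tree"))
  phy <- atree$tree
  if (!ape::is.rooted(phy)) stop("collapse_low_support expects a rooted tree")
  n <- length(phy$tip.label)
  m <- phy$Nnode
  root <- n + 1L
  sup <- node_supports(phy)
  thr <- params$support_threshold
  low <- if (params$strict_greater) !is.na(sup) & sup <= thr else !is.na(sup) & sup < thr
  low[1L] <- FALSE  # the root is always retained
  if (!any(low)) return(atree)
  kill <- which(low) + n

  e <- .cladewise_edge(phy)
  ## nearest retained ancestor of every node, rows visited parents-first
  anc <- seq_len(n + m)
  killed <- rep(FALSE, n + m)
  killed[kill] <- TRUE
  for (i in seq_len(nrow(e))) {
    p <- e[i, 1L]; ch <- e[i, 2L]
    if (killed[ch]) anc[ch] <- anc[p]
  }
  keep_row <- !killed[e[, 2L]]
  new_parent <- anc[e[keep_row, 1L]]
  new_child <- e[keep_row, 2L]

  keep_int <- sort(setdiff(unique(c(root, new_parent, new_child[new_child > n])), kill))
  remap <- integer(n + m)
  remap[seq_len(n)] <- seq_len(n)
  keep_int <- c(root, setdiff(keep_int, root))
  remap[keep_int] <- n + seq_along(keep_int)

  edge2 <- cbind(remap[new_parent], remap[new_child])
  phy2 <- list(edge = edge2,
               tip.label = phy$tip.label,
               Nnode = length(keep_int))
  if (!is.null(phy$edge.length)) {
    len_by_child <- rep(NA_real_, n + m)
    len_by_child[phy$edge[, 2L]] <- phy$edge.length
    phy2$edge.length <- len_by_child[new_child]
  }
  phy2$node.label <- sup[keep_int - n]
  class(phy2) <- "phylo"
  phy2 <- ape::reorder.phylo(phy2, "cladewise")
  class(phy2) <- c("gene_tree", "phylo")
  atree$tree <- phy2
  atree
}

.cladewise_edge <- function(phy) {
  if (identical(attr(phy, "order"), "cladewise")) return(phy$edge)
  ape::reorder.phylo(phy, "cladewise")$edge
}

## ---- walk context: per-node cumulative role/lineage counts -------------

## Builds, in one postorder pass, an (Ntip+Nnode) x (3+L) count matrix whose
## row for a node gives the role/lineage composition of its subtree.
.walk_context <- function(atree) {
  phy <- atree$tree
  n <- length(phy$tip.label)
  m <- phy$Nnode
  vocab <- unique(c(atree$vocabulary,
                    atree$lineages[atree$roles == "outgroup"]))
  vocab <- vocab[!is.na(vocab)]
  cols <- c("n_query", "n_ingroup", "n_sister", vocab)
  cnt <- matrix(0L, n + m, length(cols), dimnames = list(NULL, cols))
  roles <- atree$roles[phy$tip.label]
  lin <- atree$lineages[phy$tip.label]
  col_of <- match(roles, c("query", "ingroup", "sister"))
  og <- which(roles == "outgroup")
  col_of[og] <- 3L + match(lin[og], vocab)
  if (anyNA(col_of)) stop("leaf with unknown role or lineage outside the vocabulary")
  cnt[cbind(seq_len(n), col_of)] <- 1L

  e <- ape::reorder.phylo(phy, "postorder")$edge
  for (i in seq_len(nrow(e)))
    cnt[e[i, 1L], ] <- cnt[e[i, 1L], ] + cnt[e[i, 2L], ]
  parent <- integer(n + m)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  list(phy = phy, n = n, counts = cnt, parent = parent,
       root = n + 1L, vocab = vocab)
}

.subtree_tips <- function(ctx, node) {
  if (node <= ctx$n) return(ctx$phy$tip.label[node])
  e <- ctx$phy$edge
  stack <- node
  tips <- integer(0)
  children <- split(e[, 2L], e[, 1L])
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    kids <- children[[as.character(v)]]
    tips <- c(tips, kids[kids <= ctx$n])
    stack <- c(stack, kids[kids > ctx$n])
  }
  ctx$phy$tip.label[tips]
}

.cc_from_row <- function(ctx, node, with_leaves = FALSE) {
  row <- ctx$counts[node, ]
  out <- list(node = node,
              size = sum(row),
              n_query = unname(row[["n_query"]]),
              n_ingroup = unname(row[["n_ingroup"]]),
              n_sister = unname(row[["n_sister"]]),
              outgroup = row[-(1:3)])
  if (with_leaves) out$leaves <- .subtree_tips(ctx, node)
  structure(out, class = "clade_counts")
}

#' Construct clade composition counts
#'
#' Mostly useful for feeding hand-written traces to [classify_counts()].
#'
#' @param n_query,n_ingroup,n_sister Non-negative leaf counts.
#' @param outgroup Named integer vector of per-lineage outgroup counts.
#' @param node,leaves Optional node id and leaf names.
#' @return An object of class `clade_counts`.
#' @export
clade_counts <- function(n_query = 1L, n_ingroup = 0L, n_sister = 0L,
                         outgroup = integer(), node = NA_integer_, leaves = NULL) {
  stopifnot(n_query >= 0, n_ingroup >= 0, n_sister >= 0, all(outgroup >= 0))
  structure(list(node = node,
                 size = n_query + n_ingroup + n_sister + sum(outgroup),
                 n_query = as.integer(n_query),
                 n_ingroup = as.integer(n_ingroup),
                 n_sister = as.integer(n_sister),
                 outgroup = outgroup, leaves = leaves),
            class = "clade_counts")
}

#' Nested-clade trace from a query leaf to the root
#'
#' Returns the cumulative clade composition of every ancestor of the query,
#' from its parent up to and including the root, in walk order. Counts are
#' cumulative over each nested clade; the query leaf itself is counted in
#' `n_query` only.
#'
#' @param atree A rooted (and normally support-collapsed)
#'   `annotated_gene_tree`.
#' @param query Query leaf name.
#' @return List of `clade_counts`, each with its leaf set.
#' @export
nested_clades <- function(atree, query) {
  ## the edge matrix's root node is taken as the top of the walk; a basal
  ## polytomy is admissible here because support collapse produces them
  stopifnot(inherits(atree, "annotated_gene_tree"))
  ctx <- .walk_context(atree)
  qn <- match(query, ctx$phy$tip.label)
  if (is.na(qn)) stop("query leaf not found: ", query)
  lapply(.ancestor_path(ctx, qn), .cc_from_row, ctx = ctx, with_leaves = TRUE)
}

.ancestor_path <- function(ctx, tip_node) {
  path <- integer(0)
  v <- ctx$parent[tip_node]
  while (v != 0L) {
    path <- c(path, v)
    if (v == ctx$root) break
    v <- ctx$parent[v]
  }
  path
}

## One stopping-criteria evaluation; returns category string or NULL.
.eval_step <- function(cc, params) {
  if (cc$n_sister >= params$min_sisters) return("ancestral")
  og <- cc$outgroup
  og_tot <- sum(og)
  og_max <- if (length(og)) max(og) else 0L
  if (cc$n_sister >= 1L && og_max >= params$min_outgroup_per_lineage)
    return("ancestral_hgt")
  if (cc$n_sister == 0L && og_tot > 0L) {
    n_lin <- sum(og > 0L)
    qualifying <- sum(og >= params$min_outgroup_per_lineage)
    single <- if (params$single_lineage_rule == "all") {
      qualifying == 1L && og_max == og_tot
    } else {
      qualifying >= 1L && og_max >= params$majority_frac * og_tot
    }
    if (single) return("single_hgt")
    if (og_tot >= params$min_outgroup_per_lineage && n_lin >= 2L &&
        og_max >= params$min_outgroup_per_lineage)
      return("multi_hgt")
  }
  NULL
}

.donors_at <- function(cc, params, category) {
  og <- cc$outgroup
  if (!category %in% .HGT_CATEGORIES) return(character())
  don <- names(og)[og >= params$min_outgroup_per_lineage]
  if (category == "single_hgt" && !length(don))
    don <- names(og)[which.max(og)]
  sort(don)
}

#' Classify a nested-clade trace against the stopping criteria
#'
#' Scans the trace in walk order. At each step, with precedence
#' `ancestral` > `ancestral_hgt` > `single_hgt`/`multi_hgt`:
#' \itemize{
#'   \item `ancestral` iff `n_sister >= min_sisters`;
#'   \item `ancestral_hgt` iff `n_sister >= 1` and some lineage has at least
#'     `min_outgroup_per_lineage` outgroup leaves;
#'   \item `single_hgt` iff `n_sister == 0`, exactly one lineage reaches the
#'     per-lineage minimum and all outgroup leaves belong to it (see
#'     `single_lineage_rule`); `multi_hgt` iff `n_sister == 0`, total
#'     outgroup reaches the minimum, outgroup leaves span at least two
#'     lineages and at least one lineage reaches the per-lineage minimum.
#' }
#' If no criterion fires by the root: `ingroup_only` when the whole tree
#' holds only query and ingroup leaves, else `undetermined`.
#'
#' @param trace List of `clade_counts` (cumulative, nested); normally from
#'   [nested_clades()].
#' @param params A `walk_params`.
#' @return List with `category` and `stop_index` (1-based index into the
#'   trace, `NA` for `ingroup_only`/`undetermined`).
#' @export
classify_counts <- function(trace, params = walk_params()) {
  if (!length(trace)) stop("empty trace")
  vecs <- vapply(trace, function(cc)
    c(cc$n_query, cc$n_ingroup, cc$n_sister, sum(cc$outgroup)), numeric(4))
  if (length(trace) > 1L && any(diff(t(vecs)) < 0))
    stop("trace is not cumulative: counts decrease along the walk")
  for (i in seq_along(trace)) {
    cat_i <- .eval_step(trace[[i]], params)
    if (!is.null(cat_i)) return(list(category = cat_i, stop_index = i))
  }
  last <- trace[[length(trace)]]
  cat_f <- if (last$n_sister == 0L && sum(last$outgroup) == 0L)
    "ingroup_only" else "undetermined"
  list(category = cat_f, stop_index = NA_integer_)
}

#' Walk a single query leaf
#'
#' Roots the tree (per `params$rooting_strategy`), collapses poorly
#' supported edges, computes the nested-clade trace from the query and
#' classifies it. For HGT categories the donor lineage set is the set of
#' lineages meeting the per-lineage minimum at the stopping clade.
#'
#' @param atree An `annotated_gene_tree` with at least one query leaf.
#' @param query Query leaf name.
#' @param params A `walk_params`.
#' @return An object of class `walk_result` with fields `og_id`, `query`,
#'   `category`, `stop` (a `clade_counts` with leaves, or `NULL`), `trace`,
#'   `donor_lineages`, `trace_depth`, plus the processed tree as attribute
#'   `"tree"`.
#' @export
walk_query <- function(atree, query, params = walk_params()) {
  prepped <- .prepare_tree(atree, params)
  ctx <- .walk_context(prepped)
  res <- .walk_one(ctx, prepped, query, params)
  attr(res, "tree") <- prepped
  res
}

.prepare_tree <- function(atree, params) {
  collapse_low_support(root_tree(atree, params$rooting_strategy), params)
}

.walk_one <- function(ctx, prepped, query, params) {
  qn <- match(query, ctx$phy$tip.label)
  if (is.na(qn)) stop("query leaf not found: ", query)
  path <- .ancestor_path(ctx, qn)
  trace <- lapply(path, .cc_from_row, ctx = ctx)
  cls <- classify_counts(trace, params)
  stop_cc <- NULL
  donors <- character()
  if (!is.na(cls$stop_index)) {
    stop_cc <- .cc_from_row(ctx, path[cls$stop_index], with_leaves = TRUE)
    donors <- .donors_at(stop_cc, params, cls$category)
  }
  structure(list(og_id = prepped$og_id, query = query,
                 category = cls$category, stop = stop_cc, trace = trace,
                 donor_lineages = donors, trace_depth = length(trace)),
            class = "walk_result")
}

#' Classify every query leaf of a tree
#'
#' One walk per query leaf, in lexicographic leaf-name order. The tree is
#' rooted and collapsed once and shared across walks.
#'
#' @param atree An `annotated_gene_tree` with at least one query leaf.
#' @param params A `walk_params`.
#' @return List of `walk_result` of class `walk_result_list`, with the
#'   processed tree as attribute `"tree"`.
#' @export
classify_tree <- function(atree, params = walk_params()) {
  stopifnot(inherits(atree, "annotated_gene_tree"))
  queries <- sort(names(atree$roles)[atree$roles == "query"])
  if (!length(queries))
    stop(sprintf("tree %s has no query leaves (inadmissible)", atree$og_id))
  prepped <- .prepare_tree(atree, params)
  ctx <- .walk_context(prepped)
  out <- lapply(queries, function(q) .walk_one(ctx, prepped, q, params))
  attr(out, "tree") <- prepped
  class(out) <- "walk_result_list"
  out
}

#' Tabulate walk results
#'
#' @param results A `walk_result_list` (or list of `walk_result`).
#' @return Data frame with columns og_id, query, category, stop_clade_size,
#'   n_sister_at_stop, donor_lineages (comma-joined), trace_depth.
#' @export
walk_results_table <- function(results) {
  rows <- lapply(results, function(r) data.frame(
    og_id = r$og_id, query = r$query, category = r$category,
    stop_clade_size = if (is.null(r$stop)) NA_integer_ else r$stop$size,
    n_sister_at_stop = if (is.null(r$stop)) NA_integer_ else r$stop$n_sister,
    donor_lineages = paste(r$donor_lineages, collapse = ","),
    trace_depth = r$trace_depth,
    stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' List bipartition supports of a tree
#'
#' Each internal edge is identified by the side of its split that does not
#' contain the alphabetically first leaf; useful for checking that
#' re-rooting preserves supports on the bipartitions they describe.
#'
#' @param tree A `gene_tree`/`phylo`.
#' @return Named numeric vector: names are sorted comma-joined leaf subsets,
#'   values are supports (`NA` = absent). Trivial splits are omitted.
#' @export
bipartition_supports <- function(tree) {
  n <- length(tree$tip.label)
  if (tree$Nnode < 2L) return(stats::setNames(numeric(0), character(0)))
  sup <- node_supports(tree)
  anchor <- sort(tree$tip.label)[1L]
  out <- numeric(0)
  for (i in seq_len(tree$Nnode)[-1L]) {  # skip the root
    node <- n + i
    tips <- ape::extract.clade(.as_plain_phylo(tree), node)$tip.label
    if (length(tips) <= 1L || length(tips) >= n - 1L) next
    side <- if (anchor %in% tips) setdiff(tree$tip.label, tips) else tips
    out[paste(sort(side), collapse = ",")] <- sup[i]
  }
  out[order(names(out))]
}

.as_plain_phylo <- function(tree) { class(tree) <- "phylo"; tree }
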