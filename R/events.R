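## Ingroup-monophyly direction test and per-orthogroup event aggregation.

#' Test ingroup monophyly within a stopping clade
#'
#' With the clade's ancestral node taken as the root of the clade subtree,
#' the clade is ingroup-monophyletic iff the query + ingroup + sister leaves
#' it contains form exactly one monophyletic group, i.e. their MRCA within
#' the subtree holds no outgroup leaf -- evidence that the focal lineage is
#' nested within donor sequences rather than branching next to them. The
#' test depends only on topology, never on branch lengths or child order.
#'
#' @param atree The processed (rooted, collapsed) `annotated_gene_tree` the
#'   stopping clade belongs to.
#' @param clade_node Node id of the stopping clade; must contain at least
#'   one outgroup leaf.
#' @return Logical scalar.
#' @export
is_ingroup_monophyletic <- function(atree, clade_node) {
  stopifnot(inherits(atree, "annotated_gene_tree"))
  phy <- atree$tree
  n <- length(phy$tip.label)
  parent <- integer(n + phy$Nnode)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  tips <- .clade_tip_names(phy, clade_node)
  roles <- atree$roles[tips]
  focal <- tips[roles %in% c("query", "ingroup", "sister")]
  outg <- tips[roles == "outgroup"]
  if (!length(outg))
    stop("ingroup-monophyly test undefined: stopping clade has no outgroup leaves")
  if (!length(focal))
    stop("stopping clade has no query/ingroup/sister leaves")
  if (length(focal) == 1L) return(TRUE)
  mrca <- .mrca_nodes(parent, match(focal, phy$tip.label), n)
  mtips <- .clade_tip_names(phy, mrca)
  all(atree$roles[mtips] %in% c("query", "ingroup", "sister"))
}

.clade_tip_names <- function(phy, node) {
  n <- length(phy$tip.label)
  if (node <= n) return(phy$tip.label[node])
  e <- phy$edge
  children <- split(e[, 2L], e[, 1L])
  stack <- node
  tips <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    kids <- children[[as.character(v)]]
    tips <- c(tips, kids[kids <= n])
    stack <- c(stack, kids[kids > n])
  }
  phy$tip.label[tips]
}

## MRCA by walking ancestor chains; nodes are tip indices.
.mrca_nodes <- function(parent, nodes, n) {
  chain <- function(v) {
    path <- v
    while (parent[v] != 0L) { v <- parent[v]; path <- c(path, v) }
    path
  }
  common <- chain(nodes[1L])
  for (v in nodes[-1L]) common <- intersect(common, chain(v))
  common[1L]
}

#' Infer transfer direction for an HGT walk result
#'
#' The focal lineage is called the `acceptor` of the transfer iff the
#' stopping clade is ingroup-monophyletic; otherwise the direction (to or
#' from the focal lineage) is `unresolved`.
#'
#' @param result A `walk_result` with an HGT category.
#' @param atree The processed tree; defaults to the tree attached to
#'   `result`.
#' @return `"acceptor"` or `"unresolved"`.
#' @export
infer_direction <- function(result, atree = attr(result, "tree")) {
  stopifnot(inherits(result, "walk_result"))
  if (!result$category %in% .HGT_CATEGORIES)
    stop("direction is defined only for HGT categories, not ", result$category)
  if (is.null(atree)) stop("processed tree not available; pass atree")
  if (is_ingroup_monophyletic(atree, result$stop$node)) "acceptor" else "unresolved"
}

#' Aggregate per-query walk results into deduplicated HGT events
#'
#' Groups HGT-category results of one orthogroup by stopping-clade identity
#' (by default the query + ingroup + sister leaf set of the stopping clade,
#' so calls differing only in outgroup resolution merge) and emits one event
#' per group. The member-gene total across events equals the number of
#' HGT-category walk results. Event direction is `acceptor` only when every
#' member walk is an acceptor.
#'
#' @param results A `walk_result_list` from [classify_tree()] (one
#'   orthogroup).
#' @param atree The processed tree; defaults to the tree attached to
#'   `results`.
#' @param params A `walk_params` (for `event_key`).
#' @return Data frame of class `hgt_events` with columns og_id, event_id,
#'   category, n_genes, gene_ids, donor_lineages, direction,
#'   ingroup_monophyletic, and a list column `clade_leaves` holding the full
#'   leaf set of each event's stopping clade(s).
#' @export
aggregate_events <- function(results, atree = attr(results, "tree"),
                             params = walk_params()) {
  ogs <- unique(vapply(results, function(r) r$og_id, character(1)))
  if (length(ogs) > 1L)
    stop("results from mixed orthogroups: ", paste(ogs, collapse = ", "))
  hgt <- Filter(function(r) r$category %in% .HGT_CATEGORIES, results)
  if (!length(hgt)) return(.empty_events())
  if (is.null(atree)) stop("processed tree not available; pass atree")

  keys <- vapply(hgt, function(r) {
    leaves <- r$stop$leaves
    if (params$event_key == "focal_sister") {
      rl <- atree$roles[leaves]
      leaves <- leaves[rl %in% c("query", "ingroup", "sister")]
    }
    paste(sort(leaves), collapse = "|")
  }, character(1))
  groups <- split(hgt, keys)
  groups <- groups[order(names(groups))]

  rows <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    dirs <- vapply(g, function(r) infer_direction(r, atree), character(1))
    cats <- vapply(g, function(r) r$category, character(1))
    cat_tab <- sort(table(cats), decreasing = TRUE)
    genes <- sort(vapply(g, function(r) r$query, character(1)))
    mono <- all(dirs == "acceptor")
    rows[[i]] <- data.frame(
      og_id = ogs,
      event_id = sprintf("%s:E%d", ogs, i),
      category = names(cat_tab)[1L],
      n_genes = length(genes),
      gene_ids = paste(genes, collapse = ","),
      donor_lineages = paste(sort(unique(unlist(lapply(g, `[[`, "donor_lineages")))),
                             collapse = ","),
      direction = if (mono) "acceptor" else "unresolved",
      ingroup_monophyletic = mono,
      stringsAsFactors = FALSE)
    rows[[i]]$clade_leaves <- list(sort(unique(unlist(lapply(g, function(r) r$stop$leaves)))))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("hgt_events", "data.frame")
  out
}

.empty_events <- function() {
  out <- data.frame(og_id = character(), event_id = character(),
                    category = character(), n_genes = integer(),
                    gene_ids = character(), donor_lineages = character(),
                    direction = character(), ingroup_monophyletic = logical(),
                    stringsAsFactors = FALSE)
  out$clade_leaves <- list()
  class(out) <- c("hgt_events", "data.frame")
  out
}
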