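# Brute-force oracle for the tree walk: enumerates every supported clade
# containing the query on the rooted tree (no collapse step), sorts by clade
# size and applies the stopping criteria directly to leaf-name sets. Kept
# deliberately independent of the package's postorder-count implementation.

oracle_clade_tips <- function(phy, node) {
  n <- length(phy$tip.label)
  if (node <= n) return(phy$tip.label[node])
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  unlist(lapply(kids, oracle_clade_tips, phy = phy))
}

oracle_walk <- function(atree, query, params = walk_params()) {
  phy <- atree$tree
  stopifnot(ape::is.rooted(phy))
  n <- length(phy$tip.label)
  sup <- node_supports(phy)
  keep <- vapply(seq_len(phy$Nnode), function(i) {
    i == 1L || is.na(sup[i]) ||
      (if (params$strict_greater) sup[i] > params$support_threshold
       else sup[i] >= params$support_threshold)
  }, logical(1))
  clades <- lapply(which(keep) + n, oracle_clade_tips, phy = phy)
  clades <- Filter(function(cl) query %in% cl, clades)
  clades <- clades[order(lengths(clades))]

  roles <- atree$roles
  lins <- atree$lineages
  for (cl in clades) {
    nsis <- sum(roles[cl] == "sister")
    og_lin <- lins[cl][roles[cl] == "outgroup"]
    tab <- table(og_lin)
    fired <- NULL
    donors <- character(0)
    if (nsis >= params$min_sisters) {
      fired <- "ancestral"
    } else if (nsis >= 1 && length(tab) && max(tab) >= params$min_outgroup_per_lineage) {
      fired <- "ancestral_hgt"
      donors <- names(tab)[tab >= params$min_outgroup_per_lineage]
    } else if (nsis == 0 && length(tab)) {
      if (length(tab) == 1 && tab[[1]] >= params$min_outgroup_per_lineage) {
        fired <- "single_hgt"
        donors <- names(tab)
      } else if (sum(tab) >= params$min_outgroup_per_lineage && length(tab) >= 2 &&
                 max(tab) >= params$min_outgroup_per_lineage) {
        fired <- "multi_hgt"
        donors <- names(tab)[tab >= params$min_outgroup_per_lineage]
      }
    }
    if (!is.null(fired))
      return(list(category = fired, clade = sort(cl), donors = sort(donors)))
  }
  all_tips <- phy$tip.label
  cat_f <- if (all(roles[all_tips] %in% c("query", "ingroup")))
    "ingroup_only" else "undetermined"
  list(category = cat_f, clade = NULL, donors = character(0))
}

# Random rooted annotated tree for oracle comparison, built with local code
# (cascading paste-joins), not the package's simulator.
rand_oracle_instance <- function(n_leaves, lineages = c("L1", "L2"),
                                 support_pool = c(NA, 0.3, 0.7, 0.9, 1)) {
  labs <- paste0("t", seq_len(n_leaves))
  units <- as.list(labs)
  while (length(units) > 1) {
    k <- sample.int(length(units), 2)
    sup <- sample(support_pool, 1)
    lab <- if (is.na(sup)) "" else format(sup)
    merged <- paste0("(", units[[k[1]]], ",", units[[k[2]]], ")", lab)
    units <- c(units[-k], list(merged))
  }
  nwk <- paste0(units[[1]], ";")
  # strip any accidental root label: the final join's label stays; remove it
  nwk <- sub("\\)[0-9.]*;$", ");", nwk)
  qi <- sample.int(n_leaves, 1)
  pool <- c("ingroup", "sister", paste0("outgroup:", lineages))
  role_str <- sample(pool, n_leaves, replace = TRUE)
  role_str[qi] <- "query"
  names(role_str) <- labs
  ann(nwk, role_str)
}
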