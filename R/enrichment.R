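## Validation statistics over call sets: per-lineage enrichment in HGT
## clades and the contig-length assembly-artifact check.

#' Per-lineage enrichment in HGT clades
#'
#' Tests, for each major lineage, whether it is more abundant inside HGT
#' stopping clades than expected from the taxonomic composition of the
#' respective trees. For every tree `t` contributing at least one HGT event,
#' `x_t` is the lineage's share among non-focal (sister + outgroup) leaves
#' inside the union of that tree's HGT stopping clades and `y_t` its share
#' among non-focal leaves of the whole tree; the paired differences
#' `d_t = x_t - y_t` enter a one-sided (greater) Wilcoxon signed-rank test,
#' and p-values are Benjamini-Hochberg adjusted across lineages.
#'
#' Lineages with fewer than `min_trees` usable trees, or with all-zero
#' differences, are reported with `p = NA` and excluded from the BH family.
#'
#' @param events An `hgt_events` data frame (or list of them, one per tree)
#'   as produced by [aggregate_events()]; must retain the `clade_leaves`
#'   column.
#' @param trees Named list of `annotated_gene_tree` objects, indexed by
#'   orthogroup id, covering every og_id in `events`.
#' @param lineages Lineage vocabulary to test; defaults to the union of the
#'   trees' vocabularies.
#' @param min_trees Minimum number of usable trees per lineage.
#' @param exact_limit Passed to [wilcoxon_signed_rank()].
#' @return Data frame of class `enrichment_result` with columns lineage,
#'   n_trees, W, p, p_adj, mean_x, mean_y, sorted by adjusted p (NA last).
#' @export
lineage_enrichment <- function(events, trees, lineages = NULL,
                               min_trees = 2L, exact_limit = 20L) {
  if (is.list(events) && !is.data.frame(events))
    events <- do.call(rbind, events)
  if (!NROW(events)) stop("no HGT events to test")
  if (is.null(names(trees)) || any(!nzchar(names(trees))))
    names(trees) <- vapply(trees, function(t) t$og_id, character(1))
  miss <- setdiff(unique(events$og_id), names(trees))
  if (length(miss)) stop("trees missing for orthogroups: ", paste(miss, collapse = ", "))
  if (is.null(lineages))
    lineages <- unique(unlist(lapply(trees, function(t)
      c(t$vocabulary, t$lineages[t$roles == "outgroup"]))))
  lineages <- lineages[!is.na(lineages)]
  ogs <- unique(events$og_id)
  if (length(ogs) < 2L) stop("lineage enrichment needs events from at least 2 trees")

  ## per-tree lineage shares, clade vs whole tree
  shares <- lapply(ogs, function(og) {
    at <- trees[[og]]
    clade_union <- unique(unlist(events$clade_leaves[events$og_id == og]))
    .lineage_shares(at, clade_union, lineages)
  })
  x <- do.call(rbind, lapply(shares, `[[`, "x"))
  y <- do.call(rbind, lapply(shares, `[[`, "y"))
  usable <- do.call(rbind, lapply(shares, `[[`, "usable"))

  res <- data.frame(lineage = lineages, n_trees = NA_integer_, W = NA_real_,
                    p = NA_real_, p_adj = NA_real_, mean_x = NA_real_,
                    mean_y = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_along(lineages)) {
    ok <- usable[, j]
    res$n_trees[j] <- sum(ok)
    if (sum(ok) < min_trees) next
    d <- x[ok, j] - y[ok, j]
    res$mean_x[j] <- mean(x[ok, j])
    res$mean_y[j] <- mean(y[ok, j])
    if (all(d == 0)) next
    wt <- wilcoxon_signed_rank(d, alternative = "greater", exact_limit = exact_limit)
    res$W[j] <- wt$value
    res$p[j] <- wt$p_value
  }
  in_family <- !is.na(res$p)
  if (any(in_family)) res$p_adj[in_family] <- bh_adjust(res$p[in_family])
  res <- res[order(res$p_adj, res$lineage, na.last = TRUE), ]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

.lineage_shares <- function(atree, clade_leaves, lineages) {
  roles <- atree$roles
  lin <- atree$lineages
  nonfocal <- names(roles)[roles %in% c("sister", "outgroup")]
  in_clade <- intersect(nonfocal, clade_leaves)
  denom_tree <- length(nonfocal)
  denom_clade <- length(in_clade)
  count_of <- function(leaves, L) sum(roles[leaves] == "outgroup" & lin[leaves] == L, na.rm = TRUE)
  x <- vapply(lineages, function(L)
    if (denom_clade) count_of(in_clade, L) / denom_clade else NA_real_, numeric(1))
  y <- vapply(lineages, function(L)
    if (denom_tree) count_of(nonfocal, L) / denom_tree else NA_real_, numeric(1))
  usable <- rep(denom_clade > 0 && denom_tree > 0, length(lineages))
  list(x = x, y = y, usable = usable)
}

#' Contig-length artifact check
#'
#' Compares contig lengths of HGT-candidate genes against those of
#' vertically inherited ("ancestral") genes with a two-sided Mann-Whitney U
#' test and the Vargha-Delaney A effect size. HGT calls residing on
#' significantly shorter contigs than ancestral genes would suggest uncaught
#' assembly contamination; `"no-shortening signal"` is reported iff
#' `A >= 0.5` or `p >= p_threshold`.
#'
#' @param hgt_lengths,ancestral_lengths Positive contig lengths (bp) for the
#'   two gene sets; see [contig_lengths_for_genes()] for the id join.
#' @param p_threshold Significance threshold for the interpretation string.
#' @return List with U, p_two_sided, A, n1, n2 and interpretation.
#' @export
contig_length_check <- function(hgt_lengths, ancestral_lengths, p_threshold = 0.05) {
  if (!length(hgt_lengths) || !length(ancestral_lengths))
    stop("both length vectors must be non-empty")
  if (any(hgt_lengths <= 0) || any(ancestral_lengths <= 0))
    stop("contig lengths must be positive")
  mw <- mann_whitney_u(hgt_lengths, ancestral_lengths, alternative = "two_sided")
  a <- vargha_delaney_a(hgt_lengths, ancestral_lengths)
  list(U = mw$value, p_two_sided = mw$p_value, A = a,
       n1 = length(hgt_lengths), n2 = length(ancestral_lengths),
       interpretation = if (a >= 0.5 || mw$p_value >= p_threshold)
         "no-shortening signal" else "shortening signal")
}
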