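## Reading, validating and annotating gene trees and taxonomy maps.

.ROLES <- c("query", "ingroup", "sister", "outgroup")

#' Parse a newick gene tree
#'
#' Reads a single newick statement in the dialect emitted by fast
#' approximate-ML tree builders: internal-node labels are branch supports on
#' the unit interval, not node names. Supports on a 0--100 (bootstrap
#' percentage) scale are rescaled to `[0, 1]` with a warning when any label
#' exceeds 1. Leaf edges and the root carry no support ("absent", stored as
#' `NA`). Unquoted underscores in leaf names are preserved, never converted
#' to spaces.
#'
#' @param newick_text Character scalar, one well-formed newick statement.
#' @return An object of class `c("gene_tree", "phylo")`; internal-node
#'   supports are stored in `node.label` as numerics (`NA` = absent).
#' @examples
#' tr <- parse_gene_tree("((A:0.1,B:0.2)0.95:0.3,C:0.4);")
#' node_supports(tr)
#' @export
parse_gene_tree <- function(newick_text) {
  if (!is.character(newick_text) || length(newick_text) != 1L || is.na(newick_text))
    stop("newick_text must be a single character string")
  txt <- trimws(newick_text)
  n_open <- nchar(gsub("[^(]", "", txt))
  n_close <- nchar(gsub("[^)]", "", txt))
  if (n_open != n_close)
    stop(sprintf("malformed newick: unbalanced parentheses (%d '(' vs %d ')') in '%s'",
                 n_open, n_close, .abbrev(txt)))
  tr <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) stop(sprintf("malformed newick near '%s': %s",
                                     .abbrev(txt), conditionMessage(e)), call. = FALSE)
  )
  if (is.null(tr))
    stop(sprintf("malformed newick: could not parse '%s'", .abbrev(txt)))
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("newick_text must contain exactly one tree")
    tr <- tr[[1L]]
  }
  if (is.null(tr$tip.label) || length(tr$tip.label) < 1L)
    stop("malformed newick: tree has no leaves")
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup))
    stop("duplicate leaf names: ", paste(dup, collapse = ", "))
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0, na.rm = TRUE))
    stop("negative branch lengths are not allowed")
  tr$node.label <- .normalise_supports(tr$node.label, tr$Nnode)
  class(tr) <- c("gene_tree", "phylo")
  tr
}

.abbrev <- function(x, n = 60L) if (nchar(x) > n) paste0(substr(x, 1L, n), "...") else x

## Internal labels -> numeric supports in [0,1]; "" / NA -> absent (NA).
.normalise_supports <- function(labels, nnode) {
  if (is.null(labels)) return(rep(NA_real_, nnode))
  lab <- as.character(labels)
  lab[!nzchar(lab)] <- NA_character_
  sup <- suppressWarnings(as.numeric(lab))
  bad <- !is.na(lab) & is.na(sup)
  if (any(bad))
    stop("internal-node label is not a numeric support value: ",
         paste(unique(lab[bad]), collapse = ", "))
  if (any(sup < 0, na.rm = TRUE))
    stop("support value outside [0, 1]: ", min(sup, na.rm = TRUE))
  mx <- suppressWarnings(max(sup, na.rm = TRUE))
  if (is.finite(mx) && mx > 1) {
    if (mx > 100)
      stop("support value outside [0, 1] (and not a percentage): ", mx)
    warning("internal labels exceed 1; interpreting as bootstrap percentages and rescaling to [0, 1]")
    sup <- sup / 100
  }
  sup
}

#' Extract per-internal-node support values
#'
#' @param tree A `gene_tree`/`phylo`. The first element corresponds to the
#'   root node, whose support is conventionally absent.
#' @return Numeric vector of length `tree$Nnode`; `NA` = absent.
#' @export
node_supports <- function(tree) {
  .normalise_supports(tree$node.label, tree$Nnode)
}

#' Write a gene tree as newick
#'
#' Supports are emitted as internal-node labels with 6 significant digits;
#' absent supports are omitted. Writing then re-parsing preserves topology,
#' supports (to the printed precision) and branch lengths.
#'
#' @param tree A `gene_tree`/`phylo`.
#' @param file Optional path; when `NULL` the newick string is returned.
#' @return The newick string, invisibly when `file` is given.
#' @export
write_gene_tree <- function(tree, file = NULL) {
  sup <- node_supports(tree)
  tree$node.label <- ifelse(is.na(sup), "", formatC(signif(sup, 6), format = "g", digits = 6))
  class(tree) <- "phylo"
  txt <- ape::write.tree(tree)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Read one gene tree per file from a directory or file set
#'
#' @param paths A directory (all files matching `pattern`) or a character
#'   vector of newick files.
#' @param pattern Filename regexp used when `paths` is a directory.
#' @return Named list of `gene_tree` objects; names are file basenames
#'   without extension (used as orthogroup ids downstream).
#' @export
read_gene_trees <- function(paths, pattern = "\\.(nwk|newick|tre|tree)$") {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- sort(list.files(paths, pattern = pattern, full.names = TRUE))
  if (!length(paths)) stop("no tree files found")
  out <- lapply(paths, function(p) parse_gene_tree(paste(readLines(p, warn = FALSE), collapse = "")))
  names(out) <- sub("\\.[^.]*$", "", basename(paths))
  out
}

#' Build a taxonomy map
#'
#' A taxonomy map assigns every leaf name one of four roles: `query` (a
#' focal-proteome sequence whose origin is evaluated), `ingroup` (other
#' focal-lineage sequences), `sister` (the focal lineage's closest
#' relatives) or `outgroup` (everything else, binned into major lineages).
#' The major-lineage vocabulary is the ordered set of observed outgroup
#' lineages plus any `extra_lineages`.
#'
#' @param seq_id,role,lineage Character vectors of equal length; `lineage`
#'   must be non-empty exactly for `role == "outgroup"` rows (use `NA` or
#'   `""` elsewhere).
#' @param extra_lineages Additional lineage names to append to the vocabulary.
#' @return A data frame of class `taxonomy_map` with attribute `vocabulary`.
#' @export
taxonomy_map <- function(seq_id, role, lineage = NA_character_,
                         extra_lineages = character()) {
  seq_id <- as.character(seq_id)
  role <- as.character(role)
  lineage <- as.character(lineage)
  if (length(lineage) == 1L) lineage <- rep(lineage, length(seq_id))
  if (length(seq_id) != length(role) || length(seq_id) != length(lineage))
    stop("seq_id, role and lineage must have equal lengths")
  lineage[!is.na(lineage) & !nzchar(lineage)] <- NA_character_
  bad_role <- setdiff(unique(role), .ROLES)
  if (length(bad_role))
    stop("unknown role token(s): ", paste(bad_role, collapse = ", "),
         " (expected one of ", paste(.ROLES, collapse = ", "), ")")
  dup <- unique(seq_id[duplicated(seq_id)])
  if (length(dup)) stop("duplicate seq_id: ", paste(dup, collapse = ", "))
  miss <- role == "outgroup" & is.na(lineage)
  if (any(miss))
    stop("outgroup rows require a lineage: ", paste(seq_id[miss], collapse = ", "))
  stray <- role != "outgroup" & !is.na(lineage)
  if (any(stray))
    stop("lineage must be empty unless role = outgroup: ",
         paste(seq_id[stray], collapse = ", "))
  vocab <- unique(c(lineage[role == "outgroup"], as.character(extra_lineages)))
  out <- data.frame(seq_id = seq_id, role = role, lineage = lineage,
                    stringsAsFactors = FALSE)
  attr(out, "vocabulary") <- vocab
  class(out) <- c("taxonomy_map", "data.frame")
  out
}

#' Load a taxonomy map from tab-separated text
#'
#' Expects a header row `seq_id<TAB>role<TAB>lineage`; the lineage column may
#' be empty except on outgroup rows.
#'
#' @param path Path to a TSV file (UTF-8, LF).
#' @param text Alternatively, the table content as a single string.
#' @param extra_lineages Additional lineage names appended to the vocabulary.
#' @return A `taxonomy_map`.
#' @export
load_taxonomy_map <- function(path = NULL, text = NULL, extra_lineages = character()) {
  df <- .read_tsv(path, text)
  need <- c("seq_id", "role", "lineage")
  if (!identical(names(df)[seq_along(need)], need))
    stop("taxonomy map must have header: ", paste(need, collapse = "\t"))
  taxonomy_map(df$seq_id, df$role, df$lineage, extra_lineages = extra_lineages)
}

.read_tsv <- function(path = NULL, text = NULL) {
  if (is.null(path) && is.null(text)) stop("provide path or text")
  if (!is.null(path) && !file.exists(path)) stop("file not found: ", path)
  args <- list(sep = "\t", header = TRUE, colClasses = "character",
               quote = "", comment.char = "", na.strings = NULL,
               stringsAsFactors = FALSE)
  if (!is.null(path)) args$file <- path else args$text <- text
  do.call(read.delim, args)
}

#' Attach taxonomy roles to a gene tree
#'
#' @param tree A `gene_tree`.
#' @param map A `taxonomy_map`.
#' @param og_id Orthogroup identifier for this tree.
#' @param on_missing How to handle leaves absent from the map: `"error"`
#'   (default), `"drop"` (prune them), or `"outgroup_unknown"` (assign
#'   role outgroup with lineage `"Unknown"`).
#' @return An object of class `annotated_gene_tree`: a list with elements
#'   `tree` (the possibly pruned `gene_tree`), `roles` and `lineages` (named
#'   character vectors over leaves), `og_id` and `vocabulary`.
#' @export
annotate_tree <- function(tree, map, og_id = "OG1",
                          on_missing = c("error", "drop", "outgroup_unknown")) {
  on_missing <- match.arg(on_missing)
  stopifnot(inherits(tree, "phylo"), inherits(map, "taxonomy_map"))
  tips <- tree$tip.label
  idx <- match(tips, map$seq_id)
  unmapped <- tips[is.na(idx)]
  vocab <- attr(map, "vocabulary")
  if (length(unmapped)) {
    if (on_missing == "error")
      stop("leaves missing from the taxonomy map: ", paste(unmapped, collapse = ", "))
    if (on_missing == "drop") {
      if (length(unmapped) == length(tips))
        stop("all leaves are unmapped; nothing left after dropping")
      tree <- ape::drop.tip(tree, unmapped)
      class(tree) <- c("gene_tree", "phylo")
      tree$node.label <- .normalise_supports(tree$node.label, tree$Nnode)
      tips <- tree$tip.label
      idx <- match(tips, map$seq_id)
    }
  }
  roles <- ifelse(is.na(idx), "outgroup", map$role[idx])
  lineages <- ifelse(is.na(idx), "Unknown", map$lineage[idx])
  if (on_missing == "outgroup_unknown" && any(is.na(idx)))
    vocab <- unique(c(vocab, "Unknown"))
  names(roles) <- names(lineages) <- tips
  out <- structure(
    list(tree = tree, roles = roles, lineages = lineages,
         og_id = og_id, vocabulary = vocab),
    class = "annotated_gene_tree")
  if (!any(roles == "query"))
    warning(sprintf("tree %s has no query leaves; the walk stage will refuse it", og_id))
  out
}

#' @export
print.annotated_gene_tree <- function(x, ...) {
  cat(sprintf("Annotated gene tree '%s': %d leaves (%d query, %d ingroup, %d sister, %d outgroup), %s\n",
              x$og_id, length(x$roles),
              sum(x$roles == "query"), sum(x$roles == "ingroup"),
              sum(x$roles == "sister"), sum(x$roles == "outgroup"),
              if (ape::is.rooted(x$tree)) "rooted" else "unrooted"))
  invisible(x)
}

#' Load an orthogroup membership table
#'
#' Tab-separated with header `og_id<TAB>seq_ids`, `seq_ids` comma-separated
#' (the common ortholog-clustering output dialect).
#'
#' @inheritParams load_taxonomy_map
#' @return Named list mapping orthogroup id to a character vector of members.
#' @export
load_orthogroup_table <- function(path = NULL, text = NULL) {
  df <- .read_tsv(path, text)
  if (!identical(names(df)[1:2], c("og_id", "seq_ids")))
    stop("orthogroup table must have header: og_id\tseq_ids")
  if (anyDuplicated(df$og_id)) stop("duplicate og_id in orthogroup table")
  out <- lapply(strsplit(df$seq_ids, ",", fixed = TRUE), trimws)
  names(out) <- df$og_id
  out
}

#' Load a gene-to-contig length table
#'
#' Tab-separated with header `gene_id<TAB>contig_id<TAB>contig_length_bp`.
#'
#' @inheritParams load_taxonomy_map
#' @return Data frame with columns gene_id, contig_id, contig_length_bp.
#' @export
load_contig_lengths <- function(path = NULL, text = NULL) {
  df <- .read_tsv(path, text)
  need <- c("gene_id", "contig_id", "contig_length_bp")
  if (!identical(names(df)[seq_along(need)], need))
    stop("contig-length table must have header: ", paste(need, collapse = "\t"))
  df$contig_length_bp <- as.integer(df$contig_length_bp)
  if (any(is.na(df$contig_length_bp)) || any(df$contig_length_bp <= 0))
    stop("contig_length_bp must be positive integers")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in contig-length table")
  df
}

#' Look up contig lengths for a set of genes
#'
#' Joins gene ids through the contig table, so the contig-length statistic
#' ([contig_length_check()]) can stay a pure function of two length vectors.
#'
#' @param gene_ids Character vector.
#' @param contig_table Output of [load_contig_lengths()].
#' @return Integer vector of contig lengths (bp), one per found gene.
#' @export
contig_lengths_for_genes <- function(gene_ids, contig_table) {
  idx <- match(gene_ids, contig_table$gene_id)
  if (all(is.na(idx))) stop("none of the gene ids are in the contig table")
  contig_table$contig_length_bp[idx[!is.na(idx)]]
}
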