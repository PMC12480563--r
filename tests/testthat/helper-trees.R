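# Shared fixture builders: compact role-string annotation and small trees.

# roles: named character vector, values "query", "ingroup", "sister" or
# "outgroup:<Lineage>"
make_map <- function(roles, extra_lineages = character()) {
  role <- sub(":.*$", "", unname(roles))
  lin <- ifelse(grepl(":", roles), sub("^[^:]*:", "", roles), NA_character_)
  taxonomy_map(names(roles), role, lin, extra_lineages = extra_lineages)
}

ann <- function(nwk, roles, og = "OG1", ...) {
  annotate_tree(parse_gene_tree(nwk), make_map(roles, ...), og_id = og)
}

# the worked 7-leaf example tree used across modules
example_hgt_tree <- function(sister_role = "sister") {
  ann("(((q1:1,s1:1)1.0:1,(o1:1,o2:1,o3:1)1.0:1)1.0:1,(x1:1,x2:1)1.0:1);",
      c(q1 = "query", s1 = sister_role,
        o1 = "outgroup:Stramenopila", o2 = "outgroup:Stramenopila",
        o3 = "outgroup:Stramenopila",
        x1 = "outgroup:Alveolata", x2 = "outgroup:Alveolata"))
}
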