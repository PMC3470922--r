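#' Assemble a typed, weighted physical interaction network
#'
#' Nodes are all edge endpoints; undirected pairs are canonicalized
#' (`i < j`) and duplicate edges of the same type merged, keeping the single
#' pooled-posterior weight (the maximum when true duplicates remain).
#' Directed edge types (phosphorylation, protein-DNA) between the same genes
#' are kept distinct from undirected protein-protein edges.
#'
#' @param edges Weighted edge tibble (`i`, `j`, `w`, `itype`, `directed`)
#'   from [score_edges()].
#' @param node_annotations Optional tibble (`gene`, `phenotype`,
#'   `viability`) overlaying screen phenotypes; missing genes default to
#'   `untested` / `unknown`.
#' @param complexes Optional long-form complex catalog (`complex_id`,
#'   `name`, `gene`) attached by membership.
#' @return A `physical_network`: list of `nodes`, `edges`, `complexes`
#'   tibbles.
#' @export
assemble_network <- function(edges, node_annotations = NULL,
                             complexes = NULL) {
  edges <- as_tibble(edges)
  assert_columns(edges, c("i", "j", "w", "itype", "directed"), "edges")
  if (any(!nzchar(edges$i) | !nzchar(edges$j))) {
    abort("edges reference empty gene identifiers")
  }
  assert_probability(edges$w, "w")
  und <- !edges$directed
  swap <- und & edges$i > edges$j
  tmp <- edges$i[swap]
  edges$i[swap] <- edges$j[swap]
  edges$j[swap] <- tmp
  if (nrow(edges)) {
    edges <- summarise(group_by(edges, .data$i, .data$j, .data$itype,
                                .data$directed),
                       w = max(.data$w), .groups = "drop")
  }
  edges <- arrange(edges, .data$itype, .data$i, .data$j)[
    c("i", "j", "w", "itype", "directed")]

  nodes <- tibble(gene = sort(unique(c(edges$i, edges$j))))
  if (!is.null(node_annotations)) {
    ann <- distinct(as_tibble(node_annotations), .data$gene, .keep_all = TRUE)
    nodes <- left_join(nodes, ann, by = "gene")
  }
  if (!"phenotype" %in% names(nodes)) nodes$phenotype <- NA_character_
  if (!"viability" %in% names(nodes)) nodes$viability <- NA_character_
  nodes$phenotype[is.na(nodes$phenotype)] <- "untested"
  nodes$viability[is.na(nodes$viability)] <- "unknown"
  nodes$node_kind <- "gene"

  cpx <- if (is.null(complexes)) {
    tibble(complex_id = character(), name = character(), gene = character())
  } else {
    as_tibble(complexes)[c("complex_id", "name", "gene")]
  }
  structure(list(nodes = nodes, edges = edges, complexes = cpx),
            class = "physical_network")
}

#' @export
print.physical_network <- function(x, ...) {
  cat("<physical_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (", paste(names(table(x$edges$itype)), table(x$edges$itype),
                        sep = ": ", collapse = ", "),
      "), ", dplyr::n_distinct(x$complexes$complex_id), " complexes\n",
      sep = "")
  invisible(x)
}

#' Complement hit-containing complexes with their remaining members
#'
#' For every attached complex containing at least one screen hit, members
#' that are not hits themselves are added to the network (when absent) and
#' flagged by the viability of their deletion: `lethal_member` for essential
#' genes, `reduced_fitness_member` for decreased-fitness deletions, plain
#' `gene` (phenotype `untested`) otherwise. Idempotent.
#'
#' @param network A `physical_network` with complexes attached.
#' @param hits Character vector of screen-hit genes.
#' @param viability Optional tibble (`gene`, `viability` in `viable`,
#'   `lethal`, `decreased_fitness`, `unknown`).
#' @return The augmented `physical_network`.
#' @export
complement_small_complexes <- function(network, hits, viability = NULL) {
  stopifnot(inherits(network, "physical_network"))
  cpx <- network$complexes
  if (!nrow(cpx)) return(network)
  hit_cpx <- unique(cpx$complex_id[cpx$gene %in% hits])
  members <- unique(cpx$gene[cpx$complex_id %in% hit_cpx])
  to_flag <- setdiff(members, hits)
  if (!length(to_flag)) return(network)

  via <- setNames(rep("unknown", length(to_flag)), to_flag)
  if (!is.null(viability)) {
    viability <- as_tibble(viability)
    assert_columns(viability, c("gene", "viability"), "viability")
    known <- intersect(to_flag, viability$gene)
    via[known] <- viability$viability[match(known, viability$gene)]
  }
  kind <- dplyr::case_when(via == "lethal" ~ "lethal_member",
                           via == "decreased_fitness" ~ "reduced_fitness_member",
                           TRUE ~ "gene")

  nodes <- network$nodes
  new <- setdiff(to_flag, nodes$gene)
  if (length(new)) {
    nodes <- bind_rows(nodes, tibble(gene = new, phenotype = "untested",
                                     viability = unname(via[new]),
                                     node_kind = unname(kind[match(new, to_flag)])))
  }
  present <- intersect(to_flag, network$nodes$gene)
  idx <- match(present, nodes$gene)
  nodes$node_kind[idx] <- unname(kind[match(present, to_flag)])
  nodes$viability[idx] <- ifelse(nodes$viability[idx] == "unknown",
                                 unname(via[present]), nodes$viability[idx])
  network$nodes <- arrange(nodes, .data$gene)
  network
}

#' Condense large protein complexes into single nodes
#'
#' Complexes with at least `min_size` members present in the network
#' (default 3, i.e. more than 2 genes) collapse into one complex node; genes
#' belonging to several complexes are assigned to the complex containing the
#' most screen hits, ties broken by lexicographic complex id, so each gene
#' appears in exactly one view node. Edges are re-expressed between view
#' nodes and aggregated with the maximum underlying confidence; the number
#' of underlying edges is preserved as an attribute (edges internal to a
#' complex are counted on the complex node).
#'
#' @param network A `physical_network`.
#' @param min_size Minimum complex size to condense (default 3).
#' @param hits Screen-hit genes used for the overlap-resolution rule;
#'   defaults to nodes whose phenotype is a morphology or size class.
#' @return A `condensed_view`: list of `nodes` (with `members` list column
#'   and `n_internal_edges`) and aggregated `edges` (`from`, `to`, `w`,
#'   `n_underlying`, `itypes`).
#' @export
condense_complexes <- function(network, min_size = 3, hits = NULL) {
  stopifnot(inherits(network, "physical_network"))
  if (min_size < 2) abort("`min_size` must be >= 2")
  nodes <- network$nodes
  hits <- hits %||% nodes$gene[!nodes$phenotype %in% c("untested",
                                                       "wild_type_wrinkly")]
  cpx <- filter(network$complexes, .data$gene %in% nodes$gene)

  assign_to <- character(0)
  if (nrow(cpx)) {
    hit_counts <- summarise(group_by(cpx, .data$complex_id),
                            n_hits = sum(unique(.data$gene) %in% hits),
                            .groups = "drop")
    cpx <- left_join(cpx, hit_counts, by = "complex_id")
    # per gene: complex with most hits, then lexicographically smallest id
    cpx <- arrange(cpx, .data$gene, dplyr::desc(.data$n_hits),
                   .data$complex_id)
    assigned <- distinct(cpx, .data$gene, .keep_all = TRUE)
    sizes <- table(assigned$complex_id)
    big <- names(sizes)[sizes >= min_size]
    assigned <- filter(assigned, .data$complex_id %in% big)
    assign_to <- setNames(assigned$complex_id, assigned$gene)
  }

  view_of <- setNames(nodes$gene, nodes$gene)
  view_of[names(assign_to)] <- assign_to
  kind_of <- setNames(nodes$node_kind, nodes$gene)

  gene_nodes <- nodes[!(nodes$gene %in% names(assign_to)), ]
  cpx_ids <- sort(unique(unname(assign_to)))
  members_by_cpx <- split(names(assign_to), unname(assign_to))

  e <- network$edges
  e$from <- unname(view_of[e$i])
  e$to <- unname(view_of[e$j])
  internal <- e$from == e$to
  n_internal <- table(factor(e$from[internal], levels = cpx_ids))
  ext <- e[!internal, ]
  swap <- !ext$directed & ext$from > ext$to
  tmp <- ext$from[swap]
  ext$from[swap] <- ext$to[swap]
  ext$to[swap] <- tmp
  agg <- summarise(group_by(ext, .data$from, .data$to),
                   w = max(.data$w), n_underlying = dplyr::n(),
                   itypes = paste(sort(unique(.data$itype)), collapse = "|"),
                   .groups = "drop")

  view_nodes <- bind_rows(
    tibble(node_id = gene_nodes$gene,
           node_kind = gene_nodes$node_kind,
           phenotype = gene_nodes$phenotype,
           members = as.list(gene_nodes$gene),
           n_internal_edges = 0L),
    tibble(node_id = cpx_ids,
           node_kind = "complex",
           phenotype = NA_character_,
           members = lapply(members_by_cpx[cpx_ids], sort),
           n_internal_edges = as.integer(n_internal[cpx_ids]))
  )
  structure(list(nodes = arrange(view_nodes, .data$node_id),
                 edges = arrange(agg, .data$from, .data$to),
                 min_size = min_size),
            class = "condensed_view")
}

#' @export
print.condensed_view <- function(x, ...) {
  cat("<condensed_view> ", nrow(x$nodes), " nodes (",
      sum(x$nodes$node_kind == "complex"), " complexes), ",
      nrow(x$edges), " aggregated edges\n", sep = "")
  invisible(x)
}
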