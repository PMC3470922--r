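# Edge colour classes used in network renderings: protein-protein green,
# phosphorylation blue, dephosphorylation orange, protein-DNA red.
edge_colour_classes <- c(ppi = "green", phosphorylation = "blue",
                         dephosphorylation = "orange", protein_dna = "red")

network_tables <- function(x) {
  if (inherits(x, "physical_network")) {
    edges <- mutate(x$edges, w = round(.data$w, 6),
                    colour = unname(edge_colour_classes[.data$itype]))
    list(nodes = arrange(x$nodes, .data$gene),
         edges = arrange(edges, .data$itype, .data$i, .data$j))
  } else if (inherits(x, "condensed_view")) {
    nodes <- mutate(x$nodes,
                    members = vapply(.data$members, paste, character(1),
                                     collapse = "|"))
    edges <- tibble(i = x$edges$from, j = x$edges$to,
                    w = round(x$edges$w, 6), itype = x$edges$itypes,
                    directed = FALSE,
                    colour = unname(edge_colour_classes[x$edges$itypes]),
                    n_underlying = x$edges$n_underlying)
    edges$colour[is.na(edges$colour)] <- "grey"
    list(nodes = rename(arrange(nodes, .data$node_id), gene = "node_id"),
         edges = arrange(edges, .data$i, .data$j))
  } else {
    abort("`x` must be a physical_network or condensed_view")
  }
}

#' Export a network for visualization
#'
#' Writes a `physical_network` or `condensed_view` deterministically (sorted
#' nodes and edges, weights rounded to 6 decimals) in one of three formats:
#' `sif` (Cytoscape simple interaction format, plus a companion `.eda` edge
#' attribute file carrying the weights), `graphml` (typed node and edge
#' attributes) or `json` (plain `nodes`/`edges` arrays, the data contract
#' for web viewers). Each edge carries its colour class (green
#' protein-protein, blue phosphorylation, orange dephosphorylation, red
#' protein-DNA).
#'
#' @param x A `physical_network` or `condensed_view`.
#' @param path Output file path.
#' @param format One of `"sif"`, `"graphml"`, `"json"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(x, path, format = c("sif", "graphml", "json")) {
  if (length(format) == 1 && !format %in% c("sif", "graphml", "json")) {
    abort(sprintf("unknown export format '%s'", format))
  }
  format <- match.arg(format)
  tabs <- network_tables(x)
  switch(format,
         sif = export_sif(tabs, path),
         graphml = export_graphml(tabs, path),
         json = export_json(tabs, path))
  invisible(path)
}

export_sif <- function(tabs, path) {
  e <- tabs$edges
  readr::write_lines(paste(e$i, e$itype, e$j, sep = "\t"), path)
  eda <- sub("\\.sif$", "", path)
  readr::write_lines(
    c("weight (class=java.lang.Double)",
      sprintf("%s (%s) %s = %.6f", e$i, e$itype, e$j, e$w)),
    paste0(eda, ".eda"))
  # isolated nodes are not expressible in SIF edge lines; list them singly
  isolated <- setdiff(tabs$nodes$gene, unique(c(e$i, e$j)))
  if (length(isolated)) {
    readr::write_lines(isolated, path, append = TRUE)
  }
  path
}

export_graphml <- function(tabs, path) {
  doc <- xml2::xml_new_root("graphml",
                            xmlns = "http://graphml.graphdrawing.org/xmlns")
  node_attrs <- setdiff(names(tabs$nodes), "gene")
  edge_attrs <- setdiff(names(tabs$edges), c("i", "j", "directed"))
  attr_type <- function(v) {
    if (is.numeric(v)) "double" else if (is.logical(v)) "boolean" else "string"
  }
  for (a in node_attrs) {
    xml2::xml_add_child(doc, "key", id = paste0("n_", a), `for` = "node",
                        attr.name = a, attr.type = attr_type(tabs$nodes[[a]]))
  }
  for (a in edge_attrs) {
    xml2::xml_add_child(doc, "key", id = paste0("e_", a), `for` = "edge",
                        attr.name = a, attr.type = attr_type(tabs$edges[[a]]))
  }
  graph <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "undirected")
  fmt <- function(v) {
    if (is.numeric(v)) sprintf("%.6f", v) else as.character(v)
  }
  for (r in seq_len(nrow(tabs$nodes))) {
    nd <- xml2::xml_add_child(graph, "node", id = tabs$nodes$gene[[r]])
    for (a in node_attrs) {
      xml2::xml_add_child(nd, "data", key = paste0("n_", a),
                          fmt(tabs$nodes[[a]][[r]]))
    }
  }
  for (r in seq_len(nrow(tabs$edges))) {
    ed <- xml2::xml_add_child(graph, "edge",
                              source = tabs$edges$i[[r]],
                              target = tabs$edges$j[[r]],
                              directed = tolower(as.character(
                                isTRUE(tabs$edges$directed[[r]]))))
    for (a in edge_attrs) {
      xml2::xml_add_child(ed, "data", key = paste0("e_", a),
                          fmt(tabs$edges[[a]][[r]]))
    }
  }
  xml2::write_xml(doc, path)
  path
}

export_json <- function(tabs, path) {
  payload <- list(
    nodes = tabs$nodes,
    edges = rename(tabs$edges, source = "i", target = "j")
  )
  jsonlite::write_json(payload, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  path
}

#' Re-import an exported network
#'
#' Reads a file written by [export_network()] back into a
#' `physical_network` (complex attachments are not serialized and come back
#' empty). For SIF, the companion `.eda` file is read for weights when
#' present.
#'
#' @param path File path.
#' @param format One of `"sif"`, `"graphml"`, `"json"`; guessed from the
#'   extension when omitted.
#' @return A `physical_network`.
#' @export
import_network <- function(path, format = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  if (!format %in% c("sif", "graphml", "json")) {
    abort(sprintf("unknown import format '%s'", format))
  }
  tabs <- switch(format,
                 sif = import_sif(path),
                 graphml = import_graphml(path),
                 json = import_json(path))
  net <- assemble_network(tabs$edges)
  if (!is.null(tabs$nodes) && nrow(tabs$nodes)) {
    all_genes <- tibble(gene = sort(union(net$nodes$gene, tabs$nodes$gene)))
    net$nodes <- left_join(all_genes, tabs$nodes, by = "gene")
    if (!"phenotype" %in% names(net$nodes)) net$nodes$phenotype <- "untested"
    if (!"viability" %in% names(net$nodes)) net$nodes$viability <- "unknown"
    if (!"node_kind" %in% names(net$nodes)) net$nodes$node_kind <- "gene"
  }
  net
}

import_sif <- function(path) {
  lines <- readr::read_lines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  edge_lines <- parts[lengths(parts) >= 3]
  if (!length(edge_lines)) {
    isolated <- unlist(parts[lengths(parts) == 1], use.names = FALSE)
    return(list(nodes = if (length(isolated)) tibble(gene = isolated) else NULL,
                edges = empty_edges()))
  }
  edges <- bind_rows(lapply(edge_lines, function(p) {
    tibble(i = p[[1]], itype = p[[2]], j = p[[3]])
  }))
  edges$w <- 1
  eda_path <- paste0(sub("\\.sif$", "", path), ".eda")
  if (file.exists(eda_path)) {
    eda <- readr::read_lines(eda_path)[-1]
    m <- regmatches(eda,
                    regexec("^(\\S+) \\((\\S+)\\) (\\S+) = ([0-9.eE+-]+)$", eda))
    w_tbl <- bind_rows(lapply(m, function(g) {
      tibble(i = g[[2]], itype = g[[3]], j = g[[4]], w = as.numeric(g[[5]]))
    }))
    edges <- left_join(select(edges, -"w"), w_tbl,
                       by = c("i", "itype", "j"))
    edges$w[is.na(edges$w)] <- 1
  }
  edges$directed <- edges$itype %in%
    c("phosphorylation", "dephosphorylation", "protein_dna")
  isolated <- unlist(parts[lengths(parts) == 1], use.names = FALSE)
  nodes <- if (length(isolated)) tibble(gene = isolated) else NULL
  list(nodes = nodes, edges = edges[c("i", "j", "w", "itype", "directed")])
}

import_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  keys <- xml2::xml_find_all(doc, "//key")
  key_name <- setNames(xml2::xml_attr(keys, "attr.name"),
                       xml2::xml_attr(keys, "id"))
  key_type <- setNames(xml2::xml_attr(keys, "attr.type"),
                       xml2::xml_attr(keys, "id"))
  parse_data <- function(el) {
    data <- xml2::xml_find_all(el, "./data")
    vals <- xml2::xml_text(data)
    ids <- xml2::xml_attr(data, "key")
    out <- list()
    for (s in seq_along(ids)) {
      v <- vals[[s]]
      out[[key_name[[ids[[s]]]]]] <- switch(key_type[[ids[[s]]]],
                                            double = as.numeric(v),
                                            boolean = v == "true",
                                            v)
    }
    out
  }
  node_els <- xml2::xml_find_all(doc, "//node")
  nodes <- bind_rows(lapply(node_els, function(el) {
    c(list(gene = xml2::xml_attr(el, "id")), parse_data(el))
  }))
  edge_els <- xml2::xml_find_all(doc, "//edge")
  if (!length(edge_els)) {
    return(list(nodes = nodes, edges = empty_edges()))
  }
  edges <- bind_rows(lapply(edge_els, function(el) {
    c(list(i = xml2::xml_attr(el, "source"),
           j = xml2::xml_attr(el, "target"),
           directed = identical(xml2::xml_attr(el, "directed"), "true")),
      parse_data(el))
  }))
  list(nodes = nodes, edges = edges[c("i", "j", "w", "itype", "directed")])
}

empty_edges <- function() {
  tibble(i = character(), j = character(), w = numeric(),
         itype = character(), directed = logical())
}

import_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as_tibble(payload$nodes)
  edges <- as_tibble(payload$edges)
  edges <- if (nrow(edges)) {
    rename(edges, i = "source", j = "target")[c("i", "j", "w", "itype",
                                                "directed")]
  } else empty_edges()
  list(nodes = nodes, edges = edges)
}
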