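#' Construct an ontology from term and parent tables
#'
#' An `onto_dag` holds a directed acyclic graph of ontology terms connected by
#' `is_a` edges, one rooted DAG per namespace. Ancestor closures and term
#' levels (shortest-path distance from the namespace root, root = level 1) are
#' precomputed at construction time.
#'
#' @param terms A data frame with columns `term_id`, `name`, `namespace`.
#' @param parents A named list mapping each `term_id` to a character vector of
#'   parent term ids (`is_a` edges); roots have a zero-length entry.
#' @return An object of class `onto_dag` with components `terms` (tibble),
#'   `parents`, `ancestors` (named lists) and `levels` (named integer vector).
#' @export
onto_dag <- function(terms, parents) {
  terms <- as_tibble(terms)
  assert_columns(terms, c("term_id", "name", "namespace"), "terms")
  if (anyDuplicated(terms$term_id)) {
    abort("duplicate term ids in ontology")
  }
  ids <- terms$term_id
  parents <- lapply(ids, function(id) {
    p <- unique(parents[[id]] %||% character())
    unknown <- setdiff(p, ids)
    if (length(unknown)) {
      abort(sprintf("term '%s' has unknown parent(s): %s", id,
                    paste(unknown, collapse = ", ")))
    }
    p
  })
  names(parents) <- ids

  ord <- topo_order(ids, parents)          # errors on cycles
  ancestors <- vector("list", length(ids))
  names(ancestors) <- ids
  for (id in ord) {                        # parents precede children
    ps <- parents[[id]]
    ancestors[[id]] <- unique(c(ps, unlist(ancestors[ps], use.names = FALSE)))
  }

  structure(
    list(terms = terms, parents = parents, ancestors = ancestors,
         levels = compute_levels(ids, parents, terms$namespace)),
    class = "onto_dag"
  )
}

# Kahn topological sort; aborts if the parent graph has a cycle.
topo_order <- function(ids, parents) {
  indeg <- vapply(parents, length, integer(1))
  children <- vector("list", length(ids))
  names(children) <- ids
  for (id in ids) {
    for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  }
  queue <- ids[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    id <- queue[[1L]]
    queue <- queue[-1L]
    out <- c(out, id)
    for (ch in children[[id]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != length(ids)) abort("ontology parent graph contains a cycle")
  out
}

# BFS from each namespace root; root sits at level 1.
compute_levels <- function(ids, parents, namespace) {
  lev <- setNames(rep(NA_integer_, length(ids)), ids)
  roots <- ids[vapply(parents, length, integer(1)) == 0L]
  children <- vector("list", length(ids))
  names(children) <- ids
  for (id in ids) {
    for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  }
  frontier <- roots
  lev[roots] <- 1L
  while (length(frontier)) {
    nxt <- unique(unlist(children[frontier], use.names = FALSE))
    nxt <- nxt[is.na(lev[nxt])]
    lev[nxt] <- lev[frontier[[1L]]] + 1L
    frontier <- nxt
  }
  lev
}

#' Read an OBO-format ontology file
#'
#' Parses the OBO v1.2 subset used for Gene Ontology releases: `[Term]`
#' stanzas with `id`, `name`, `namespace`, `is_a` and `is_obsolete` tags.
#' Obsolete terms are dropped; unknown tags are ignored.
#'
#' @param path Path to an OBO file.
#' @return An [onto_dag()] object.
#' @export
read_obo <- function(path) {
  lines <- readr::read_lines(path)
  starts <- which(lines == "[Term]")
  if (!length(starts)) abort("no [Term] stanzas found in OBO file")
  bounds <- c(starts, length(lines) + 1L)
  terms <- list()
  parents <- list()
  for (s in seq_along(starts)) {
    block <- lines[(bounds[s] + 1L):(bounds[s + 1L] - 1L)]
    block <- block[nzchar(block) & !startsWith(block, "[")]
    tag_split <- regmatches(block, regexpr(": ", block), invert = TRUE)
    tags <- vapply(tag_split, `[`, character(1), 1L)
    vals <- vapply(tag_split, function(x) if (length(x) > 1) x[[2L]] else "",
                   character(1))
    if (any(tags == "is_obsolete" & vals == "true")) next
    id <- vals[tags == "id"]
    if (!length(id) || !nzchar(id[[1L]])) {
      abort(sprintf("malformed [Term] stanza starting at line %d: missing id",
                    starts[s]))
    }
    id <- id[[1L]]
    isa <- vals[tags == "is_a"]
    # "GO:0000002 ! name" -> "GO:0000002"
    isa <- sub(" *!.*$", "", isa)
    terms[[id]] <- tibble(
      term_id = id,
      name = if (any(tags == "name")) vals[tags == "name"][[1L]] else id,
      namespace = if (any(tags == "namespace")) vals[tags == "namespace"][[1L]]
                  else "biological_process"
    )
    parents[[id]] <- isa
  }
  term_tbl <- bind_rows(terms)
  # drop is_a references to obsolete (absent) terms
  parents <- lapply(parents, function(p) intersect(p, term_tbl$term_id))
  onto_dag(term_tbl, parents)
}

#' Write an ontology to OBO format
#'
#' @param ontology An [onto_dag()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ontology, path) {
  stopifnot(inherits(ontology, "onto_dag"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  tm <- ontology$terms[order(ontology$terms$term_id), ]
  for (i in seq_len(nrow(tm))) {
    id <- tm$term_id[[i]]
    writeLines(c(
      "[Term]",
      paste0("id: ", id),
      paste0("name: ", tm$name[[i]]),
      paste0("namespace: ", tm$namespace[[i]]),
      paste0("is_a: ", sort(ontology$parents[[id]])),
      ""
    ), con)
  }
  invisible(path)
}

#' Term level: shortest-path depth below the namespace root
#'
#' The namespace root is level 1, its children level 2, and so on; a term
#' reachable from the root by paths of several lengths takes the shortest.
#' This is the depth convention used when restricting enrichment to a window
#' of ontology levels (e.g. levels 3 to 8).
#'
#' @param ontology An [onto_dag()].
#' @param term_ids Character vector of term ids.
#' @return Integer vector of levels.
#' @export
term_level <- function(ontology, term_ids) {
  stopifnot(inherits(ontology, "onto_dag"))
  unknown <- setdiff(term_ids, ontology$terms$term_id)
  if (length(unknown)) {
    abort(sprintf("unknown term id(s): %s", paste(unknown, collapse = ", ")))
  }
  unname(ontology$levels[term_ids])
}

#' Ancestors of ontology terms
#'
#' @param ontology An [onto_dag()].
#' @param term_ids Character vector of term ids.
#' @return Named list of character vectors of ancestor term ids (excluding the
#'   term itself).
#' @export
term_ancestors <- function(ontology, term_ids) {
  stopifnot(inherits(ontology, "onto_dag"))
  unknown <- setdiff(term_ids, ontology$terms$term_id)
  if (length(unknown)) {
    abort(sprintf("unknown term id(s): %s", paste(unknown, collapse = ", ")))
  }
  ontology$ancestors[term_ids]
}

#' @export
print.onto_dag <- function(x, ...) {
  ns <- table(x$terms$namespace)
  cat("<onto_dag> ", nrow(x$terms), " terms (",
      paste(names(ns), ns, sep = ": ", collapse = ", "), ")\n", sep = "")
  invisible(x)
}
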