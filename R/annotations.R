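#' Read gene-to-term annotations
#'
#' Accepts a two-column TSV (`gene<TAB>term_id`, no header, GAF-like subset)
#' or any TSV whose first two columns are gene and term id.
#'
#' @param path Path to the annotation TSV.
#' @return A tibble with columns `gene` and `term_id`.
#' @export
read_annotations <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        comment = "!")
  if (ncol(df) < 2) abort("annotation file needs at least two columns")
  tibble(gene = as.character(df[[1]]), term_id = as.character(df[[2]]))
}

#' Write annotations as a two-column TSV
#' @param annotations Tibble with columns `gene`, `term_id`.
#' @param path Output path.
#' @export
write_annotations <- function(annotations, path) {
  assert_columns(annotations, c("gene", "term_id"), "annotations")
  readr::write_tsv(annotations[c("gene", "term_id")], path, col_names = FALSE)
  invisible(path)
}

#' Propagate direct annotations up the ontology
#'
#' Each gene's annotation set is closed over `is_a` ancestry: a gene directly
#' annotated to a term is implicitly annotated to every ancestor of that term.
#' The closure is what term-size thresholds (e.g. the 1000-annotation rule for
#' negative training pairs) and enrichment counts operate on.
#'
#' @param annotations Tibble with columns `gene`, `term_id` (direct
#'   annotations), or an existing `annotation_set` (returned unchanged:
#'   propagation is idempotent).
#' @param ontology An [onto_dag()].
#' @return An `annotation_set`: list with `direct` and `propagated` annotation
#'   tibbles, `universe` (annotated genes), and `term_counts` (named integer
#'   vector of propagated annotation counts per term).
#' @export
propagate_annotations <- function(annotations, ontology) {
  if (inherits(annotations, "annotation_set")) return(annotations)
  stopifnot(inherits(ontology, "onto_dag"))
  annotations <- distinct(as_tibble(annotations))
  assert_columns(annotations, c("gene", "term_id"), "annotations")
  unknown <- setdiff(annotations$term_id, ontology$terms$term_id)
  if (length(unknown)) {
    abort(sprintf("annotations reference unknown term(s): %s",
                  paste(sort(unknown), collapse = ", ")))
  }
  anc <- ontology$ancestors
  direct_by_gene <- split(annotations$term_id, annotations$gene)
  prop_by_gene <- lapply(direct_by_gene, function(ts) {
    sort(unique(c(ts, unlist(anc[ts], use.names = FALSE))))
  })
  propagated <- tibble(
    gene = rep(names(prop_by_gene), lengths(prop_by_gene)),
    term_id = unlist(prop_by_gene, use.names = FALSE)
  )
  counts <- table(propagated$term_id)
  structure(
    list(direct = annotations,
         propagated = propagated,
         universe = sort(names(direct_by_gene)),
         term_counts = setNames(as.integer(counts), names(counts)),
         sets = prop_by_gene),
    class = "annotation_set"
  )
}

#' Number of genes annotated to a term after propagation
#'
#' @param annotation_set An `annotation_set` from [propagate_annotations()].
#' @param term_ids Character vector of term ids; terms with no annotations
#'   (including unknown terms) count 0.
#' @return Integer vector of annotation counts.
#' @export
annotation_count <- function(annotation_set, term_ids) {
  stopifnot(inherits(annotation_set, "annotation_set"))
  n <- annotation_set$term_counts[term_ids]
  n[is.na(n)] <- 0L
  unname(n)
}

#' Genes annotated to each term (propagated)
#'
#' @param annotation_set An `annotation_set`.
#' @param term_ids Terms to extract; defaults to all annotated terms.
#' @return Named list of character vectors of genes.
#' @export
term_genes <- function(annotation_set, term_ids = NULL) {
  stopifnot(inherits(annotation_set, "annotation_set"))
  by_term <- split(annotation_set$propagated$gene,
                   annotation_set$propagated$term_id)
  if (is.null(term_ids)) return(by_term)
  out <- by_term[term_ids]
  names(out) <- term_ids
  out[vapply(out, is.null, logical(1))] <- list(character(0))
  out
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set> ", length(x$universe), " genes, ",
      nrow(x$direct), " direct / ", nrow(x$propagated),
      " propagated annotations\n", sep = "")
  invisible(x)
}

#' Read a protein-complex catalog
#'
#' TSV with columns `complex_id`, `name`, `members` (pipe-separated gene ids);
#' a header line is required.
#'
#' @param path Path to the complex TSV.
#' @return A tibble in long form: `complex_id`, `name`, `gene`.
#' @export
read_complexes <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  assert_columns(df, c("complex_id", "name", "members"), "complex catalog")
  tidyr::unnest(
    mutate(df, gene = strsplit(.data$members, "|", fixed = TRUE)),
    "gene"
  )[c("complex_id", "name", "gene")]
}

#' Write a protein-complex catalog
#' @param complexes Long-form tibble (`complex_id`, `name`, `gene`).
#' @param path Output path.
#' @export
write_complexes <- function(complexes, path) {
  assert_columns(complexes, c("complex_id", "name", "gene"), "complexes")
  wide <- summarise(group_by(complexes, .data$complex_id, .data$name),
                    members = paste(sort(.data$gene), collapse = "|"),
                    .groups = "drop")
  readr::write_tsv(arrange(wide, .data$complex_id), path)
  invisible(path)
}

#' Read GMT-format gene sets
#'
#' Standard GMT: one set per line, `set_id<TAB>description<TAB>gene1<TAB>...`.
#'
#' @param path Path to the GMT file.
#' @return A tibble in long form: `set_id`, `name`, `gene`.
#' @export
read_gene_sets <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) {
    abort(sprintf("GMT line(s) with fewer than 3 fields: %s",
                  paste(bad, collapse = ", ")))
  }
  bind_rows(lapply(parts, function(p) {
    tibble(set_id = p[[1]], name = p[[2]], gene = unique(p[-(1:2)]))
  }))
}

#' Write gene sets in GMT format
#' @param sets Long-form tibble (`set_id`, `name`, `gene`).
#' @param path Output path.
#' @export
write_gene_sets <- function(sets, path) {
  assert_columns(sets, c("set_id", "name", "gene"), "gene sets")
  by_set <- split(sets, sets$set_id)
  lines <- vapply(by_set[sort(names(by_set))], function(s) {
    paste(c(s$set_id[[1]], s$name[[1]], sort(unique(s$gene))), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}
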