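#' Cohen's kappa agreement between two gene sets
#'
#' Chance-corrected agreement of the two membership indicators over a common
#' gene universe, from the 2x2 table (in both / A only / B only / neither):
#' `kappa = (p_o - p_e) / (1 - p_e)`. When expected agreement is 1 (both sets
#' empty or both equal to the universe) kappa is defined as 1 for identical
#' sets and 0 otherwise.
#'
#' @param set_a,set_b Character vectors of genes, subsets of `universe`.
#' @param universe Character vector: the gene universe.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  if (!length(universe)) abort("empty universe")
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (length(setdiff(set_a, universe)) || length(setdiff(set_b, universe))) {
    abort("sets must be subsets of `universe`")
  }
  N <- length(universe)
  a <- length(intersect(set_a, set_b))
  b <- length(setdiff(set_a, set_b))
  c <- length(setdiff(set_b, set_a))
  d <- N - a - b - c
  p_o <- (a + d) / N
  p_e <- ((a + b) * (a + c) + (c + d) * (b + d)) / N^2
  if (p_e >= 1) {
    return(if (setequal(set_a, set_b)) 1 else 0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Group enriched terms by kappa agreement of their gene sets
#'
#' ClueGO-style redundancy reduction: terms are connected when the kappa
#' agreement of their (in-universe) gene sets reaches `kappa_threshold`
#' (default 0.3); groups are the connected components of that graph, each
#' represented by its lowest-adjusted-p term (ties broken by term id).
#'
#' @param results A `colonynet_enrichment` tibble (columns `set_id`,
#'   `p_adjusted`).
#' @param gene_sets Named list mapping each `set_id` to its gene vector,
#'   e.g. from [term_genes()].
#' @param universe Character vector: the gene universe for the kappa tables.
#' @param kappa_threshold Minimum kappa to connect two terms (default 0.3).
#' @return Tibble of groups: `group_id`, `representative`, `n_terms`,
#'   `term_ids` (list column), `kappa_min` (smallest pairwise kappa among
#'   connected pairs in the group; 1 for singletons), ordered by the
#'   representative's `p_adjusted`. The term-to-group map is available by
#'   `tidyr::unnest()`ing `term_ids`.
#' @export
cluego_grouping <- function(results, gene_sets, universe,
                            kappa_threshold = 0.3) {
  assert_columns(results, c("set_id", "p_adjusted"), "results")
  if (kappa_threshold <= 0 || kappa_threshold > 1) {
    abort("`kappa_threshold` must be in (0, 1]")
  }
  ids <- sort(unique(results$set_id))
  missing <- setdiff(ids, names(gene_sets))
  if (length(missing)) {
    abort(sprintf("no gene set supplied for term(s): %s",
                  paste(missing, collapse = ", ")))
  }
  universe <- unique(universe)
  sets <- lapply(gene_sets[ids], intersect, y = universe)

  pairs <- if (length(ids) > 1) utils::combn(seq_along(ids), 2) else
    matrix(integer(0), nrow = 2)
  kappas <- if (ncol(pairs)) {
    apply(pairs, 2, function(idx) {
      cohen_kappa(sets[[idx[1]]], sets[[idx[2]]], universe)
    })
  } else numeric(0)
  linked <- which(kappas >= kappa_threshold)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (length(linked)) {
    g <- igraph::add_edges(g, as.vector(pairs[, linked, drop = FALSE]))
  }
  comp <- igraph::components(g)$membership

  p_by_id <- setNames(results$p_adjusted[match(ids, results$set_id)], ids)
  groups <- lapply(split(ids, comp), function(members) {
    members <- sort(members)
    rep_id <- members[order(p_by_id[members], members)][[1]]
    kmin <- 1
    if (length(members) > 1 && length(linked)) {
      in_grp <- linked[ids[pairs[1, linked]] %in% members &
                         ids[pairs[2, linked]] %in% members]
      if (length(in_grp)) kmin <- min(kappas[in_grp])
    }
    tibble(representative = rep_id, n_terms = length(members),
           term_ids = list(members), kappa_min = kmin,
           p_representative = unname(p_by_id[rep_id]))
  })
  out <- bind_rows(groups)
  out <- arrange(out, .data$p_representative, .data$representative)
  out$group_id <- sprintf("group_%03d", seq_len(nrow(out)))
  out[c("group_id", "representative", "p_representative", "n_terms",
        "term_ids", "kappa_min")]
}
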