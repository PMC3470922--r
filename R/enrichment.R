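#' Cumulative (upper-tail) hypergeometric probability
#'
#' Probability of observing at least `k` annotated genes among `n` hits drawn
#' without replacement from a universe of `N` genes of which `K` are
#' annotated, i.e. `P(X >= k)` with `X ~ Hypergeometric(N, K, n)`. This is
#' the over-representation p-value used for complex, pathway and GO term
#' association. Evaluated in log space via [stats::phyper()] (exact).
#'
#' @param k Observed overlap count(s).
#' @param K Annotated-set size(s) within the universe.
#' @param n Hit-set size(s).
#' @param N Universe size(s).
#' @return Numeric vector of upper-tail probabilities.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  check_hyper_bounds(k, K, n, N)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

check_hyper_bounds <- function(k, K, n, N) {
  if (any(K > N | n > N | K < 0 | n < 0 | N < 0)) {
    abort("hypergeometric bounds violated: need 0 <= K, n <= N")
  }
  if (any(k < 0 | k > pmin(K, n))) {
    abort("hypergeometric bounds violated: need 0 <= k <= min(K, n)")
  }
  invisible(TRUE)
}

#' Two-sided hypergeometric enrichment/depletion test
#'
#' ClueGO-style two-sided test: the smaller of the two cumulative tails at
#' the observed overlap, doubled and capped at 1. Direction is `enriched`
#' when the upper tail is the smaller (or equal) one, else `depleted`.
#'
#' @inheritParams hypergeom_upper_tail
#' @return A tibble with columns `direction` and `p`.
#' @export
two_sided_test <- function(k, K, n, N) {
  check_hyper_bounds(k, K, n, N)
  upper <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  lower <- phyper(k, K, N - K, n, lower.tail = TRUE)
  tibble(direction = ifelse(upper <= lower, "enriched", "depleted"),
         p = pmin(1, 2 * pmin(upper, lower)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in input order (monotone, capped at 1).
#' @export
bh_adjust <- function(p) {
  assert_probability(p, "p")
  p.adjust(p, method = "BH")
}

#' Bonferroni adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return `min(1, m * p)` elementwise, `m = length(p)`.
#' @export
bonferroni_adjust <- function(p) {
  assert_probability(p, "p")
  p.adjust(p, method = "bonferroni")
}

adjust_p <- function(p, correction = c("BH", "bonferroni", "none")) {
  switch(match.arg(correction),
         BH = bh_adjust(p),
         bonferroni = bonferroni_adjust(p),
         none = p)
}

#' Association of protein complexes (or any gene sets) with screen hits
#'
#' For each complex, tests whether at least as many members would be present
#' among the hits if the same number of genes had been picked at random from
#' the universe (cumulative hypergeometric upper tail). Set sizes are taken
#' after intersection with the universe; sets smaller than `min_size` in the
#' universe are not tested.
#'
#' @param complexes Long-form tibble with columns `complex_id` (or `set_id`),
#'   `name`, `gene` — a complex catalog from [read_complexes()] or pathway
#'   sets from [read_gene_sets()].
#' @param hits Character vector of hit genes; must be a subset of `universe`.
#' @param universe Character vector: the background gene universe (typically
#'   the screened deletion collection).
#' @param correction Multiple-testing correction across tested sets.
#' @param min_size Minimum in-universe set size to test (default 2).
#' @return A `colonynet_enrichment` tibble: `set_id`, `name`, `k`, `K`, `n`,
#'   `N`, `p_raw`, `p_adjusted`, `direction`, sorted by `p_adjusted` then
#'   `set_id`.
#' @export
complex_association <- function(complexes, hits, universe,
                                correction = c("BH", "bonferroni", "none"),
                                min_size = 2) {
  correction <- match.arg(correction)
  complexes <- as_tibble(complexes)
  if ("set_id" %in% names(complexes) && !"complex_id" %in% names(complexes)) {
    complexes <- rename(complexes, complex_id = "set_id")
  }
  assert_columns(complexes, c("complex_id", "gene"), "complexes")
  if (!"name" %in% names(complexes)) complexes$name <- complexes$complex_id
  universe <- unique(universe)
  hits <- unique(hits)
  if (length(setdiff(hits, universe))) {
    abort("`hits` must be a subset of `universe`")
  }
  members <- filter(distinct(complexes, .data$complex_id, .data$name,
                             .data$gene),
                    .data$gene %in% universe)
  stats_tbl <- summarise(group_by(members, .data$complex_id, .data$name),
                         K = dplyr::n_distinct(.data$gene),
                         k = sum(unique(.data$gene) %in% hits),
                         .groups = "drop")
  stats_tbl <- filter(stats_tbl, .data$K >= min_size)
  res <- tibble(
    set_id = stats_tbl$complex_id,
    name = stats_tbl$name,
    k = stats_tbl$k, K = stats_tbl$K,
    n = length(hits), N = length(universe),
    p_raw = hypergeom_upper_tail(stats_tbl$k, stats_tbl$K,
                                 length(hits), length(universe)),
    direction = "enriched"
  )
  res$p_adjusted <- adjust_p(res$p_raw, correction)
  res <- arrange(res, .data$p_adjusted, .data$p_raw, .data$set_id)
  res <- res[c("set_id", "name", "k", "K", "n", "N", "p_raw", "p_adjusted",
               "direction")]
  class(res) <- c("colonynet_enrichment", class(res))
  res
}

#' GO term enrichment over a hit set
#'
#' Tests propagated GO terms against a hit set within a background universe,
#' restricted to terms whose level (shortest-path depth from the namespace
#' root, root = 1) lies in `level_window` and whose hit coverage `k / K`
#' reaches `min_fraction`. `mode = "enrichment"` uses the one-sided
#' cumulative upper tail (BiNGO-style); `mode = "two_sided"` uses the doubled
#' smaller tail with a direction (ClueGO-style). Correction is applied across
#' tested terms only.
#'
#' @param hits Character vector of hit genes (subset of `universe`).
#' @param annotation_set An `annotation_set` from [propagate_annotations()].
#' @param ontology The [onto_dag()] the annotations refer to.
#' @param universe Background genes; defaults to the annotated universe.
#' @param level_window Integer vector `c(low, high)` of admissible term
#'   levels (default `c(3, 8)`).
#' @param min_fraction Minimum `k / K` coverage to test a term (default 0).
#' @param correction Multiple-testing correction.
#' @param mode One-sided enrichment or two-sided enrichment/depletion.
#' @param min_size Minimum in-universe term size (default 2).
#' @return A `colonynet_enrichment` tibble (as [complex_association()], plus
#'   `level`).
#' @export
go_enrichment <- function(hits, annotation_set, ontology, universe = NULL,
                          level_window = c(3, 8), min_fraction = 0,
                          correction = c("BH", "bonferroni", "none"),
                          mode = c("enrichment", "two_sided"),
                          min_size = 2) {
  correction <- match.arg(correction)
  mode <- match.arg(mode)
  stopifnot(inherits(annotation_set, "annotation_set"),
            inherits(ontology, "onto_dag"))
  universe <- unique(universe %||% annotation_set$universe)
  if (!length(universe)) abort("empty universe")
  hits <- unique(hits)
  if (length(setdiff(hits, universe))) {
    abort("`hits` must be a subset of `universe`")
  }
  genes_by_term <- term_genes(annotation_set)
  genes_by_term <- lapply(genes_by_term, intersect, y = universe)
  lev <- ontology$levels[names(genes_by_term)]
  K <- lengths(genes_by_term)
  k <- vapply(genes_by_term, function(g) sum(g %in% hits), integer(1))
  keep <- !is.na(lev) & lev >= level_window[[1]] & lev <= level_window[[2]] &
    K >= min_size & (K > 0 & k / K >= min_fraction)
  ids <- names(genes_by_term)[keep]
  nm <- setNames(ontology$terms$name, ontology$terms$term_id)

  if (mode == "enrichment") {
    p <- unname(hypergeom_upper_tail(k[keep], K[keep], length(hits),
                                     length(universe)))
    direction <- rep("enriched", sum(keep))
  } else {
    ts <- two_sided_test(k[keep], K[keep], length(hits), length(universe))
    p <- unname(ts$p)
    direction <- unname(ts$direction)
  }
  res <- tibble(
    set_id = ids, name = unname(nm[ids]), level = unname(lev[keep]),
    k = unname(k[keep]), K = unname(K[keep]),
    n = length(hits), N = length(universe),
    p_raw = p, p_adjusted = adjust_p(p, correction), direction = direction
  )
  res <- arrange(res, .data$p_adjusted, .data$p_raw, .data$set_id)
  class(res) <- c("colonynet_enrichment", class(res))
  res
}

#' Write an enrichment result table
#' @param results A `colonynet_enrichment` tibble.
#' @param path Output path (TSV).
#' @export
write_enrichment <- function(results, path) {
  readr::write_tsv(as_tibble(results), path)
  invisible(path)
}

#' Lollipop plot of enrichment results
#'
#' @param object A `colonynet_enrichment` tibble.
#' @param top Number of top sets to show (by adjusted p).
#' @param alpha Significance line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot colonynet_enrichment
#' @export
autoplot.colonynet_enrichment <- function(object, top = 20, alpha = 0.05, ...) {
  df <- head(as_tibble(object), top)
  df$label <- factor(df$name, levels = rev(unique(df$name)))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_adjusted),
                                   y = .data$label)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = -log10(.data$p_adjusted),
                                       yend = .data$label),
                          colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$k,
                                     colour = .data$direction)) +
    ggplot2::geom_vline(xintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = expression(-log[10] ~ "adjusted p"), y = NULL,
                  size = "hits in set", colour = NULL) +
    ggplot2::theme_minimal()
}
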