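#' Read an interaction table
#'
#' TSV with columns `gene_a`, `gene_b`, `itype` (one of `ppi`,
#' `phosphorylation`, `dephosphorylation`, `protein_dna`), `techniques`
#' (pipe-separated technique names), `source`, `throughput`
#' (`low`/`high`/`unknown`), `curated` (logical), `directed` (logical) and
#' optionally `binding_pvalue` (protein-DNA only).
#'
#' @param path Path to the interaction TSV.
#' @return A tibble of interaction records.
#' @export
read_interactions <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          curated = readr::col_logical(),
                          directed = readr::col_logical(),
                          .default = readr::col_character()))
  validate_interactions(df)
}

#' Write an interaction table
#' @param records Interaction record tibble.
#' @param path Output path.
#' @export
write_interactions <- function(records, path) {
  readr::write_tsv(validate_interactions(records), path)
  invisible(path)
}

validate_interactions <- function(records) {
  records <- as_tibble(records)
  assert_columns(records, c("gene_a", "gene_b", "itype", "techniques",
                            "source", "throughput", "curated", "directed"),
                 "interaction records")
  if (!"binding_pvalue" %in% names(records)) {
    records$binding_pvalue <- NA_real_
  }
  records$binding_pvalue <- as.numeric(records$binding_pvalue)
  ok_types <- c("ppi", "phosphorylation", "dephosphorylation", "protein_dna")
  bad <- setdiff(unique(records$itype), ok_types)
  if (length(bad)) {
    abort(sprintf("unknown interaction type(s): %s", paste(bad, collapse = ", ")))
  }
  if (any(!nzchar(records$gene_a) | !nzchar(records$gene_b))) {
    abort("interaction records contain empty gene identifiers")
  }
  empty_tech <- records$itype == "ppi" & !nzchar(records$techniques)
  if (any(empty_tech)) {
    abort("ppi records must carry at least one technique")
  }
  records
}

#' Positive training pairs: curated low-throughput interactions
#'
#' The positive set for the edge classifier consists of gene pairs supported
#' by at least one literature-curated record measured with a low-throughput
#' technique.
#'
#' @param records Interaction record tibble.
#' @return Tibble of unordered, deduplicated pairs (`gene_a < gene_b`).
#' @export
build_positive_set <- function(records) {
  records <- validate_interactions(records)
  sel <- filter(records, .data$curated & .data$throughput == "low")
  distinct(arrange(canonical_pairs(sel$gene_a, sel$gene_b),
                   .data$gene_a, .data$gene_b))
}

#' Negative training pairs by most-specific co-annotation size
#'
#' A candidate pair is called non-interacting when the most specific Gene
#' Ontology term the two genes share (after propagation) is a large, hence
#' uninformative, term: the minimum propagated annotation count over the
#' shared terms must reach `threshold` (default 1000). Pairs sharing no term
#' are left unclassified, pairs in `positives` are excluded, and pairs with
#' an unannotated gene are skipped with a warning.
#'
#' @param candidate_pairs Tibble with columns `gene_a`, `gene_b`.
#' @param annotation_set An `annotation_set` from [propagate_annotations()].
#' @param threshold Minimum size of the most specific shared term
#'   (default 1000).
#' @param positives Optional tibble of positive pairs to exclude.
#' @return Tibble of unordered negative pairs.
#' @export
build_negative_set <- function(candidate_pairs, annotation_set,
                               threshold = 1000, positives = NULL) {
  stopifnot(inherits(annotation_set, "annotation_set"))
  if (!is.numeric(threshold) || threshold < 1) {
    abort("`threshold` must be a positive integer")
  }
  pairs <- distinct(canonical_pairs(candidate_pairs$gene_a,
                                    candidate_pairs$gene_b))
  sets <- annotation_set$sets
  counts <- annotation_set$term_counts
  annotated <- pairs$gene_a %in% names(sets) & pairs$gene_b %in% names(sets)
  if (any(!annotated)) {
    warn(sprintf("skipping %d pair(s) with unannotated gene(s)",
                 sum(!annotated)))
    pairs <- pairs[annotated, ]
  }
  msc <- vapply(seq_len(nrow(pairs)), function(i) {
    shared <- intersect(sets[[pairs$gene_a[[i]]]], sets[[pairs$gene_b[[i]]]])
    if (!length(shared)) return(NA_real_)
    min(counts[shared])
  }, numeric(1))
  neg <- pairs[!is.na(msc) & msc >= threshold, ]
  if (!is.null(positives) && nrow(positives)) {
    neg <- neg[!pair_key(neg$gene_a, neg$gene_b) %in%
                 pair_key(positives$gene_a, positives$gene_b), ]
  }
  arrange(neg, .data$gene_a, .data$gene_b)
}

#' Train the naive Bayes edge classifier
#'
#' For each experimental technique the classifier estimates the probability
#' of observing that technique on a truly interacting pair versus a
#' non-interacting pair, with Laplace-style pseudocount smoothing. A pair's
#' evidence is the union of the distinct techniques reported for it across
#' sources; each technique enters once.
#'
#' @param records Interaction record tibble (technique evidence).
#' @param positives,negatives Pair tibbles (`gene_a`, `gene_b`) from
#'   [build_positive_set()] / [build_negative_set()].
#' @param smoothing Pseudocount added to technique counts (default 0.5).
#'   With `smoothing = 0`, techniques with a zero count in either class make
#'   the classifier degenerate; set `clamp_zero = TRUE` to clamp such
#'   probabilities instead of erroring.
#' @param prior Prior probability that an edge is true; defaults to the class
#'   balance `n_pos / (n_pos + n_neg)`.
#' @param clamp_zero Clamp zero/one probabilities under zero smoothing.
#' @return A `technique_likelihoods` object.
#' @export
train_classifier <- function(records, positives, negatives, smoothing = 0.5,
                             prior = NULL, clamp_zero = FALSE) {
  records <- validate_interactions(records)
  if (is.null(positives) || nrow(positives) == 0) {
    abort("positive training set is empty")
  }
  if (is.null(negatives) || nrow(negatives) == 0) {
    abort("negative training set is empty")
  }
  if (smoothing < 0) abort("`smoothing` must be >= 0")

  tech_by_pair <- pair_technique_sets(records)
  techniques <- sort(unique(unlist(tech_by_pair, use.names = FALSE)))
  if (!length(techniques)) abort("no technique evidence in records")

  count_class <- function(pairs) {
    keys <- unique(pair_key(pairs$gene_a, pairs$gene_b))
    present <- tech_by_pair[intersect(keys, names(tech_by_pair))]
    tab <- table(factor(unlist(present, use.names = FALSE),
                        levels = techniques))
    list(n = length(keys), counts = setNames(as.integer(tab), techniques))
  }
  pos <- count_class(positives)
  neg <- count_class(negatives)

  p_pos <- (pos$counts + smoothing) / (pos$n + 2 * smoothing)
  p_neg <- (neg$counts + smoothing) / (neg$n + 2 * smoothing)
  degenerate <- p_pos <= 0 | p_pos >= 1 | p_neg <= 0 | p_neg >= 1
  if (any(degenerate)) {
    if (!clamp_zero) {
      abort(sprintf(
        "zero-count technique(s) under zero smoothing: %s (set clamp_zero = TRUE or smoothing > 0)",
        paste(techniques[degenerate], collapse = ", ")))
    }
    eps_pos <- 0.5 / (pos$n + 1)
    eps_neg <- 0.5 / (neg$n + 1)
    p_pos <- pmin(pmax(p_pos, eps_pos), 1 - eps_pos)
    p_neg <- pmin(pmax(p_neg, eps_neg), 1 - eps_neg)
  }
  prior <- prior %||% (pos$n / (pos$n + neg$n))
  assert_probability(prior, "prior")

  structure(
    list(likelihoods = tibble(technique = techniques,
                              p_tech_given_pos = unname(p_pos),
                              p_tech_given_neg = unname(p_neg),
                              likelihood_ratio = unname(p_pos / p_neg)),
         prior_true = prior, smoothing = smoothing,
         n_pos = pos$n, n_neg = neg$n),
    class = "technique_likelihoods"
  )
}

# pair key -> sorted unique techniques pooled across records/sources
pair_technique_sets <- function(records) {
  keys <- pair_key(records$gene_a, records$gene_b)
  tech <- split_techniques(records$techniques)
  by_pair <- split(tech, keys)
  lapply(by_pair, function(x) sort(unique(unlist(x, use.names = FALSE))))
}

#' @export
print.technique_likelihoods <- function(x, ...) {
  cat("<technique_likelihoods> ", nrow(x$likelihoods),
      " techniques; prior P(true) = ", signif(x$prior_true, 4),
      " (", x$n_pos, " pos / ", x$n_neg, " neg pairs)\n", sep = "")
  print(x$likelihoods)
  invisible(x)
}

#' Naive Bayes posterior edge confidence
#'
#' Posterior probability that an interaction is real given the set of
#' distinct techniques supporting it:
#' \deqn{P(T | t_1..t_k) = \frac{\pi \prod_t P(t|T)}{\pi \prod_t P(t|T) +
#'   (1-\pi) \prod_t P(t|F)}}
#' computed on the log-odds scale. Techniques unseen in training contribute a
#' likelihood ratio of 1 and are reported with a warning.
#'
#' @param techniques Character vector of technique names (one edge), or a
#'   list of such vectors (vectorized over edges). Duplicates count once.
#' @param likelihoods A `technique_likelihoods` object.
#' @return Numeric vector of posterior probabilities.
#' @export
edge_posterior <- function(techniques, likelihoods) {
  stopifnot(inherits(likelihoods, "technique_likelihoods"))
  if (!is.list(techniques)) techniques <- list(techniques)
  lik <- likelihoods$likelihoods
  log_ratio <- setNames(log(lik$p_tech_given_pos) - log(lik$p_tech_given_neg),
                        lik$technique)
  unknown <- setdiff(unique(unlist(techniques, use.names = FALSE)),
                     names(log_ratio))
  if (length(unknown)) {
    warn(sprintf("technique(s) not seen in training treated as uninformative: %s",
                 paste(unknown, collapse = ", ")))
  }
  prior_lo <- log(likelihoods$prior_true) - log(1 - likelihoods$prior_true)
  lo <- vapply(techniques, function(ts) {
    ts <- intersect(unique(ts), names(log_ratio))
    prior_lo + sum(log_ratio[ts])
  }, numeric(1))
  stats::plogis(lo)
}

#' Fixed weights for phosphorylation and protein-DNA edges
#'
#' (De)phosphorylation edges take a fixed configured confidence (default
#' 0.8). Protein-DNA edges take `1 - binding_pvalue` when a binding p-value
#' is available (clamped into (0, 1]), else a fixed default (0.6).
#'
#' @param records Interaction records with `itype` in `phosphorylation`,
#'   `dephosphorylation` or `protein_dna`.
#' @param phospho_weight Constant for (de)phosphorylation edges.
#' @param pdna_weight Fallback constant for protein-DNA edges without a
#'   binding p-value.
#' @return Numeric vector of weights, one per record.
#' @export
assign_special_weights <- function(records, phospho_weight = 0.8,
                                   pdna_weight = 0.6) {
  records <- validate_interactions(records)
  if (any(records$itype == "ppi")) {
    abort("ppi records are weighted by the classifier, not ad hoc")
  }
  pv <- records$binding_pvalue
  if (any(!is.na(pv) & (pv < 0 | pv > 1))) {
    abort("binding_pvalue outside [0, 1]")
  }
  w <- ifelse(records$itype %in% c("phosphorylation", "dephosphorylation"),
              phospho_weight,
              ifelse(is.na(pv), pdna_weight, pmin(pmax(1 - pv, 1e-12), 1)))
  as.numeric(w)
}

#' Score all interactions into weighted edges
#'
#' Protein-protein records are pooled per unordered pair (union of distinct
#' techniques across sources) and weighted by the classifier posterior;
#' phosphorylation, dephosphorylation and protein-DNA records receive their
#' fixed weights via [assign_special_weights()]. Directed types are kept
#' distinct from undirected ppi edges between the same genes.
#'
#' @param records Interaction record tibble.
#' @param likelihoods A trained `technique_likelihoods`.
#' @inheritParams assign_special_weights
#' @return Tibble of weighted edges: `i`, `j`, `w`, `itype`, `directed`
#'   (undirected edges canonicalized with `i < j`).
#' @export
score_edges <- function(records, likelihoods, phospho_weight = 0.8,
                        pdna_weight = 0.6) {
  records <- validate_interactions(records)
  ppi <- filter(records, .data$itype == "ppi")
  special <- filter(records, .data$itype != "ppi")

  out <- list()
  if (nrow(ppi)) {
    tech_by_pair <- pair_technique_sets(ppi)
    keys <- names(tech_by_pair)
    genes <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    out$ppi <- tibble(
      i = genes[, 1], j = genes[, 2],
      w = unname(edge_posterior(tech_by_pair, likelihoods)),
      itype = "ppi", directed = FALSE
    )
  }
  if (nrow(special)) {
    special <- distinct(special, .data$gene_a, .data$gene_b, .data$itype,
                        .keep_all = TRUE)
    out$special <- tibble(
      i = special$gene_a, j = special$gene_b,
      w = unname(assign_special_weights(special, phospho_weight, pdna_weight)),
      itype = special$itype, directed = TRUE
    )
  }
  edges <- bind_rows(out)
  arrange(edges, .data$itype, .data$i, .data$j)
}

#' Trim low-confidence edges
#'
#' Removes edges whose confidence falls below `threshold`; input order is
#' preserved. Idempotent.
#'
#' @param edges Weighted edge tibble (column `w`).
#' @param threshold Minimum retained confidence, in `[0, 1]` (default 0.2).
#' @return The retained edges.
#' @export
trim_network <- function(edges, threshold = 0.2) {
  assert_columns(edges, "w", "edges")
  assert_probability(threshold, "threshold")
  edges[edges$w >= threshold, ]
}
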