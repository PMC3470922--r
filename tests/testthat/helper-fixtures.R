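# Shared fixtures and independent oracles for the test suite.

# --- tiny ontologies -------------------------------------------------------

make_terms <- function(ids) {
  tibble::tibble(term_id = ids, name = paste("term", ids),
                 namespace = "biological_process")
}

# root -> a -> b linear chain
chain_ontology <- function() {
  onto_dag(make_terms(c("root", "a", "b")),
           list(root = character(), a = "root", b = "a"))
}

# a term reachable from the root both via a short and a long path
uneven_path_ontology <- function() {
  # root(1) -> s(2) -> x ; root -> l1(2) -> l2(3) -> l3(4) -> l4(5) -> x
  onto_dag(make_terms(c("root", "s", "l1", "l2", "l3", "l4", "x")),
           list(root = character(), s = "root", l1 = "root", l2 = "l1",
                l3 = "l2", l4 = "l3", x = c("s", "l4")))
}

# small scaled-down simulation config used across tests
small_config <- function(seed = 1, ...) {
  defaults <- list(
    seed = seed, n_genes = 300, n_true_pairs = 150,
    n_false_candidates = 300, n_phospho = 10, n_pdna = 10,
    n_complexes = 15, n_lethal = 20, big_term_size = 150,
    n_expr_genes = 300, n_de = 30,
    planted_modules = tibble::tibble(
      class = c("smooth", "semi_smooth", "small", "large"),
      size = c(10L, 20L, 10L, 10L)))
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# hand-made classifier with chosen likelihoods (bypasses training)
make_likelihoods <- function(techniques, p_pos, p_neg, prior = 0.5) {
  structure(
    list(likelihoods = tibble::tibble(
           technique = techniques,
           p_tech_given_pos = p_pos,
           p_tech_given_neg = p_neg,
           likelihood_ratio = p_pos / p_neg),
         prior_true = prior, smoothing = 0.5, n_pos = 10, n_neg = 10),
    class = "technique_likelihoods")
}

# --- independent oracles ---------------------------------------------------

# ancestor closure by iterative breadth-first traversal over the parent lists
oracle_ancestors <- function(parents, id) {
  out <- character(0)
  frontier <- parents[[id]]
  while (length(frontier)) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(parents[frontier], use.names = FALSE)),
                        out)
  }
  out
}

# P(X >= k) by exhaustive enumeration of all C(N, n) draws
oracle_hyper_tail <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)   # annotated genes are 1..K
  mean(overlap >= k)
}

# BH step-up by direct formula: min over j >= i of m * p_(j) / j, capped
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(m * p[ord][i:m] / seq_len(m)[i:m]))
  }, numeric(1))
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

# classical pooled-variance two-sample t statistic for one gene
oracle_pooled_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
  (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}
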