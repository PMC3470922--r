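record_row <- function(a, b, itype = "ppi", tech = "two_hybrid",
                       throughput = "high", curated = FALSE,
                       directed = FALSE, pv = NA_real_) {
  tibble::tibble(gene_a = a, gene_b = b, itype = itype, techniques = tech,
                 source = "test", throughput = throughput, curated = curated,
                 directed = directed, binding_pvalue = pv)
}

test_that("positive set keeps curated low-throughput pairs, deduplicated", {
  recs <- dplyr::bind_rows(
    record_row("a", "b", curated = TRUE, throughput = "low"),
    record_row("b", "a", curated = FALSE, throughput = "high"),
    record_row("c", "d", curated = TRUE, throughput = "high"),
    record_row("e", "f", curated = FALSE, throughput = "low"))
  pos <- build_positive_set(recs)
  expect_equal(pos, tibble::tibble(gene_a = "a", gene_b = "b"))
})

test_that("positive set equals a record-filter scan on a random table", {
  set.seed(11)
  n <- 200
  recs <- record_row(sprintf("g%02d", sample(30, n, TRUE)),
                     sprintf("h%02d", sample(30, n, TRUE)),
                     curated = sample(c(TRUE, FALSE), n, TRUE),
                     throughput = sample(c("low", "high", "unknown"), n, TRUE))
  pos <- build_positive_set(recs)
  keep <- recs$curated & recs$throughput == "low"
  oracle <- unique(paste(pmin(recs$gene_a, recs$gene_b)[keep],
                         pmax(recs$gene_a, recs$gene_b)[keep]))
  expect_setequal(paste(pos$gene_a, pos$gene_b), oracle)
})

test_that("negative pairs require a large most-specific co-annotation", {
  # universe of 2000 genes all annotated to the root; two genes also share a
  # small specific term
  ont <- chain_ontology()
  genes <- sprintf("g%04d", 1:2000)
  ann <- dplyr::bind_rows(
    tibble::tibble(gene = genes, term_id = "root"),
    tibble::tibble(gene = c("g0001", "g0002", "g0003", "g0004", "g0005"),
                   term_id = "b"))
  aset <- propagate_annotations(ann, ont)
  pairs <- tibble::tibble(gene_a = c("g0010", "g0001"),
                          gene_b = c("g0020", "g0002"))
  neg <- build_negative_set(pairs, aset, threshold = 1000)
  # root-sharing pair is negative; the pair sharing the 5-gene term is not
  expect_equal(paste(neg$gene_a, neg$gene_b), "g0010 g0020")
  # unannotated genes are skipped with a warning
  expect_warning(
    out <- build_negative_set(tibble::tibble(gene_a = "zz", gene_b = "g0001"),
                              aset, threshold = 1000),
    "unannotated")
  expect_equal(nrow(out), 0)
})

test_that("training likelihoods follow the smoothed count formula", {
  pos_pairs <- tibble::tibble(gene_a = sprintf("p%02d", 1:10),
                              gene_b = sprintf("q%02d", 1:10))
  neg_pairs <- tibble::tibble(gene_a = sprintf("x%02d", 1:10),
                              gene_b = sprintf("y%02d", 1:10))
  # technique "gold" on every positive, never on a negative; negatives carry
  # "noise" so they are part of the recorded evidence
  recs <- dplyr::bind_rows(
    record_row(pos_pairs$gene_a, pos_pairs$gene_b, tech = "gold"),
    record_row(neg_pairs$gene_a, neg_pairs$gene_b, tech = "noise"))
  cl <- train_classifier(recs, pos_pairs, neg_pairs, smoothing = 0.5)
  gold <- cl$likelihoods[cl$likelihoods$technique == "gold", ]
  expect_equal(gold$p_tech_given_pos, 10.5 / 11)
  expect_equal(gold$p_tech_given_neg, 0.5 / 11)
  expect_equal(cl$prior_true, 0.5)

  # a technique equally frequent in both classes is uninformative
  recs2 <- dplyr::bind_rows(
    record_row(pos_pairs$gene_a, pos_pairs$gene_b, tech = "both"),
    record_row(neg_pairs$gene_a, neg_pairs$gene_b, tech = "both"))
  cl2 <- train_classifier(recs2, pos_pairs, neg_pairs)
  expect_equal(cl2$likelihoods$p_tech_given_pos,
               cl2$likelihoods$p_tech_given_neg)

  # zero smoothing with a technique absent from one class
  expect_error(train_classifier(recs, pos_pairs, neg_pairs, smoothing = 0),
               "zero-count")
  cl3 <- train_classifier(recs, pos_pairs, neg_pairs, smoothing = 0,
                          clamp_zero = TRUE)
  expect_true(all(cl3$likelihoods$p_tech_given_neg > 0))
  expect_error(train_classifier(recs, pos_pairs[0, ], neg_pairs), "empty")
})

test_that("edge posterior follows the Bayes formula", {
  # uninformative techniques return the prior
  flat <- make_likelihoods(c("a", "b"), c(0.4, 0.2), c(0.4, 0.2), prior = 0.3)
  expect_equal(edge_posterior(c("a", "b"), flat), 0.3)
  # single technique, textbook case
  lk <- make_likelihoods(c("a", "b"), c(0.9, 0.9), c(0.1, 0.1))
  expect_equal(edge_posterior("a", lk), 0.9)
  # two independent ratio-9 techniques combine to 81/82
  expect_equal(edge_posterior(c("a", "b"), lk), 81 / 82)
  # ordering of evidence is irrelevant, duplicates count once
  expect_equal(edge_posterior(c("b", "a"), lk), edge_posterior(c("a", "b"), lk))
  expect_equal(edge_posterior(c("a", "a"), lk), edge_posterior("a", lk))
  # unknown technique acts as likelihood ratio 1, with a warning
  expect_warning(p <- edge_posterior(c("a", "mystery"), lk), "mystery")
  expect_equal(p, 0.9)
})

test_that("posterior is monotone in added supportive evidence", {
  lk <- make_likelihoods(c("a", "b", "c"), c(0.5, 0.6, 0.7),
                         c(0.25, 0.2, 0.1), prior = 0.2)
  combos <- list("a", c("a", "b"), c("a", "b", "c"))
  post <- edge_posterior(combos, lk)
  expect_true(all(diff(post) > 0))
})

test_that("ad-hoc weights for phospho and protein-DNA edges", {
  expect_equal(assign_special_weights(
    record_row("a", "b", itype = "phosphorylation", directed = TRUE)), 0.8)
  expect_equal(assign_special_weights(
    record_row("a", "b", itype = "dephosphorylation", directed = TRUE),
    phospho_weight = 0.7), 0.7)
  expect_equal(assign_special_weights(
    record_row("a", "b", itype = "protein_dna", directed = TRUE, pv = 0.001)),
    0.999)
  expect_equal(assign_special_weights(
    record_row("a", "b", itype = "protein_dna", directed = TRUE)), 0.6)
  expect_error(assign_special_weights(
    record_row("a", "b", itype = "protein_dna", directed = TRUE, pv = 1.5)),
    "binding_pvalue")
  expect_error(assign_special_weights(record_row("a", "b")), "classifier")
})

test_that("score_edges pools techniques per pair and keeps types distinct", {
  pos <- tibble::tibble(gene_a = "p1", gene_b = "p2")
  neg <- tibble::tibble(gene_a = "n1", gene_b = "n2")
  recs <- dplyr::bind_rows(
    record_row("a", "b", tech = "t1"),
    record_row("b", "a", tech = "t2"),                      # same pair, 2nd source
    record_row("a", "b", itype = "phosphorylation", tech = "t1",
               directed = TRUE),
    record_row("p1", "p2", tech = "t1|t2"),
    record_row("n1", "n2", tech = "t1"))
  cl <- train_classifier(recs, pos, neg)
  edges <- score_edges(recs, cl)
  ab <- edges[edges$i == "a" & edges$j == "b", ]
  expect_setequal(ab$itype, c("ppi", "phosphorylation"))
  # pooled posterior equals the posterior of the unioned technique set
  expect_equal(ab$w[ab$itype == "ppi"],
               edge_posterior(c("t1", "t2"), cl))
  expect_equal(ab$w[ab$itype == "phosphorylation"], 0.8)
})

test_that("trimming keeps exactly the edges above threshold and is idempotent", {
  set.seed(21)
  edges <- tibble::tibble(i = "a", j = "b", w = runif(1000),
                          itype = "ppi", directed = FALSE)
  expect_equal(nrow(trim_network(edges, 0)), 1000)
  expect_equal(nrow(trim_network(edges, 1)), sum(edges$w == 1))
  t3 <- trim_network(edges, 0.3)
  expect_equal(nrow(t3), sum(edges$w >= 0.3))
  expect_identical(trim_network(t3, 0.3), t3)
  # raising the threshold never increases the count
  counts <- vapply(seq(0, 1, 0.1),
                   function(t) nrow(trim_network(edges, t)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("trained likelihood-ratio ordering recovers generative reliability ordering", {
  cfg <- sim_config(seed = 77, n_genes = 1500, n_true_pairs = 800,
                    n_false_candidates = 1500, n_phospho = 0, n_pdna = 0)
  gi <- gen_interactome(cfg)
  pos <- build_positive_set(gi$records)
  expect_gte(nrow(pos), 300)
  set.seed(78)
  neg <- gi$truth$false_pairs[sample(nrow(gi$truth$false_pairs), 600), ]
  cl <- train_classifier(gi$records, pos, neg)
  lik <- cl$likelihoods[match(cfg$techniques$name, cl$likelihoods$technique), ]
  gen_ratio <- cfg$techniques$reliability_pos / cfg$techniques$reliability_neg
  expect_equal(order(lik$likelihood_ratio), order(gen_ratio))
})
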