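test_that("hypergeometric upper tail: boundary identities and exact value", {
  expect_equal(hypergeom_upper_tail(0, 4, 3, 10), 1)
  expect_equal(hypergeom_upper_tail(3, 10, 3, 10), 1)   # K = N
  expect_equal(hypergeom_upper_tail(2, 4, 3, 10), 1 / 3)
  expect_error(hypergeom_upper_tail(5, 4, 3, 10), "bounds")
  expect_error(hypergeom_upper_tail(1, 11, 3, 10), "bounds")
})

test_that("p_raw decreases as the observed overlap grows", {
  p <- hypergeom_upper_tail(0:5, 8, 5, 30)
  expect_true(all(diff(p) < 0))
})

test_that("two-sided test doubles the smaller tail with a direction", {
  # complete depletion: k = 0 of a 5-gene set among 5 hits in 10 genes
  res <- two_sided_test(0, 5, 5, 10)
  expect_equal(res$direction, "depleted")
  expect_equal(res$p, 2 * 1 / choose(10, 5))
  # maximal overlap is enrichment
  expect_equal(two_sided_test(3, 3, 3, 10)$direction, "enriched")
  # at the mode both tails are large: capped at 1
  expect_equal(two_sided_test(2, 4, 5, 10)$p, 1)
})

test_that("BH and Bonferroni match their defining formulas", {
  expect_equal(bh_adjust(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bonferroni_adjust(0.2), 0.2)
  expect_equal(bonferroni_adjust(c(0.3, 0.4)), c(0.6, 0.8))
  expect_equal(bonferroni_adjust(c(0.7, 0.2)), c(1, 0.4))
  expect_error(bh_adjust(c(0.5, 1.2)), "probabilities")
  # adjustment never lowers a p-value and preserves ranking
  set.seed(8)
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
  expect_equal(order(bh_adjust(p), p), order(p))
})

test_that("complex association ranks a planted complex first", {
  set.seed(41)
  universe <- sprintf("g%04d", 1:1000)
  planted <- sprintf("g%04d", 1:10)
  cpx <- dplyr::bind_rows(
    tibble::tibble(complex_id = "cpx_planted", name = "planted",
                   gene = planted),
    tibble::tibble(complex_id = rep(sprintf("cpx_%02d", 1:30), each = 6),
                   name = rep(sprintf("random %d", 1:30), each = 6),
                   gene = sample(universe, 30 * 6, replace = TRUE)))
  hits <- union(planted[1:8], sample(setdiff(universe, planted), 192))
  res <- complex_association(cpx, hits, universe)
  expect_s3_class(res, "colonynet_enrichment")
  expect_equal(res$set_id[[1]], "cpx_planted")
  expect_lt(res$p_raw[[1]], 1e-3)
  # a complex disjoint from the hits scores p_raw = 1
  disj <- complex_association(
    tibble::tibble(complex_id = "d", name = "d",
                   gene = setdiff(universe, hits)[1:5]),
    hits, universe)
  expect_equal(disj$p_raw, 1)
  # single tested set: adjusted equals raw
  expect_equal(disj$p_adjusted, disj$p_raw)
  expect_error(complex_association(cpx, c(hits, "alien"), universe),
               "subset")
})

test_that("GO enrichment honours the level window and coverage filter", {
  ont <- uneven_path_ontology()   # levels: root 1, s 2, l1 2, l2 3, l3 4, l4 5, x 3
  genes <- sprintf("g%02d", 1:40)
  ann <- dplyr::bind_rows(
    tibble::tibble(gene = genes, term_id = "root"),
    tibble::tibble(gene = genes[1:10], term_id = "x"),
    tibble::tibble(gene = genes[11:30], term_id = "s"))
  aset <- propagate_annotations(ann, ont)
  hits <- genes[1:10]
  res <- go_enrichment(hits, aset, ont, level_window = c(3, 8))
  # the root (level 1) and level-2 terms are outside the window
  expect_false(any(c("root", "s", "l1") %in% res$set_id))
  expect_true("x" %in% res$set_id)
  expect_equal(res$p_raw[res$set_id == "x"],
               hypergeom_upper_tail(10, 10, 10, 40))
  expect_true(all(res$p_adjusted >= res$p_raw))
  # coverage filter: term "x" has k/K = 1; demanding more than that drops it
  res2 <- go_enrichment(hits[1], aset, ont, level_window = c(3, 8),
                        min_fraction = 0.5)
  expect_false("x" %in% res2$set_id)
  expect_error(go_enrichment(hits, aset, ont, universe = character()),
               "universe")
})

test_that("planted enriched term has the minimum p across seeds", {
  hits_found <- vapply(1:10, function(seed) {
    ga <- gen_go_and_complexes(small_config(seed = seed))
    aset <- propagate_annotations(ga$annotations, ga$ontology)
    # plant: hits concentrated in one mid-level term's genes
    tg <- term_genes(aset)
    lev <- ga$ontology$levels
    mid <- names(tg)[lev[names(tg)] >= 3 & lengths(tg) >= 15 &
                       lengths(tg) <= 60]
    target <- mid[[1 + seed %% length(mid)]]
    set.seed(seed + 1000)
    hits <- union(tg[[target]],
                  sample(aset$universe, 20))
    res <- go_enrichment(hits, aset, ga$ontology, level_window = c(3, 10))
    # the planted term must be the arg-min p term (or an ancestor thereof
    # containing the same genes); require exact id match
    res$set_id[[which.min(res$p_raw)]] == target
  }, logical(1))
  expect_gte(sum(hits_found), 9)
})

test_that("kappa agreement matches the 2x2-table definition", {
  u <- sprintf("g%02d", 1:10)
  expect_equal(cohen_kappa(u[1:4], u[1:4], u), 1)
  expect_equal(cohen_kappa(u[1:4], u[3:6], u), 1 / 6)
  expect_equal(cohen_kappa(u[1:4], u[3:6], u),
               cohen_kappa(u[3:6], u[1:4], u))
  # disjoint sets agree less than chance
  expect_lt(cohen_kappa(u[1:5], u[6:10], u), 0)
  # degenerate expected-agreement-1 cases
  expect_equal(cohen_kappa(u, u, u), 1)
  expect_equal(cohen_kappa(character(0), character(0), u), 1)
  expect_error(cohen_kappa("a", "a", character(0)), "universe")
})

test_that("kappa grouping joins redundant terms and keeps strangers apart", {
  u <- sprintf("g%03d", 1:100)
  sets <- list(fam1_a = u[1:20], fam1_b = u[2:21], fam1_c = u[1:19],
               fam2_a = u[51:70], fam2_b = u[52:71],
               loner = u[c(1, 30, 60, 90)])
  res <- tibble::tibble(set_id = names(sets),
                        p_adjusted = c(0.001, 0.002, 0.003, 0.01, 0.02, 0.04))
  groups <- cluego_grouping(res, sets, u, kappa_threshold = 0.3)
  expect_equal(nrow(groups), 3)
  byrep <- tidyr::unnest(groups, "term_ids")
  fam1 <- byrep$group_id[byrep$term_ids == "fam1_a"]
  expect_setequal(byrep$term_ids[byrep$group_id == fam1],
                  c("fam1_a", "fam1_b", "fam1_c"))
  expect_equal(groups$representative[groups$group_id == fam1], "fam1_a")
  # identical sets always share a group; sub-threshold kappas are singletons
  g2 <- cluego_grouping(res[1:2, ], list(fam1_a = u[1:20], fam1_b = u[1:20]),
                        u)
  expect_equal(nrow(g2), 1)
  g3 <- cluego_grouping(res, sets, u, kappa_threshold = 0.999)
  expect_equal(nrow(g3), length(sets))   # nothing reaches kappa 0.999
  # grouping does not depend on input order
  perm <- sample(nrow(res))
  g4 <- cluego_grouping(res[perm, ], sets, u, kappa_threshold = 0.3)
  expect_equal(lapply(groups$term_ids, sort), lapply(g4$term_ids, sort))
})

test_that("enrichment plot builds", {
  res <- complex_association(
    tibble::tibble(complex_id = c("a", "a", "b", "b"), name = c("A", "A", "B", "B"),
                   gene = c("g1", "g2", "g3", "g4")),
    c("g1", "g2"), sprintf("g%d", 1:10))
  expect_s3_class(autoplot(res), "ggplot")
})
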