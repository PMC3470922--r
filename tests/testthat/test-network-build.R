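edge_tbl <- function(i, j, w = 0.9, itype = "ppi", directed = FALSE) {
  tibble::tibble(i = i, j = j, w = w, itype = itype, directed = directed)
}

test_that("assembly canonicalizes, deduplicates and types edges", {
  net <- assemble_network(edge_tbl(c("a", "b", "c"), c("b", "c", "a")))
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 3)
  # same pair as ppi and phosphorylation stays two edges
  net2 <- assemble_network(dplyr::bind_rows(
    edge_tbl("a", "b"),
    edge_tbl("a", "b", itype = "phosphorylation", directed = TRUE)))
  expect_equal(nrow(net2$edges), 2)
  # reversed duplicate of an undirected pair collapses to one edge
  net3 <- assemble_network(edge_tbl(c("a", "b"), c("b", "a"), w = c(0.5, 0.9)))
  expect_equal(nrow(net3$edges), 1)
  expect_equal(net3$edges$w, 0.9)
  expect_error(assemble_network(edge_tbl("", "b")), "empty gene")
})

test_that("assembly dedup matches a canonical-pair scan on random edge lists", {
  set.seed(52)
  for (rep in 1:5) {
    n <- 200
    e <- edge_tbl(sprintf("g%02d", sample(25, n, TRUE)),
                  sprintf("g%02d", sample(25, n, TRUE)),
                  w = runif(n))
    e <- e[e$i != e$j, ]
    net <- assemble_network(e)
    oracle <- unique(paste(pmin(e$i, e$j), pmax(e$i, e$j)))
    expect_equal(nrow(net$edges), length(oracle))
  }
})

test_that("complementing adds flagged non-hit members of hit complexes", {
  cpx <- tibble::tibble(complex_id = c("c1", "c1", "c1", "c2", "c2"),
                        name = "x",
                        gene = c("A", "B", "C", "D", "E"))
  net <- assemble_network(edge_tbl("A", "Z"), complexes = cpx)
  via <- tibble::tibble(gene = c("B", "C"),
                        viability = c("lethal", "decreased_fitness"))
  out <- complement_small_complexes(net, hits = "A", viability = via)
  expect_true(all(c("B", "C") %in% out$nodes$gene))
  expect_equal(out$nodes$node_kind[out$nodes$gene == "B"], "lethal_member")
  expect_equal(out$nodes$node_kind[out$nodes$gene == "C"],
               "reduced_fitness_member")
  # complex without hits contributes nothing
  expect_false(any(c("D", "E") %in% out$nodes$gene))
  # idempotence
  expect_identical(complement_small_complexes(out, "A", via), out)
})

test_that("complement additions equal a set-difference oracle", {
  cfg <- small_config(seed = 14)
  ga <- gen_go_and_complexes(cfg)
  gi <- gen_interactome(cfg)
  pos <- build_positive_set(gi$records)
  cl <- train_classifier(gi$records, pos, gi$truth$false_pairs[1:100, ])
  net <- assemble_network(score_edges(gi$records, cl),
                          complexes = ga$complexes)
  hits <- sample(net$nodes$gene, 40)
  out <- complement_small_complexes(net, hits, ga$viability)
  cpx <- ga$complexes
  hit_cpx <- unique(cpx$complex_id[cpx$gene %in% hits])
  expected <- setdiff(cpx$gene[cpx$complex_id %in% hit_cpx], hits)
  expect_setequal(setdiff(out$nodes$gene, net$nodes$gene),
                  setdiff(expected, net$nodes$gene))
})

test_that("condensation collapses only complexes of three or more present genes", {
  e <- edge_tbl(c("A", "B", "C", "D"), c("B", "C", "D", "E"))
  cpx <- dplyr::bind_rows(
    tibble::tibble(complex_id = "big", name = "big", gene = c("A", "B", "C")),
    tibble::tibble(complex_id = "duo", name = "duo", gene = c("D", "E")))
  net <- assemble_network(e, complexes = cpx)
  cv <- condense_complexes(net)
  expect_true("big" %in% cv$nodes$node_id)
  expect_false("duo" %in% cv$nodes$node_id)
  expect_true(all(c("D", "E") %in% cv$nodes$node_id))
  expect_false(any(c("A", "B", "C") %in% cv$nodes$node_id))
  # gene conservation
  expect_setequal(unname(unlist(cv$nodes$members)), net$nodes$gene)
})

test_that("overlapping complexes resolve by most-hits then lexicographic id", {
  genes <- c("A", "B", "C", "D", "E", "F", "G")
  e <- edge_tbl(genes[-7], genes[-1])
  cpx <- dplyr::bind_rows(
    tibble::tibble(complex_id = "c_one", name = "1",
                   gene = c("A", "B", "C", "D")),
    tibble::tibble(complex_id = "c_two", name = "2",
                   gene = c("D", "E", "F", "G")))
  net <- assemble_network(e, complexes = cpx)
  # c_two holds 2 hits vs 1 in c_one: shared gene D goes to c_two
  cv <- condense_complexes(net, hits = c("A", "E", "F"))
  members <- setNames(cv$nodes$members, cv$nodes$node_id)
  expect_true("D" %in% members[["c_two"]])
  expect_false("D" %in% members[["c_one"]])
  # equal hit counts: lexicographically smaller id wins
  cv2 <- condense_complexes(net, hits = c("A", "E"))
  members2 <- setNames(cv2$nodes$members, cv2$nodes$node_id)
  expect_true("D" %in% members2[["c_one"]])
  # every gene lands in exactly one view node
  expect_setequal(unname(unlist(cv$nodes$members)), net$nodes$gene)
  expect_equal(anyDuplicated(unname(unlist(cv$nodes$members))), 0L)
})

test_that("aggregated edges carry max weight and underlying count", {
  e <- dplyr::bind_rows(
    edge_tbl("A", "X", w = 0.5),
    edge_tbl("B", "X", w = 0.8),
    edge_tbl("A", "B", w = 0.9),   # internal to the complex
    edge_tbl("C", "X", w = 0.3))
  cpx <- tibble::tibble(complex_id = "abc", name = "abc",
                        gene = c("A", "B", "C"))
  cv <- condense_complexes(assemble_network(e, complexes = cpx))
  agg <- cv$edges[(cv$edges$from == "abc" & cv$edges$to == "X") |
                    (cv$edges$from == "X" & cv$edges$to == "abc"), ]
  expect_equal(agg$w, 0.8)
  expect_equal(agg$n_underlying, 3L)
  expect_equal(cv$nodes$n_internal_edges[cv$nodes$node_id == "abc"], 1L)
})

test_that("exports are deterministic and round-trip through all formats", {
  cfg <- small_config(seed = 6)
  gi <- gen_interactome(cfg)
  pos <- build_positive_set(gi$records)
  cl <- train_classifier(gi$records, pos, gi$truth$false_pairs[1:100, ])
  scr <- gen_screen(cfg)
  calls <- suppressMessages(screen_consensus(scr$screen))
  net <- assemble_network(
    trim_network(score_edges(gi$records, cl), 0.2),
    tibble::tibble(gene = calls$gene, phenotype = calls$consensus))
  d <- withr::local_tempdir()
  for (fmt in c("sif", "graphml", "json")) {
    p1 <- file.path(d, paste0("net1.", fmt))
    p2 <- file.path(d, paste0("net2.", fmt))
    export_network(net, p1, fmt)
    export_network(net, p2, fmt)
    expect_identical(readLines(p1), readLines(p2))
    back <- import_network(p1)
    expect_setequal(back$nodes$gene, net$nodes$gene)
    a <- dplyr::arrange(net$edges, itype, i, j)
    b <- dplyr::arrange(back$edges, itype, i, j)
    expect_equal(nrow(a), nrow(b))
    expect_equal(round(a$w, 6), b$w, tolerance = 1e-9)
    expect_equal(a$itype, b$itype)
    expect_equal(a$directed, b$directed)
    # phenotype attributes survive graphml and json
    if (fmt != "sif") {
      expect_equal(back$nodes$phenotype[match(net$nodes$gene,
                                              back$nodes$gene)],
                   net$nodes$phenotype)
    }
  }
  expect_error(export_network(net, file.path(d, "x.foo"), "foo"), "format")
})

test_that("an empty network exports valid files", {
  net <- assemble_network(edge_tbl(character(), character(), w = numeric(),
                                   itype = character(), directed = logical()))
  d <- withr::local_tempdir()
  for (fmt in c("sif", "graphml", "json")) {
    p <- file.path(d, paste0("empty.", fmt))
    export_network(net, p, fmt)
    expect_true(file.exists(p))
  }
  back <- import_network(file.path(d, "empty.json"))
  expect_equal(nrow(back$edges), 0)
})
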