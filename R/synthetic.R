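#' Simulation configuration for the synthetic study
#'
#' Bundles every parameter of the synthetic data generators. Defaults mirror
#' the study conditions the pipeline is built for: a deletion collection of
#' 4156 non-essential genes screened in triplicate, with 52 smooth, 159
#' semi-smooth and 268 size-class hit genes planted; an interactome reported
#' by several techniques of unequal reliability; a rooted GO-like DAG with at
#' least one >= 1000-annotation term (so the negative-training rule has
#' material to work with); and a two-genotype x two-media expression design
#' with replicated arrays and planted fold changes.
#'
#' @param seed Integer seed; every generator derives its RNG stream from it.
#' @param n_genes Size of the screened gene universe (default 4156).
#' @param techniques Tibble with `name`, `reliability_pos` (detection
#'   probability on a true pair) and `reliability_neg` (on a false pair).
#' @param n_true_pairs,n_false_candidates True interactions and
#'   non-interacting candidate pairs eligible for (false) reports.
#' @param curated_low_frac Fraction of true pairs additionally backed by a
#'   literature-curated low-throughput record.
#' @param n_phospho,n_pdna Planted (de)phosphorylation and protein-DNA
#'   interactions.
#' @param n_complexes,complex_size_range Protein-complex catalog size and
#'   membership range.
#' @param n_lethal,lethal_frac Pool of essential genes (absent from the
#'   deletion collection) and their rate among complex members.
#' @param go_depth,go_branching,terms_per_gene,big_term_size GO DAG shape,
#'   direct annotations per gene, and the size of the planted large term.
#' @param n_pathways,pathway_size_range Pathway gene-set catalog.
#' @param planted_modules Tibble (`class`, `size`) of planted phenotype
#'   modules.
#' @param penetrance Probability that a planted gene shows its class in one
#'   replicate.
#' @param miscall_rate Probability that a non-planted gene is miscalled in
#'   one replicate.
#' @param n_de,log2_effect,replicates Planted differentially expressed genes,
#'   their log2 effect size, and arrays per condition cell.
#' @param d0,s0_sq Scaled-inverse-chi-square variance prior for expression
#'   noise (the conjugate form the moderated-t model assumes).
#' @param absent_frac Fraction of absent detection calls.
#' @param n_expr_genes Genes on the synthetic array (default 2000).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 4156,
                       techniques = default_techniques(),
                       n_true_pairs = 1500,
                       n_false_candidates = 3000,
                       curated_low_frac = 0.4,
                       n_phospho = 60,
                       n_pdna = 80,
                       n_complexes = 60,
                       complex_size_range = c(2, 12),
                       n_lethal = 150,
                       lethal_frac = 0.05,
                       go_depth = 5,
                       go_branching = 3,
                       terms_per_gene = c(1, 3),
                       big_term_size = 1200,
                       n_pathways = 20,
                       pathway_size_range = c(5, 50),
                       planted_modules = default_planted_modules(),
                       penetrance = 0.9,
                       miscall_rate = 0.01,
                       n_de = 200,
                       log2_effect = 2,
                       replicates = 3,
                       d0 = 4,
                       s0_sq = 0.04,
                       absent_frac = 0.05,
                       n_expr_genes = 2000) {
  if (go_depth < 3) abort("`go_depth` must be >= 3 (level window needs depth)")
  if (penetrance <= 0 || penetrance > 1) abort("`penetrance` must be in (0, 1]")
  if (replicates < 2) abort("`replicates` must be >= 2")
  techniques <- as_tibble(techniques)
  assert_columns(techniques, c("name", "reliability_pos", "reliability_neg"),
                 "techniques")
  if (nrow(techniques) < 2) abort("need >= 2 techniques")
  if (all(techniques$reliability_pos == techniques$reliability_neg)) {
    warn("all techniques equally reliable on true and false pairs: classifier unidentifiable")
  }
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' Default technique reliability table
#'
#' Four techniques of increasing specificity (decreasing false-report rate),
#' giving well-separated true/false likelihood ratios.
#'
#' @return Tibble with `name`, `reliability_pos`, `reliability_neg`.
#' @export
default_techniques <- function() {
  tibble(name = c("two_hybrid", "affinity_capture_ms",
                  "affinity_capture_western", "reconstituted_complex"),
         reliability_pos = c(0.55, 0.50, 0.45, 0.35),
         reliability_neg = c(0.30, 0.10, 0.03, 0.008))
}

#' Default planted phenotype modules
#'
#' Hit-class sizes matching the screened collection: 52 smooth, 159
#' semi-smooth, and 268 size-class genes (split small/large).
#'
#' @return Tibble with `class` and `size`.
#' @export
default_planted_modules <- function() {
  tibble(class = c("smooth", "semi_smooth", "small", "large"),
         size = c(52L, 159L, 134L, 134L))
}

sim_genes <- function(config) sprintf("g%04d", seq_len(config$n_genes))

# sample integers uniformly from an inclusive range (safe for width-1 ranges)
sample_int_range <- function(range, n) {
  vals <- seq(range[[1]], range[[2]])
  vals[sample.int(length(vals), n, replace = TRUE)]
}
sim_lethal <- function(config) sprintf("l%03d", seq_len(config$n_lethal))

# sample `n` distinct unordered pairs from `genes`, excluding `exclude` keys
sample_pairs <- function(genes, n, exclude = character()) {
  got <- tibble(gene_a = character(), gene_b = character())
  seen <- exclude
  while (nrow(got) < n) {
    a <- sample(genes, 2 * n, replace = TRUE)
    b <- sample(genes, 2 * n, replace = TRUE)
    keep <- a != b
    cand <- distinct(canonical_pairs(a[keep], b[keep]))
    cand <- cand[!pair_key(cand$gene_a, cand$gene_b) %in% seen, ]
    got <- bind_rows(got, cand)
    seen <- c(seen, pair_key(cand$gene_a, cand$gene_b))
  }
  got[seq_len(n), ]
}

#' Generate a synthetic interactome with technique evidence
#'
#' True and false gene pairs are sampled; each technique reports a pair with
#' probability `reliability_pos` if it is a true interaction and
#' `reliability_neg` if not, one record per (pair, technique) report. A
#' fraction of true pairs carries an additional literature-curated
#' low-throughput record (the positive-training signal); planted
#' (de)phosphorylation and protein-DNA records are appended.
#'
#' @param config A [sim_config()].
#' @return List with `records` (interaction tibble) and `truth` (list:
#'   `true_pairs`, `curated_pairs`, `reported` with an `is_true` flag,
#'   `techniques`).
#' @export
gen_interactome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- sim_genes(config)
  true_pairs <- sample_pairs(genes, config$n_true_pairs)
  false_pairs <- sample_pairs(genes, config$n_false_candidates,
                              exclude = pair_key(true_pairs$gene_a,
                                                 true_pairs$gene_b))
  tech <- config$techniques
  report_class <- function(pairs, p, is_true) {
    bind_rows(lapply(seq_len(nrow(tech)), function(t) {
      hit <- runif(nrow(pairs)) < p[[t]]
      if (!any(hit)) return(NULL)
      tibble(gene_a = pairs$gene_a[hit], gene_b = pairs$gene_b[hit],
             itype = "ppi", techniques = tech$name[[t]],
             source = "simulated_db", throughput = "high", curated = FALSE,
             directed = FALSE, binding_pvalue = NA_real_, is_true = is_true)
    }))
  }
  reports <- bind_rows(report_class(true_pairs, tech$reliability_pos, TRUE),
                       report_class(false_pairs, tech$reliability_neg, FALSE))

  n_cur <- round(config$curated_low_frac * nrow(true_pairs))
  cur_idx <- sample(nrow(true_pairs), n_cur)
  curated <- true_pairs[cur_idx, ]
  curated_records <- tibble(
    gene_a = curated$gene_a, gene_b = curated$gene_b, itype = "ppi",
    techniques = sample(tech$name, n_cur, replace = TRUE),
    source = "curated_literature", throughput = "low", curated = TRUE,
    directed = FALSE, binding_pvalue = NA_real_, is_true = TRUE)

  phos <- sample_pairs(genes, config$n_phospho + config$n_pdna)
  phospho_records <- tibble(
    gene_a = phos$gene_a[seq_len(config$n_phospho)],
    gene_b = phos$gene_b[seq_len(config$n_phospho)],
    itype = rep_len(c("phosphorylation", "dephosphorylation"),
                    config$n_phospho),
    techniques = "biochemical_activity", source = "curated_literature",
    throughput = "low", curated = TRUE, directed = TRUE,
    binding_pvalue = NA_real_, is_true = TRUE)
  pdna_idx <- config$n_phospho + seq_len(config$n_pdna)
  pdna_records <- tibble(
    gene_a = phos$gene_a[pdna_idx], gene_b = phos$gene_b[pdna_idx],
    itype = "protein_dna", techniques = "chip_chip",
    source = "simulated_chip", throughput = "high", curated = FALSE,
    directed = TRUE,
    binding_pvalue = ifelse(runif(config$n_pdna) < 0.8,
                            round(runif(config$n_pdna, 0, 0.05), 6),
                            NA_real_),
    is_true = TRUE)

  records <- bind_rows(reports, curated_records, phospho_records,
                       pdna_records)
  records <- arrange(records, .data$itype, .data$gene_a, .data$gene_b,
                     .data$techniques, .data$source)
  truth <- list(true_pairs = true_pairs, curated_pairs = curated,
                false_pairs = false_pairs,
                reported = distinct(records[c("gene_a", "gene_b", "itype",
                                              "is_true")]),
                techniques = tech)
  list(records = select(records, -"is_true"), truth = truth)
}

#' Generate a synthetic GO DAG, annotations, complexes and pathways
#'
#' Builds one rooted `biological_process` DAG of the configured depth and
#' branching (some terms get a second parent, making it a genuine DAG),
#' annotates genes to leaf terms, plants one large term annotated by
#' `big_term_size` genes (exercising the >= 1000-annotation negative-pair
#' rule at full scale), and samples protein complexes (sizes spanning the
#' configured range, occasionally including essential genes) plus pathway
#' gene sets.
#'
#' @param config A [sim_config()].
#' @return List with `ontology` ([onto_dag()]), `annotations`, `complexes`,
#'   `pathways`, `viability` tibbles and `truth` (planted big term id).
#' @export
gen_go_and_complexes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  genes <- sim_genes(config)

  counter <- 0L
  new_id <- function(n) {
    ids <- sprintf("GO:%07d", counter + seq_len(n))
    counter <<- counter + n
    ids
  }
  levels <- list(new_id(1))
  parents <- list()
  parents[[levels[[1]]]] <- character()
  for (l in 2:config$go_depth) {
    n_l <- min(config$go_branching^(l - 1), 64L)
    ids <- new_id(n_l)
    prev <- levels[[l - 1]]
    for (id in ids) {
      p <- sample(prev, 1)
      if (l > 2 && runif(1) < 0.25) {
        extra_level <- sample(seq_len(l - 1), 1)
        p <- unique(c(p, sample(levels[[extra_level]], 1)))
      }
      parents[[id]] <- p
    }
    levels[[l]] <- ids
  }
  all_ids <- unlist(levels, use.names = FALSE)
  terms <- tibble(term_id = all_ids,
                  name = paste0("process ", sub("GO:0*", "", all_ids)),
                  namespace = "biological_process")
  ontology <- onto_dag(terms, parents)

  leaves <- levels[[config$go_depth]]
  n_terms <- sample_int_range(config$terms_per_gene, length(genes))
  annotations <- tibble(
    gene = rep(genes, n_terms),
    term_id = unlist(lapply(n_terms, sample, x = leaves), use.names = FALSE)
  )
  big_term <- levels[[2]][[1]]
  big_n <- min(config$big_term_size, length(genes))
  annotations <- distinct(bind_rows(
    annotations,
    tibble(gene = sample(genes, big_n), term_id = big_term)))

  lethal <- sim_lethal(config)
  sizes <- sample_int_range(config$complex_size_range, config$n_complexes)
  complexes <- bind_rows(lapply(seq_len(config$n_complexes), function(i) {
    n_leth <- rbinom(1, sizes[[i]], config$lethal_frac)
    members <- c(sample(genes, sizes[[i]] - n_leth),
                 if (n_leth) sample(lethal, min(n_leth, length(lethal))))
    tibble(complex_id = sprintf("complex_%03d", i),
           name = sprintf("complex %d", i), gene = members)
  }))
  psizes <- sample_int_range(config$pathway_size_range, config$n_pathways)
  pathways <- bind_rows(lapply(seq_len(config$n_pathways), function(i) {
    tibble(set_id = sprintf("pathway_%02d", i),
           name = sprintf("pathway %d", i),
           gene = sample(genes, psizes[[i]]))
  }))
  viability <- bind_rows(
    tibble(gene = lethal, viability = "lethal"),
    tibble(gene = genes,
           viability = ifelse(runif(length(genes)) < 0.05,
                              "decreased_fitness", "viable")))
  list(ontology = ontology, annotations = annotations, complexes = complexes,
       pathways = pathways, viability = viability,
       truth = list(big_term = big_term))
}

#' Generate a synthetic triplicate phenotype screen
#'
#' Planted module genes show their phenotype class in each replicate with
#' probability `penetrance` (wild-type wrinkly otherwise); non-planted genes
#' are wild type up to a small per-replicate miscall rate.
#'
#' @param config A [sim_config()].
#' @return List with `screen` (tibble `gene`, `code1`..`code3`) and `truth`
#'   (tibble `gene`, `class` for planted genes).
#' @export
gen_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  genes <- sim_genes(config)
  mods <- as_tibble(config$planted_modules)
  assert_columns(mods, c("class", "size"), "planted_modules")
  if (anyDuplicated(mods$class)) {
    abort("planted modules must have distinct phenotype classes")
  }
  if (sum(mods$size) > length(genes)) abort("planted modules exceed universe")
  planted_genes <- sample(genes, sum(mods$size))
  truth <- tibble(gene = planted_genes,
                  class = rep(mods$class, mods$size))
  class_of <- setNames(rep("wild_type_wrinkly", length(genes)), genes)
  class_of[truth$gene] <- truth$class
  alt_codes <- setdiff(phenotype_codes(), "wild_type_wrinkly")
  draw_rep <- function() {
    planted <- class_of != "wild_type_wrinkly"
    code <- ifelse(planted & runif(length(genes)) < config$penetrance,
                   class_of, "wild_type_wrinkly")
    mis <- !planted & runif(length(genes)) < config$miscall_rate
    code[mis] <- sample(alt_codes, sum(mis), replace = TRUE)
    unname(code)
  }
  screen <- tibble(gene = genes, code1 = draw_rep(), code2 = draw_rep(),
                   code3 = draw_rep())
  list(screen = screen, truth = arrange(truth, .data$gene))
}

#' Generate a synthetic two-genotype, two-media expression experiment
#'
#' Per-gene variances are drawn from a scaled inverse-chi-square prior with
#' `d0` degrees of freedom and scale `s0_sq` (the conjugate form the
#' moderated-t model assumes); planted differentially expressed genes gain
#' `+/- log2_effect` in the mutant samples of their medium (`liquid`,
#' `solid` or `both`); a configured fraction of detection calls is absent.
#'
#' @param config A [sim_config()].
#' @return List with `expression` (an [expression_set()]) and `truth`
#'   (tibble `gene`, `medium`, `sign`, `effect`).
#' @export
gen_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  genes <- sprintf("g%04d", seq_len(min(config$n_expr_genes, config$n_genes)))
  n_g <- length(genes)
  sigma2 <- if (is.infinite(config$d0)) rep(config$s0_sq, n_g) else
    config$s0_sq * config$d0 / rchisq(n_g, df = config$d0)
  mu <- rnorm(n_g, mean = 7.5, sd = 1.2)

  n_de <- min(config$n_de, n_g)
  de_genes <- sample(genes, n_de)
  de_medium <- sample(c("liquid", "solid", "both"), n_de, replace = TRUE,
                      prob = c(0.35, 0.35, 0.3))
  de_sign <- sample(c(-1, 1), n_de, replace = TRUE)
  truth <- tibble(gene = de_genes, medium = de_medium, sign = de_sign,
                  effect = de_sign * config$log2_effect)

  samples <- tidyr::expand_grid(medium = c("liquid", "solid"),
                                genotype = c("wt", "flo11_del"),
                                rep = seq_len(config$replicates))
  samples$sample <- sprintf("%s_%s_%d", samples$medium, samples$genotype,
                            samples$rep)
  values <- matrix(NA_real_, n_g, nrow(samples),
                   dimnames = list(genes, samples$sample))
  effect_in <- function(medium) {
    eff <- setNames(rep(0, n_g), genes)
    sel <- truth$medium %in% c(medium, "both")
    eff[truth$gene[sel]] <- truth$effect[sel]
    eff
  }
  for (s in seq_len(nrow(samples))) {
    eff <- if (samples$genotype[[s]] == "flo11_del")
      effect_in(samples$medium[[s]]) else 0
    values[, s] <- rnorm(n_g, mean = mu + eff, sd = sqrt(sigma2))
  }
  detection <- matrix(runif(n_g * nrow(samples)) >= config$absent_frac,
                      n_g, nrow(samples), dimnames = dimnames(values))
  es <- expression_set(values, samples[c("sample", "genotype", "medium")],
                       detection)
  list(expression = es, truth = truth)
}
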