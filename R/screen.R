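#' Phenotype vocabulary of the colony-morphology screen
#'
#' Colony classes scored in the deletion-collection screen: the wild-type
#' wrinkly morphology, the morphology-altering classes (smooth, semi-smooth,
#' extra wrinkly) and the size classes (small, large).
#'
#' @return Character vector of valid phenotype codes.
#' @export
phenotype_codes <- function() {
  c("wild_type_wrinkly", "smooth", "semi_smooth", "extra_wrinkly",
    "small", "large")
}

#' Read a triplicate screen phenotype table
#'
#' TSV with columns `gene`, `code1`, `code2`, `code3` (header required),
#' one row per deletion strain pinned in triplicate.
#'
#' @param path Path to the phenotype TSV.
#' @return A tibble with columns `gene`, `code1`, `code2`, `code3`.
#' @export
read_screen <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  assert_columns(df, c("gene", "code1", "code2", "code3"), "screen table")
  df
}

#' Write a screen phenotype table
#' @param screen Tibble with `gene`, `code1`, `code2`, `code3`.
#' @param path Output path.
#' @export
write_screen <- function(screen, path) {
  assert_columns(screen, c("gene", "code1", "code2", "code3"), "screen table")
  readr::write_tsv(screen[c("gene", "code1", "code2", "code3")], path)
  invisible(path)
}

#' Consensus phenotype call from triplicate codes
#'
#' A strain's phenotype is the strict majority code over its three replicate
#' pinnings (at least 2 of 3 agreeing); with three distinct codes the call is
#' `"ambiguous"`. The call is invariant to replicate order.
#'
#' @param code1,code2,code3 Character vectors of phenotype codes (recycled
#'   together), each a value of [phenotype_codes()].
#' @return Character vector of consensus codes (or `"ambiguous"`).
#' @export
consensus_call <- function(code1, code2, code3) {
  codes <- cbind(code1, code2, code3)
  bad <- setdiff(unique(as.vector(codes)), phenotype_codes())
  if (length(bad)) {
    abort(sprintf("unknown phenotype code(s): %s (valid: %s)",
                  paste(bad, collapse = ", "),
                  paste(phenotype_codes(), collapse = ", ")))
  }
  apply(codes, 1L, function(x) {
    tab <- sort(table(x), decreasing = TRUE)
    if (tab[[1]] >= 2L) names(tab)[[1]] else "ambiguous"
  })
}

#' Consensus calls for a whole screen table
#'
#' @param screen Tibble with columns `gene`, `code1`, `code2`, `code3`.
#' @return The input with a `consensus` column appended; ambiguous strains
#'   are reported with a message.
#' @export
screen_consensus <- function(screen) {
  assert_columns(screen, c("gene", "code1", "code2", "code3"), "screen")
  out <- mutate(as_tibble(screen),
                consensus = consensus_call(.data$code1, .data$code2,
                                           .data$code3))
  n_amb <- sum(out$consensus == "ambiguous")
  if (n_amb > 0) {
    inform(sprintf("%d gene(s) with ambiguous triplicate calls excluded from hit classes",
                   n_amb))
  }
  out
}

#' Select morphology and size hit sets from consensus calls
#'
#' Morphology hits are strains called smooth or semi-smooth; size hits are
#' strains called small or large. Genes on the exclusion list (dubious ORFs,
#' putative proteins) are removed from the hit sets and reported separately.
#'
#' @param calls Tibble with columns `gene` and `consensus` (from
#'   [screen_consensus()]).
#' @param exclude Character vector of genes to exclude from hit sets.
#' @return A `hit_selection`: list with `morphology_hits`, `size_hits`,
#'   `extra_wrinkly_hits`, `excluded`, `ambiguous` (character vectors) and a
#'   `counts` tibble of per-class totals.
#' @export
select_hits <- function(calls, exclude = character()) {
  assert_columns(calls, c("gene", "consensus"), "calls")
  morph <- calls$gene[calls$consensus %in% c("smooth", "semi_smooth")]
  size <- calls$gene[calls$consensus %in% c("small", "large")]
  wrink <- calls$gene[calls$consensus == "extra_wrinkly"]
  excluded <- intersect(unique(c(morph, size, wrink)), exclude)
  counts <- dplyr::count(filter(calls, !.data$gene %in% exclude),
                         .data$consensus, name = "n_genes")
  structure(
    list(morphology_hits = sort(setdiff(morph, exclude)),
         size_hits = sort(setdiff(size, exclude)),
         extra_wrinkly_hits = sort(setdiff(wrink, exclude)),
         excluded = sort(excluded),
         ambiguous = sort(calls$gene[calls$consensus == "ambiguous"]),
         counts = counts),
    class = "hit_selection"
  )
}

#' @export
print.hit_selection <- function(x, ...) {
  cat("<hit_selection> ", length(x$morphology_hits), " morphology hits, ",
      length(x$size_hits), " size hits, ",
      length(x$excluded), " excluded, ",
      length(x$ambiguous), " ambiguous\n", sep = "")
  print(x$counts)
  invisible(x)
}
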