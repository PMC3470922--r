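# Shared internal helpers.

# Canonical (unordered) representation of gene pairs: element-wise min/max so
# that (a,b) and (b,a) collapse to one key.
canonical_pairs <- function(a, b) {
  tibble(gene_a = pmin(a, b), gene_b = pmax(a, b))
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

assert_probability <- function(x, what) {
  if (any(!is.finite(x) | x < 0 | x > 1)) {
    abort(sprintf("`%s` must contain probabilities in [0, 1]", what))
  }
  invisible(x)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("`%s` is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Split pipe-separated technique strings into sorted unique character vectors.
split_techniques <- function(x) {
  lapply(strsplit(x, "|", fixed = TRUE),
         function(t) sort(unique(t[nzchar(t)])))
}
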