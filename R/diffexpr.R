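#' Bundle an expression matrix with its sample sheet and detection calls
#'
#' @param values Numeric matrix of log2 intensities, genes x samples, with
#'   dimnames.
#' @param samples Tibble with columns `sample`, `genotype` (`wt` or
#'   `flo11_del`) and `medium` (`liquid` or `solid`); `sample` must match the
#'   matrix columns.
#' @param detection Logical matrix, same shape as `values`; `TRUE` = present
#'   call. Defaults to all present.
#' @return An `expression_set`.
#' @export
expression_set <- function(values, samples, detection = NULL) {
  samples <- as_tibble(samples)
  assert_columns(samples, c("sample", "genotype", "medium"), "samples")
  if (is.null(colnames(values)) || is.null(rownames(values))) {
    abort("`values` must have gene rownames and sample colnames")
  }
  if (!setequal(samples$sample, colnames(values)) ||
      anyDuplicated(samples$sample)) {
    abort("sample sheet must match matrix columns one-to-one")
  }
  bad_gt <- setdiff(unique(samples$genotype), c("wt", "flo11_del"))
  bad_md <- setdiff(unique(samples$medium), c("liquid", "solid"))
  if (length(bad_gt) || length(bad_md)) {
    abort("genotype must be wt/flo11_del and medium liquid/solid")
  }
  if (is.null(detection)) {
    detection <- matrix(TRUE, nrow(values), ncol(values),
                        dimnames = dimnames(values))
  }
  if (!identical(dim(detection), dim(values))) {
    abort("`detection` must have the shape of `values`")
  }
  structure(list(values = values,
                 samples = samples[match(colnames(values), samples$sample), ],
                 detection = detection),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat("<expression_set> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples; ", round(100 * mean(!x$detection), 1),
      "% absent calls\n", sep = "")
  invisible(x)
}

#' Mask absent detection calls
#'
#' Intensities below background (detection call absent) are masked to `NA`
#' so they never enter a contrast; genes left with fewer than two present
#' replicates in a group are flagged untestable downstream rather than
#' erroring.
#'
#' @param es An [expression_set()].
#' @return The `expression_set` with absent values masked.
#' @export
filter_absent <- function(es) {
  stopifnot(inherits(es, "expression_set"))
  es$values[!es$detection] <- NA_real_
  es
}

#' Read an expression set from TSV files
#'
#' @param matrix_path Genes x samples TSV, first column `gene`, header row of
#'   sample names.
#' @param samples_path Sample sheet TSV (`sample`, `genotype`, `medium`).
#' @param detection_path Optional TSV of the same shape as the matrix with
#'   `P`/`A` present/absent calls.
#' @return An [expression_set()].
#' @export
read_expression <- function(matrix_path, samples_path, detection_path = NULL) {
  m <- readr::read_tsv(matrix_path, show_col_types = FALSE)
  values <- as.matrix(m[-1])
  rownames(values) <- m[[1]]
  samples <- readr::read_tsv(samples_path, show_col_types = FALSE)
  detection <- NULL
  if (!is.null(detection_path)) {
    d <- readr::read_tsv(detection_path, show_col_types = FALSE)
    detection <- as.matrix(d[-1]) == "P"
    rownames(detection) <- d[[1]]
    detection <- detection[rownames(values), colnames(values)]
  }
  expression_set(values, samples, detection)
}

#' Write an expression set to TSV files
#' @param es An [expression_set()].
#' @param matrix_path,samples_path,detection_path Output paths.
#' @export
write_expression <- function(es, matrix_path, samples_path,
                             detection_path = NULL) {
  stopifnot(inherits(es, "expression_set"))
  m <- as_tibble(es$values)
  m <- dplyr::bind_cols(tibble(gene = rownames(es$values)), m)
  readr::write_tsv(m, matrix_path)
  readr::write_tsv(es$samples, samples_path)
  if (!is.null(detection_path)) {
    d <- as_tibble(ifelse(es$detection, "P", "A"))
    d <- dplyr::bind_cols(tibble(gene = rownames(es$values)), d)
    readr::write_tsv(d, detection_path)
  }
  invisible(matrix_path)
}

# Inverse of the trigamma function by Newton iteration on 1/trigamma,
# following the standard empirical-Bayes moment-matching scheme.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

# Empirical-Bayes squeezing of per-gene variances: the s_g^2 are modelled as
# s0^2 * F(d_g, d0); (d0, s0^2) are estimated by moment matching on log s_g^2
# and each variance is shrunk to (d0*s0^2 + d_g*s_g^2) / (d0 + d_g).
squeeze_variances <- function(s2, df, d0 = NULL, s0_sq = NULL) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  estimated <- is.null(d0)
  if (is.null(d0) || is.null(s0_sq)) {
    if (sum(ok) < 2) abort("too few positive variances to moment-match")
    z <- log(s2[ok])
    e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
    evar <- var(e) - mean(trigamma(df[ok] / 2))
    if (is.finite(evar) && evar > 0) {
      d0_est <- 2 * trigamma_inverse(evar)
      s0_est <- exp(mean(e) + digamma(d0_est / 2) - log(d0_est / 2))
    } else {
      d0_est <- Inf
      s0_est <- exp(mean(e))
    }
    d0 <- d0 %||% d0_est
    s0_sq <- s0_sq %||% s0_est
  }
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + df * s2) / (d0 + df)
  s2_post[!ok & df > 0] <- s0_sq   # all-identical replicates: fall back to prior
  list(d0 = d0, s0_sq = s0_sq, s2_post = s2_post, estimated = estimated)
}

#' Moderated-t contrast between genotypes within one medium
#'
#' Per gene, the mutant-versus-wild-type log2 fold change is tested with an
#' empirical-Bayes moderated t-statistic: the pooled residual variance
#' `s_g^2` (with `d_g = n1 + n2 - 2` degrees of freedom) is shrunk towards a
#' prior variance `s0^2` with prior degrees of freedom `d0`, both estimated
#' from the whole gene set by moment matching on `log s_g^2`; the statistic
#' `logFC / sqrt(s2_post * (1/n1 + 1/n2))` is referred to a t distribution
#' with `d0 + d_g` degrees of freedom. With `d0 = 0` this is the classical
#' pooled two-sample t; with `d0 = Inf` all variances equal `s0^2`.
#'
#' @param es An [expression_set()] (apply [filter_absent()] first to honour
#'   detection calls).
#' @param medium Which medium's samples to contrast (`"liquid"` or
#'   `"solid"`).
#' @param d0,s0_sq Optional fixed prior degrees of freedom / prior variance;
#'   both estimated from the data when `NULL`.
#' @param correction Multiple-testing correction for `p_adjusted`.
#' @return A `moderated_fit`: list with `results` tibble (`gene`, `logFC`,
#'   `s_g`, `t_mod`, `df_total`, `p_raw`, `p_adjusted`, `testable`,
#'   `medium`), `params` (`d0`, `s0_sq`, `estimated`) and group sizes.
#' @export
fit_moderated_t <- function(es, medium = c("liquid", "solid"), d0 = NULL,
                            s0_sq = NULL,
                            correction = c("BH", "bonferroni", "none")) {
  stopifnot(inherits(es, "expression_set"))
  medium <- match.arg(medium)
  correction <- match.arg(correction)
  sel <- es$samples$medium == medium
  if (!any(sel)) abort(sprintf("no samples in medium '%s'", medium))
  v <- es$values[, sel, drop = FALSE]
  gt <- es$samples$genotype[sel]
  x1 <- v[, gt == "flo11_del", drop = FALSE]
  x2 <- v[, gt == "wt", drop = FALSE]
  if (ncol(x1) < 2 || ncol(x2) < 2) {
    abort("need >= 2 replicates per genotype for a contrast")
  }
  n1 <- rowSums(!is.na(x1))
  n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE)
  m2 <- rowMeans(x2, na.rm = TRUE)
  ss1 <- rowSums((x1 - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((x2 - m2)^2, na.rm = TRUE)
  dg <- n1 + n2 - 2
  testable <- n1 >= 2 & n2 >= 2
  s2 <- ifelse(dg > 0, (ss1 + ss2) / dg, NA_real_)

  sq <- squeeze_variances(s2[testable], dg[testable], d0 = d0, s0_sq = s0_sq)
  logFC <- ifelse(testable, m1 - m2, NA_real_)
  s2_post <- rep(NA_real_, length(s2))
  s2_post[testable] <- sq$s2_post
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- logFC / se
  df_total <- ifelse(testable, dg + sq$d0, NA_real_)
  p_raw <- 2 * pt(-abs(t_mod), df = df_total)
  p_adjusted <- rep(NA_real_, length(p_raw))
  p_adjusted[testable] <- adjust_p(p_raw[testable], correction)

  structure(
    list(results = tibble(gene = rownames(es$values),
                          logFC = unname(logFC),
                          s_g = unname(sqrt(pmax(s2, 0))),
                          t_mod = unname(t_mod),
                          df_total = unname(df_total),
                          p_raw = unname(p_raw),
                          p_adjusted = unname(p_adjusted),
                          testable = unname(testable),
                          medium = medium),
         params = list(d0 = sq$d0, s0_sq = sq$s0_sq,
                       estimated = sq$estimated),
         n_mut = ncol(x1), n_wt = ncol(x2), medium = medium,
         correction = correction),
    class = "moderated_fit"
  )
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat("<moderated_fit> ", x$medium, " medium: flo11_del vs wt, ",
      sum(x$results$testable), "/", nrow(x$results), " genes testable; ",
      "d0 = ", signif(x$params$d0, 4), ", s0^2 = ",
      signif(x$params$s0_sq, 4), "\n", sep = "")
  invisible(x)
}

#' Select differentially expressed genes
#'
#' A gene is selected when its corrected p-value is below `alpha` and its
#' absolute log2 fold change exceeds `lfc_min` (defaults: adjusted P < 0.05
#' and |log-ratio| > 1, i.e. fold change larger than 2).
#'
#' @param fit A `moderated_fit` (or its `results` tibble).
#' @param alpha Adjusted p-value cutoff.
#' @param lfc_min Minimum absolute log2 fold change (strict).
#' @return Sorted character vector of selected genes.
#' @export
select_de <- function(fit, alpha = 0.05, lfc_min = 1) {
  res <- if (inherits(fit, "moderated_fit")) fit$results else as_tibble(fit)
  assert_columns(res, c("gene", "logFC", "p_adjusted"), "results")
  sel <- !is.na(res$p_adjusted) & res$p_adjusted < alpha &
    abs(res$logFC) > lfc_min
  sort(res$gene[sel])
}

#' Liquid/solid overlay of two differential-expression contrasts
#'
#' Combines the liquid-medium and solid-medium mutant-versus-wild-type
#' contrasts into a per-gene overlay record, mirroring a node rendering
#' where the core colour encodes the liquid contrast and the border colour
#' the solid contrast: each is `up`, `down` or `ns` (not selected), and the
#' gene falls in one of `both_media`, `liquid_only`, `solid_only`,
#' `neither`.
#'
#' @param liquid,solid `moderated_fit` objects (or results tibbles) for the
#'   two media.
#' @param alpha,lfc_min Selection thresholds, as [select_de()].
#' @return Tibble: `gene`, `core_state`, `border_state`, `category`.
#' @export
annotate_liquid_solid <- function(liquid, solid, alpha = 0.05, lfc_min = 1) {
  state_of <- function(fit) {
    res <- if (inherits(fit, "moderated_fit")) fit$results else as_tibble(fit)
    sel <- select_de(res, alpha, lfc_min)
    tibble(gene = res$gene,
           state = ifelse(res$gene %in% sel,
                          ifelse(res$logFC > 0, "up", "down"), "ns"))
  }
  liq <- state_of(liquid)
  sol <- state_of(solid)
  genes <- sort(union(liq$gene, sol$gene))
  core <- liq$state[match(genes, liq$gene)]
  border <- sol$state[match(genes, sol$gene)]
  core[is.na(core)] <- "ns"
  border[is.na(border)] <- "ns"
  tibble(
    gene = genes, core_state = core, border_state = border,
    category = dplyr::case_when(
      core != "ns" & border != "ns" ~ "both_media",
      core != "ns" ~ "liquid_only",
      border != "ns" ~ "solid_only",
      TRUE ~ "neither"
    )
  )
}

#' @rdname fit_moderated_t
#' @param x A `moderated_fit`.
#' @param alpha,lfc_min Selection thresholds used to set the `selected` flag.
#' @param ... Unused.
#' @method tidy moderated_fit
#' @export
tidy.moderated_fit <- function(x, alpha = 0.05, lfc_min = 1, ...) {
  sel <- select_de(x, alpha, lfc_min)
  mutate(x$results, selected = .data$gene %in% sel)
}

#' @rdname fit_moderated_t
#' @method glance moderated_fit
#' @export
glance.moderated_fit <- function(x, ...) {
  tibble(medium = x$medium, d0 = x$params$d0, s0_sq = x$params$s0_sq,
         d0_estimated = x$params$estimated,
         n_genes = nrow(x$results), n_testable = sum(x$results$testable),
         n_mut = x$n_mut, n_wt = x$n_wt)
}

#' Volcano plot of a moderated-t contrast
#'
#' @param object A `moderated_fit`.
#' @param alpha,lfc_min Selection thresholds.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot moderated_fit
#' @export
autoplot.moderated_fit <- function(object, alpha = 0.05, lfc_min = 1, ...) {
  df <- tidy(object, alpha = alpha, lfc_min = lfc_min)
  df <- filter(df, .data$testable)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$logFC,
                                   y = -log10(.data$p_adjusted),
                                   colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-lfc_min, lfc_min),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(log[2] ~ "fold change (flo11" * Delta *
                                   " vs wt)"),
                  y = expression(-log[10] ~ "adjusted p"),
                  colour = "selected") +
    ggplot2::theme_minimal()
}
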