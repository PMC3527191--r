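#' Drop excluded rows from an expression matrix
#'
#' Removes rows by id (e.g. array control probes and probes targeting
#' genetic elements rather than transcripts). Ids not present are ignored
#' with a warning.
#'
#' @param matrix Numeric matrix with row names.
#' @param exclude_ids Character vector of row ids to drop.
#' @return The matrix without the listed rows.
#' @export
filter_rows <- function(matrix, exclude_ids) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)))
  exclude_ids <- unique(as.character(exclude_ids))
  absent <- setdiff(exclude_ids, rownames(matrix))
  if (length(absent)) {
    warning(sprintf("%d exclude id(s) not present in the matrix",
                    length(absent)))
  }
  keep <- !(rownames(matrix) %in% exclude_ids)
  message(sprintf("filter_rows: removed %d of %d rows",
                  sum(!keep), nrow(matrix)))
  matrix[keep, , drop = FALSE]
}

#' Average multi-probe transcripts
#'
#' Collapses probe-level rows to transcript-level rows by the arithmetic
#' mean (per sample, on the matrix's current scale) of all probes mapped
#' to the same transcript. Single-probe transcripts pass through.
#'
#' @param matrix Numeric probe x sample matrix with row names.
#' @param probe_to_transcript Named character vector mapping every probe
#'   row id to a transcript id.
#' @return Transcript x sample matrix.
#' @export
collapse_multiprobe <- function(matrix, probe_to_transcript) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)))
  missing <- setdiff(rownames(matrix), names(probe_to_transcript))
  if (length(missing)) {
    stop(sprintf("probe(s) absent from the map: %s",
                 paste(utils::head(missing, 5), collapse = ", ")),
         call. = FALSE)
  }
  tx <- unname(probe_to_transcript[rownames(matrix)])
  sums <- rowsum(matrix, tx)
  counts <- as.vector(table(tx)[rownames(sums)])
  sums / counts
}

#' Scale an expression matrix to a reference gene
#'
#' Rescales every (linear-scale) value so that the mean expression of
#' `reference_gene` over the samples of `reference_group` becomes exactly
#' 100 -- the convention of reporting expression as a percentage of the
#' actin level during exponential growth.
#'
#' @param matrix Linear-scale gene x sample matrix with row names.
#' @param groups Named character vector: sample -> group label.
#' @param reference_gene Row id of the reference gene.
#' @param reference_group Group whose samples define the reference mean.
#' @return The rescaled matrix.
#' @export
scale_to_reference <- function(matrix, groups, reference_gene,
                               reference_group) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)))
  groups <- check_groups(matrix, groups)
  if (!reference_gene %in% rownames(matrix)) {
    stop(sprintf("reference gene %s not in matrix", reference_gene),
         call. = FALSE)
  }
  ref_samples <- names(groups)[groups == reference_group]
  if (length(ref_samples) == 0L) {
    stop(sprintf("no samples in reference group %s", reference_group),
         call. = FALSE)
  }
  ref_mean <- mean(matrix[reference_gene, ref_samples])
  if (!is.finite(ref_mean) || ref_mean == 0) {
    stop("reference mean expression is zero", call. = FALSE)
  }
  matrix * (100 / ref_mean)
}

#' Per-group fold changes against a baseline group
#'
#' `FC(gene, g) = mean_linear(gene, g) / mean_linear(gene, baseline)`,
#' computed on unrounded linear-scale values (arithmetic group means).
#'
#' @param matrix Linear-scale gene x sample matrix with row names.
#' @param groups Named character vector: sample -> group label.
#' @param baseline_group Baseline group label (e.g. exponential growth).
#' @return Numeric gene x group matrix of fold changes for every
#'   non-baseline group.
#' @export
fold_changes <- function(matrix, groups, baseline_group = "exp") {
  stopifnot(is.matrix(matrix))
  groups <- check_groups(matrix, groups)
  if (!baseline_group %in% groups) {
    stop(sprintf("baseline group %s not present", baseline_group),
         call. = FALSE)
  }
  gm <- group_means(matrix, groups)
  base <- gm[, baseline_group]
  if (any(base == 0)) {
    stop("zero baseline mean expression for at least one gene",
         call. = FALSE)
  }
  others <- setdiff(colnames(gm), baseline_group)
  gm[, others, drop = FALSE] / base
}

group_means <- function(matrix, groups) {
  gs <- unique(unname(groups))
  out <- vapply(gs, function(g) {
    rowMeans(matrix[, names(groups)[groups == g], drop = FALSE])
  }, numeric(nrow(matrix)))
  # vapply drops to a vector for a single-gene matrix
  if (!is.matrix(out)) {
    out <- matrix(out, nrow = 1L, dimnames = list(rownames(matrix), gs))
  }
  out
}

check_groups <- function(matrix, groups) {
  groups <- setNames(as.character(groups), names(groups))
  if (is.null(names(groups)) || !all(colnames(matrix) %in% names(groups))) {
    stop("`groups` must be a named vector labelling every sample",
         call. = FALSE)
  }
  groups[colnames(matrix)]
}

#' Empirical-Bayes moderated t-test for one two-group contrast
#'
#' Per-gene two-sample comparison with variance shrinkage: the pooled
#' within-group variance `s_g^2` (with `d_g = n1 + n0 - 2` degrees of
#' freedom) is shrunk towards a prior `s_0^2` with `d_0` prior degrees of
#' freedom, estimated by closed-form moment matching on the log variances
#' (mean and variance of `log s_g^2` against the theoretical moments of a
#' scaled log-F distribution). The moderated statistic
#' `t_g = (mean1 - mean0) / sqrt(s_tilde_g^2 (1/n1 + 1/n0))` is referred
#' to a t distribution with `d_0 + d_g` degrees of freedom.
#'
#' When the moment equation for `d_0` has no positive solution (the gene
#' variances are effectively exchangeable), `d_0 = Inf` and every
#' posterior variance equals `s_0^2`.
#'
#' @param matrix Log2-scale gene x sample matrix with row names.
#' @param groups Named character vector: sample -> group label.
#' @param contrast Length-2 character vector `c(group, baseline)`; the
#'   reported difference is group minus baseline.
#' @param prior_df Optional override for `d_0` (0 gives the ordinary
#'   pooled t-test; `Inf` full shrinkage).
#' @return Object of class `contrast_result`: data frame with one row per
#'   gene (`gene`, `mean_diff` in log2, `fold_change` = 2^mean_diff, `s2`,
#'   `t`, `df`, `p`) and attributes `d0`, `s02`, `contrast`.
#' @export
moderated_t_fit <- function(matrix, groups, contrast, prior_df = NULL) {
  stopifnot(is.matrix(matrix), length(contrast) == 2L)
  groups <- check_groups(matrix, groups)
  s1 <- names(groups)[groups == contrast[1L]]
  s0 <- names(groups)[groups == contrast[2L]]
  n1 <- length(s1); n0 <- length(s0)
  if (n1 < 2L || n0 < 2L) {
    stop("need at least 2 samples per contrasted group", call. = FALSE)
  }
  if (!all(is.finite(matrix[, c(s1, s0)]))) {
    stop("expression values must be finite", call. = FALSE)
  }
  x1 <- matrix[, s1, drop = FALSE]
  x0 <- matrix[, s0, drop = FALSE]
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  ss <- rowSums((x1 - m1)^2) + rowSums((x0 - m0)^2)
  dg <- n1 + n0 - 2L
  s2 <- ss / dg
  if (is.null(prior_df)) {
    hyper <- fit_variance_prior(s2, dg)
  } else {
    stopifnot(prior_df >= 0)
    s02 <- if (is.infinite(prior_df)) mean(s2) else {
      fit_variance_prior(s2, dg)$s02
    }
    hyper <- list(d0 = prior_df, s02 = s02)
  }
  d0 <- hyper$d0; s02 <- hyper$s02
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else {
    (d0 * s02 + dg * s2) / (d0 + dg)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n0))
  t <- (m1 - m0) / se
  df <- d0 + dg
  p <- 2 * pt(-abs(t), df = df)
  out <- data.frame(
    gene = rownames(matrix) %||% as.character(seq_len(nrow(matrix))),
    mean_diff = m1 - m0, fold_change = 2^(m1 - m0),
    s2 = s2, t = t, df = df, p = p,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, d0 = d0, s02 = s02,
            contrast = paste(contrast, collapse = " vs "),
            class = c("contrast_result", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Moment-matching estimate of the variance prior (d0, s02) from the
# per-gene pooled variances: with z = log(s2),
#   E z   = log(s02) + digamma(dg/2) - log(dg/2)
#           - digamma(d0/2) + log(d0/2)   (sign convention below)
#   Var z = trigamma(dg/2) + trigamma(d0/2)
# so trigamma(d0/2) is the excess of Var z over trigamma(dg/2); a
# non-positive excess means no positive solution and d0 = Inf.
fit_variance_prior <- function(s2, dg) {
  z <- log(s2[s2 > 0 & is.finite(s2)])
  if (length(z) < 2L) {
    return(list(d0 = Inf, s02 = mean(s2)))
  }
  e <- z - digamma(dg / 2) + log(dg / 2)
  emean <- mean(e)
  evar <- var(e)
  excess <- evar - trigamma(dg / 2)
  if (is.na(excess) || excess <= 0) {
    return(list(d0 = Inf, s02 = exp(emean)))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

# Newton solve of trigamma(x) = y for x > 0 (trigamma is decreasing).
trigamma_inverse <- function(y) {
  stopifnot(is.finite(y), y > 0)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    f <- trigamma(x) - y
    step <- f / psigamma(x, deriv = 2L)
    x_new <- x - step
    if (x_new <= 0) x_new <- x / 2
    if (abs(x_new - x) < 1e-10 * (1 + abs(x))) {
      x <- x_new
      break
    }
    x <- x_new
  }
  x
}

#' Call differential expression at a critical FDR
#'
#' Adds Benjamini-Hochberg q-values and three-way calls: `up` if
#' `q < q_crit` and the mean log2 difference is positive, `down` if
#' `q < q_crit` and it is negative, otherwise `ns`. The inequality is
#' strict and no minimal fold-change filter is applied.
#'
#' @param result A `contrast_result` from [moderated_t_fit()].
#' @param q_crit Critical FDR q-value (default 0.005).
#' @return The result with added columns `q` and `call`.
#' @export
call_de <- function(result, q_crit = 0.005) {
  stopifnot(inherits(result, "contrast_result"))
  result$q <- bh_adjust(result$p)
  result$call <- ifelse(
    result$q < q_crit & result$mean_diff > 0, "up",
    ifelse(result$q < q_crit & result$mean_diff < 0, "down", "ns")
  )
  result
}

#' Three-set Venn region counts for up- and downregulated genes
#'
#' Partitions the day-wise up (and down) call sets into the seven Venn
#' regions; the triple intersection counts the conjointly regulated genes.
#' Also reports the number and fraction of genes differentially expressed
#' at one or more time points.
#'
#' @param calls_day1,calls_day3,calls_day6 `contrast_result`s with calls
#'   (from [call_de()]) over the same gene universe, or named character
#'   vectors of calls (`up`/`down`/`ns`) with gene names.
#' @return Object of class `venn_counts`: list with `up` and `down`
#'   (named integer vectors over regions `d1`, `d3`, `d6`, `d1d3`, `d1d6`,
#'   `d3d6`, `d1d3d6`), `conjoint_up`, `conjoint_down`, `n_universe`,
#'   `n_de_any`, `fraction_de_any`.
#' @export
venn_counts <- function(calls_day1, calls_day3, calls_day6) {
  get_calls <- function(x) {
    if (inherits(x, "contrast_result")) {
      if (is.null(x$call)) stop("run call_de() first", call. = FALSE)
      setNames(x$call, x$gene)
    } else {
      stopifnot(!is.null(names(x)))
      x
    }
  }
  c1 <- get_calls(calls_day1); c3 <- get_calls(calls_day3)
  c6 <- get_calls(calls_day6)
  u <- names(c1)
  if (!setequal(u, names(c3)) || !setequal(u, names(c6))) {
    stop("call sets must share the same gene universe", call. = FALSE)
  }
  c3 <- c3[u]; c6 <- c6[u]
  region_counts <- function(s1, s3, s6) {
    in1 <- u %in% s1; in3 <- u %in% s3; in6 <- u %in% s6
    c(
      d1 = sum(in1 & !in3 & !in6), d3 = sum(!in1 & in3 & !in6),
      d6 = sum(!in1 & !in3 & in6), d1d3 = sum(in1 & in3 & !in6),
      d1d6 = sum(in1 & !in3 & in6), d3d6 = sum(!in1 & in3 & in6),
      d1d3d6 = sum(in1 & in3 & in6)
    )
  }
  up <- region_counts(u[c1 == "up"], u[c3 == "up"], u[c6 == "up"])
  down <- region_counts(u[c1 == "down"], u[c3 == "down"], u[c6 == "down"])
  de_any <- c1 != "ns" | c3 != "ns" | c6 != "ns"
  structure(list(
    up = up, down = down,
    conjoint_up = unname(up["d1d3d6"]), conjoint_down = unname(down["d1d3d6"]),
    n_universe = length(u), n_de_any = sum(de_any),
    fraction_de_any = mean(de_any)
  ), class = "venn_counts")
}

#' @export
print.venn_counts <- function(x, ...) {
  cat(sprintf(
    "<venn_counts> %d/%d genes DE at >= 1 time point (%.1f%%); conjoint up %d, down %d\n",
    x$n_de_any, x$n_universe, 100 * x$fraction_de_any,
    x$conjoint_up, x$conjoint_down
  ))
  invisible(x)
}
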