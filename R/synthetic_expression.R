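#' Generate a synthetic expression study with planted fold changes
#'
#' Emulates the starvation study design: a linear-scale gene x sample
#' matrix over four groups (exponential growth plus three starvation
#' time points) with log-normal noise. Each gene's log2 expression is
#' `baseline + group effect + N(0, noise_sd^2)`; a `de_fraction` of genes
#' receive, for every starvation group, a planted log2 effect
#' `+/- log2(FC)` with the fold change drawn uniformly from `fc_range`
#' and the sign drawn per gene and group. The per-gene, per-group true
#' linear fold change versus the exponential group is recorded (1 for
#' non-DE genes).
#'
#' @param n_genes Number of genes.
#' @param replicates Named integer vector of per-group replicate counts;
#'   the default `c(exp = 3, day1 = 2, day3 = 2, day6 = 2)` mirrors
#'   triplicate exponential and duplicate starvation cultures.
#' @param de_fraction Fraction of genes with planted differential
#'   expression.
#' @param fc_range Length-2 vector, minimum and maximum fold change
#'   (minimum >= 1).
#' @param noise_sd Standard deviation of log2 noise.
#' @param seed Integer seed.
#' @return Object of class `expression_bundle`: list with `matrix`
#'   (linear scale, samples named `<group>_<i>`), `groups` (named sample
#'   -> group vector), `truth` (gene x starvation-group matrix of true
#'   linear fold changes) and `de_genes`.
#' @export
generate_expression <- function(n_genes,
                                replicates = c(exp = 3L, day1 = 2L,
                                               day3 = 2L, day6 = 2L),
                                de_fraction = 0.1,
                                fc_range = c(2, 8),
                                noise_sd = 0.3,
                                seed = 1L) {
  stopifnot(n_genes >= 1, all(replicates >= 2), !is.null(names(replicates)),
            "exp" %in% names(replicates), length(fc_range) == 2L,
            fc_range[1L] >= 1, fc_range[2L] >= fc_range[1L], noise_sd >= 0)
  if (de_fraction < 0 || de_fraction > 1) {
    stop("`de_fraction` must lie in [0, 1]", call. = FALSE)
  }
  starve_groups <- setdiff(names(replicates), "exp")
  with_seed(seed, {
    genes <- sprintf("gene%05d", seq_len(n_genes))
    samples <- unlist(lapply(names(replicates), function(g) {
      paste(g, seq_len(replicates[[g]]), sep = "_")
    }))
    groups <- setNames(rep(names(replicates), replicates), samples)
    baseline <- rnorm(n_genes, mean = 6, sd = 1.5)
    n_de <- round(de_fraction * n_genes)
    de_genes <- if (n_de > 0) sort(sample(genes, n_de)) else character(0)
    effect <- matrix(0, n_genes, length(starve_groups),
                     dimnames = list(genes, starve_groups))
    if (n_de > 0) {
      for (g in starve_groups) {
        fc <- runif(n_de, fc_range[1L], fc_range[2L])
        sign <- sample(c(-1, 1), n_de, replace = TRUE)
        effect[de_genes, g] <- sign * log2(fc)
      }
    }
    log2_mat <- matrix(NA_real_, n_genes, length(samples),
                       dimnames = list(genes, samples))
    for (s in samples) {
      g <- groups[[s]]
      mu <- baseline + if (g == "exp") 0 else effect[, g]
      log2_mat[, s] <- mu + rnorm(n_genes, 0, noise_sd)
    }
    structure(list(
      matrix = 2^log2_mat,
      groups = groups,
      truth = 2^effect,
      de_genes = de_genes
    ), class = "expression_bundle")
  })
}

#' @export
print.expression_bundle <- function(x, ...) {
  cat(sprintf(
    "<expression_bundle> %d genes x %d samples (%s), %d DE genes\n",
    nrow(x$matrix), ncol(x$matrix),
    paste(sprintf("%s:%d", unique(x$groups),
                  as.vector(table(x$groups)[unique(x$groups)])),
          collapse = ", "),
    length(x$de_genes)
  ))
  invisible(x)
}

#' Write an expression matrix and its group labels as TSV
#'
#' @param bundle An `expression_bundle` (or list with `matrix`, `groups`).
#' @param matrix_file Output TSV (genes in rows, header = sample ids).
#' @param groups_file Sidecar TSV `sample<TAB>group`.
#' @return Invisibly, `matrix_file`.
#' @export
write_expression <- function(bundle, matrix_file, groups_file) {
  write.table(data.frame(gene = rownames(bundle$matrix), bundle$matrix,
                         check.names = FALSE),
              matrix_file, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = names(bundle$groups),
                         group = unname(bundle$groups)),
              groups_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(matrix_file)
}

#' Read an expression matrix and group labels written by
#' [write_expression()]
#'
#' @param matrix_file TSV with a `gene` column then one column per sample.
#' @param groups_file TSV with `sample` and `group` columns.
#' @return List with `matrix` and `groups`.
#' @export
read_expression <- function(matrix_file, groups_file) {
  df <- read.delim(matrix_file, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1L]]
  g <- read.delim(groups_file, colClasses = "character")
  list(matrix = m, groups = setNames(g$group, g$sample))
}
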