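#' Run the morphometry workflow over multiple time points
#'
#' Batch-processes each time point's micrographs through the six-step
#' diameter pipeline and summarizes each time point as a kernel density
#' with thin/thick population fractions, the way hyphal population
#' dynamics are tracked across a starvation time course.
#'
#' @param time_points Named list; each element is a vector of image paths
#'   or a list of `micrograph` objects / matrices for one time point.
#' @param config Parameters from [morphometry_config()].
#' @return Object of class `morphometry_report`: list with
#'   `distributions` (named list of `diameter_distribution`), `samples`
#'   (named list of pooled sample data frames), `counts`, `density_table`
#'   (long data frame `time_point`, `diameter_um`, `density`),
#'   `summary` (data frame per time point: n, mean, thin/thick fractions)
#'   and `config`.
#' @export
run_morphometry_study <- function(time_points, config = morphometry_config()) {
  if (!is.list(time_points) || length(time_points) == 0L ||
      is.null(names(time_points)) || any(names(time_points) == "")) {
    stop("`time_points` must be a non-empty named list of image sets",
         call. = FALSE)
  }
  distributions <- list(); samples <- list(); counts <- list()
  for (tp in names(time_points)) {
    batch <- process_micrograph_batch(time_points[[tp]], config)
    samples[[tp]] <- batch$samples
    counts[[tp]] <- batch$counts
    distributions[[tp]] <- diameter_density(
      batch$samples, bandwidth = config$kde_bandwidth,
      split_threshold = config$split_threshold
    )
  }
  density_table <- do.call(rbind, lapply(names(distributions), function(tp) {
    d <- distributions[[tp]]
    data.frame(time_point = tp, diameter_um = d$grid, density = d$density)
  }))
  summary <- do.call(rbind, lapply(names(distributions), function(tp) {
    d <- distributions[[tp]]
    data.frame(
      time_point = tp, n = d$n_samples,
      mean_diameter_um = mean(samples[[tp]]$diameter_um),
      thin_fraction = d$thin_fraction, thick_fraction = d$thick_fraction
    )
  }))
  structure(list(
    distributions = distributions, samples = samples, counts = counts,
    density_table = density_table, summary = summary, config = config
  ), class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, ...) {
  cat("<morphometry_report>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Run the transcriptome + enrichment workflow
#'
#' For each starvation time point: moderated-t contrast against the
#' exponential group and FDR-controlled up/down calls; then three-way
#' Venn counts, per-list annotation enrichment, and reduction of the
#' day-wise enriched GO term sets to common most-specific terms for the
#' up- and downregulated directions separately.
#'
#' @param matrix Linear- or log2-scale gene x sample matrix (see
#'   `log2_scale`).
#' @param groups Named character vector sample -> group over
#'   `exp`/`day1`/`day3`/`day6` (additional baselines allowed via
#'   `baseline_group`).
#' @param annotations Named list gene -> term ids (direct annotations).
#' @param dag Optional [go_dag()]; when supplied, annotations are
#'   propagated and the common most-specific reduction is run.
#' @param log2_scale Whether `matrix` is already log2.
#' @param baseline_group Baseline group label.
#' @param q_de Critical FDR for differential-expression calls.
#' @param q_enrich Critical FDR for enrichment.
#' @return Object of class `transcriptome_report`: list with `contrasts`
#'   (named list of called `contrast_result`s), `venn`, `up_lists`,
#'   `down_lists`, `enrichment` (nested `up`/`down` lists of enrichment
#'   tables), `common_up`, `common_down` (when `dag` given) and `config`.
#' @export
run_transcriptome_study <- function(matrix, groups, annotations = NULL,
                                    dag = NULL, log2_scale = FALSE,
                                    baseline_group = "exp",
                                    q_de = 0.005, q_enrich = 0.05) {
  stopifnot(is.matrix(matrix))
  groups <- check_groups(matrix, groups)
  starve <- setdiff(unique(unname(groups)), baseline_group)
  if (length(starve) == 0L) {
    stop("no non-baseline groups to contrast", call. = FALSE)
  }
  if (!log2_scale && any(matrix <= 0)) {
    stop("linear-scale matrix must be positive", call. = FALSE)
  }
  lmat <- if (log2_scale) matrix else log2(matrix)
  contrasts <- list(); up_lists <- list(); down_lists <- list()
  for (g in starve) {
    res <- call_de(moderated_t_fit(lmat, groups, c(g, baseline_group)),
                   q_crit = q_de)
    contrasts[[g]] <- res
    up_lists[[g]] <- res$gene[res$call == "up"]
    down_lists[[g]] <- res$gene[res$call == "down"]
  }
  venn <- if (length(starve) == 3L) {
    do.call(venn_counts, unname(contrasts[starve]))
  } else NULL
  enrichment <- NULL
  common_up <- NULL; common_down <- NULL
  if (!is.null(annotations)) {
    if (!is.null(dag) && !isTRUE(attr(annotations, "propagated"))) {
      annotations <- propagate_annotations(dag, annotations)
    }
    population <- rownames(matrix)
    run_enrich <- function(gene_lists) {
      lapply(gene_lists, function(gl) {
        if (length(gl) == 0L) {
          enrich(character(0), population, annotations, q_enrich, dag = dag,
                 propagate = FALSE)
        } else {
          enrich(gl, population, annotations, q_enrich, dag = dag,
                 propagate = FALSE)
        }
      })
    }
    enrichment <- list(up = run_enrich(up_lists), down = run_enrich(down_lists))
    if (!is.null(dag)) {
      enriched_terms <- function(tables) {
        lapply(tables, function(tb) tb$term[tb$enriched])
      }
      up_sets <- enriched_terms(enrichment$up)
      down_sets <- enriched_terms(enrichment$down)
      common_up <- if (all(lengths(up_sets) > 0)) {
        common_most_specific(dag, up_sets)
      } else {
        structure(list(common = character(0), non_common = character(0),
                       provenance = data.frame(common_term = character(0),
                                               child = character(0),
                                               distance = integer(0))),
                  class = "common_specific_result")
      }
      common_down <- if (all(lengths(down_sets) > 0)) {
        common_most_specific(dag, down_sets)
      } else {
        structure(list(common = character(0), non_common = character(0),
                       provenance = data.frame(common_term = character(0),
                                               child = character(0),
                                               distance = integer(0))),
                  class = "common_specific_result")
      }
    }
  }
  structure(list(
    contrasts = contrasts, venn = venn, up_lists = up_lists,
    down_lists = down_lists, enrichment = enrichment,
    common_up = common_up, common_down = common_down,
    config = list(baseline_group = baseline_group, q_de = q_de,
                  q_enrich = q_enrich, log2_scale = log2_scale)
  ), class = "transcriptome_report")
}

#' @export
print.transcriptome_report <- function(x, ...) {
  cat("<transcriptome_report>\n")
  for (g in names(x$contrasts)) {
    cat(sprintf("  %s: %d up, %d down of %d genes\n", g,
                length(x$up_lists[[g]]), length(x$down_lists[[g]]),
                nrow(x$contrasts[[g]])))
  }
  if (!is.null(x$venn)) print(x$venn)
  if (!is.null(x$common_up)) {
    cat(sprintf("  common most-specific terms: %d up, %d down\n",
                length(x$common_up$common), length(x$common_down$common)))
  }
  invisible(x)
}

#' Bundled autophagy-gene expression summary
#'
#' Group-mean expression values (percent of the actin level during
#' exponential growth) and published fold changes for predicted
#' *Aspergillus niger* autophagy genes across exponential growth and
#' days 1, 3 and 6 of carbon starvation. Used as a worked example for
#' the fold-change table conventions.
#'
#' @return Data frame with columns `gene`, `orf`, `exp`, `day1`, `day3`,
#'   `day6` (mean expression) and `fc_day1`, `fc_day3`, `fc_day6`
#'   (published fold change).
#' @export
autophagy_expression <- function() {
  read.delim(system.file("extdata", "autophagy_expression.tsv",
                         package = "mycostarve"),
             check.names = FALSE, stringsAsFactors = FALSE)
}
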