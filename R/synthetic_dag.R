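#' Generate a random single-rooted ontology DAG
#'
#' Terms are created in order; the first is the root and every later term
#' draws between 1 and `max_parents` parents uniformly among the earlier
#' terms, which guarantees acyclicity and a single root.
#'
#' @param n_terms Number of terms (>= 1).
#' @param max_parents Maximum parents per non-root term (>= 1).
#' @param seed Integer seed; the same seed reproduces the same edge list.
#' @return A [go_dag()] object with term ids `T:0001`, `T:0002`, ...
#' @export
generate_go_dag <- function(n_terms, max_parents = 3, seed = 1L) {
  stopifnot(n_terms >= 1, max_parents >= 1)
  with_seed(seed, {
    ids <- sprintf("T:%04d", seq_len(n_terms))
    parents <- setNames(vector("list", n_terms), ids)
    parents[[1L]] <- character(0)
    if (n_terms > 1L) {
      for (i in 2:n_terms) {
        k <- sample.int(min(max_parents, i - 1L), 1L)
        parents[[i]] <- ids[sample.int(i - 1L, k)]
      }
    }
    go_dag(setNames(paste("synthetic term", seq_len(n_terms)), ids), parents)
  })
}

#' Generate gene annotations with planted enriched terms
#'
#' Assigns direct (unpropagated) term annotations to genes and selects a
#' study set. Non-planted terms annotate every gene independently at
#' `background_rate`. Each planted term annotates study genes at its
#' `study_fraction` and non-study genes at its `background_fraction`, so
#' downstream Fisher testing should recover the planted terms.
#'
#' @param dag A [go_dag()].
#' @param n_genes Number of genes (`g0001`, ...).
#' @param planted Data frame (or NULL) with columns `term`,
#'   `study_fraction`, `background_fraction`.
#' @param study_size Size of the study set.
#' @param background_rate Annotation probability for non-planted terms.
#' @param seed Integer seed.
#' @return List with `annotations` (named list gene -> term ids, direct
#'   annotations only), `study` (character vector) and `genes` (the full
#'   population).
#' @export
generate_annotations <- function(dag, n_genes, planted = NULL,
                                 study_size = max(1L, round(0.1 * n_genes)),
                                 background_rate = 0.05, seed = 1L) {
  stopifnot(inherits(dag, "go_dag"), n_genes >= 1,
            study_size >= 1, study_size <= n_genes)
  if (!is.null(planted)) {
    planted <- as.data.frame(planted)
    stopifnot(all(c("term", "study_fraction", "background_fraction") %in%
                    names(planted)))
    unknown <- setdiff(planted$term, names(dag$terms))
    if (length(unknown)) {
      stop(sprintf("unknown planted term(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    stopifnot(all(planted$study_fraction >= 0 & planted$study_fraction <= 1),
              all(planted$background_fraction >= 0 &
                    planted$background_fraction <= 1))
  }
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    study <- sort(sample(genes, study_size))
    is_study <- genes %in% study
    ann <- setNames(vector("list", n_genes), genes)
    plain_terms <- setdiff(names(dag$terms),
                           if (is.null(planted)) character(0) else planted$term)
    for (t in plain_terms) {
      hit <- runif(n_genes) < background_rate
      for (g in which(hit)) ann[[g]] <- c(ann[[g]], t)
    }
    if (!is.null(planted)) {
      for (i in seq_len(nrow(planted))) {
        pr <- ifelse(is_study, planted$study_fraction[i],
                     planted$background_fraction[i])
        hit <- runif(n_genes) < pr
        for (g in which(hit)) ann[[g]] <- c(ann[[g]], planted$term[i])
      }
    }
    ann <- lapply(ann, function(x) if (is.null(x)) character(0) else x)
    attr(ann, "propagated") <- FALSE
    list(annotations = ann, study = study, genes = genes)
  })
}

#' Write gene annotations as a two-column TSV
#'
#' One `gene<TAB>term` row per direct annotation.
#'
#' @param annotations Named list gene -> character vector of term ids.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_annotations <- function(annotations, file) {
  df <- data.frame(
    gene = rep(names(annotations), lengths(annotations)),
    term = unlist(annotations, use.names = FALSE)
  )
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}

#' Read gene annotations from a two-column TSV
#'
#' @param file Path to a headerless `gene<TAB>term` TSV.
#' @return Named list gene -> character vector of term ids.
#' @export
read_annotations <- function(file) {
  df <- read.delim(file, header = FALSE, col.names = c("gene", "term"),
                   colClasses = "character")
  ann <- split(df$term, df$gene)
  attr(ann, "propagated") <- FALSE
  ann
}
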