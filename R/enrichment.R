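#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, shared by the enrichment and
#' differential-expression stages so both use identical arithmetic.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Annotation-term overrepresentation by Fisher's exact test
#'
#' One-sided (overrepresentation) Fisher's exact test per annotation term:
#' with `N` population genes of which `K` carry the term, and `n` study
#' genes of which `k` carry it, the p-value is the hypergeometric tail
#' `P(X >= k)`. Terms absent from the population (`K = 0`) are not tested
#' and do not enter the Benjamini-Hochberg denominator.
#'
#' When `dag` is supplied (Gene Ontology style), annotations are first
#' closed under ancestors unless already propagated or
#' `propagate = FALSE`. With `dag = NULL` the same test runs on flat
#' annotations (Pfam domains, KEGG pathways, ...).
#'
#' @param study Character vector of study genes (must be a subset of
#'   `population`).
#' @param population Character vector of population (background) genes.
#' @param annotations Named list: gene -> character vector of term ids.
#'   Population genes missing from the list count as unannotated.
#' @param q_crit Critical Benjamini-Hochberg q-value for the `enriched`
#'   flag.
#' @param dag Optional [go_dag()] for true-path propagation and term
#'   names.
#' @param propagate Whether to propagate annotations when `dag` is given.
#' @return Data frame sorted by p: `term`, `name` (if `dag` given), `k`,
#'   `n`, `K`, `N`, `p`, `q`, `enriched`.
#' @export
enrich <- function(study, population, annotations, q_crit = 0.05,
                   dag = NULL, propagate = TRUE) {
  study <- unique(as.character(study))
  population <- unique(as.character(population))
  if (!all(study %in% population)) {
    stop("study genes must be a subset of the population", call. = FALSE)
  }
  stopifnot(is.list(annotations), q_crit > 0, q_crit <= 1)
  if (!is.null(dag) && propagate && !isTRUE(attr(annotations, "propagated"))) {
    annotations <- propagate_annotations(dag, annotations)
  }
  ann <- annotations[intersect(names(annotations), population)]
  N <- length(population)
  n <- length(study)
  pop_terms <- unlist(ann, use.names = FALSE)
  K_tab <- table(pop_terms)
  terms <- names(K_tab)
  if (length(terms) == 0L) {
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), enriched = logical(0)))
  }
  study_ann <- ann[intersect(names(ann), study)]
  k_tab <- table(factor(unlist(study_ann, use.names = FALSE), levels = terms))
  K <- as.integer(K_tab)
  k <- as.integer(k_tab)
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  q <- bh_adjust(p)
  out <- data.frame(term = terms, k = k, n = n, K = K, N = N,
                    p = p, q = q, enriched = q <= q_crit,
                    stringsAsFactors = FALSE)
  if (!is.null(dag)) {
    out$name <- unname(dag$terms[out$term])
    out <- out[, c("term", "name", "k", "n", "K", "N", "p", "q", "enriched")]
  }
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
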