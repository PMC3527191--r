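#' Construct an ontology DAG
#'
#' A minimal directed acyclic graph over ontology terms connected by
#' `is_a` edges (child -> parent). Acyclicity and referential integrity
#' are validated on construction.
#'
#' @param terms Named character vector: term id -> term name.
#' @param parents Named list: term id -> character vector of parent ids
#'   (empty for roots). Terms missing from the list are treated as roots.
#' @return Object of class `go_dag`: list with `terms`, `parents`, `roots`.
#' @export
go_dag <- function(terms, parents) {
  stopifnot(is.character(terms), !is.null(names(terms)))
  ids <- names(terms)
  parents <- parents[intersect(names(parents), ids)]
  full <- setNames(vector("list", length(ids)), ids)
  full[names(parents)] <- parents
  full <- lapply(full, function(p) if (is.null(p)) character(0) else unique(p))
  dangling <- setdiff(unlist(full), ids)
  if (length(dangling)) {
    stop(sprintf("is_a target(s) not defined: %s",
                 paste(utils::head(dangling, 5), collapse = ", ")),
         call. = FALSE)
  }
  check_acyclic(full)
  roots <- ids[vapply(full, length, integer(1)) == 0L]
  if (length(roots) == 0L) stop("ontology has no root", call. = FALSE)
  structure(list(terms = terms, parents = full, roots = roots),
            class = "go_dag")
}

# Kahn's algorithm; stops naming one edge of a cycle if present.
check_acyclic <- function(parents) {
  indeg <- vapply(parents, length, integer(1)) # edges child->parent: count per child
  children_of <- split(
    rep(names(parents), lengths(parents)), unlist(parents)
  )
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in children_of[[t]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(parents)) {
    bad <- names(indeg)[indeg > 0L][1L]
    stop(sprintf("cycle detected in is_a hierarchy involving edge %s -> %s",
                 bad, parents[[bad]][1L]), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("<go_dag> %d terms, %d is_a edges, %d root(s)\n",
              length(x$terms), sum(lengths(x$parents)), length(x$roots)))
  invisible(x)
}

#' Parse an OBO file (id / name / is_a subset)
#'
#' Reads `[Term]` stanzas, keeping `id`, `name` and `is_a` fields and
#' skipping obsolete terms; all other relationship types are ignored.
#' Validates that every `is_a` target exists and that the hierarchy is
#' acyclic.
#'
#' @param file Path to an OBO file.
#' @return A [go_dag()] object.
#' @export
parse_obo <- function(file) {
  lines <- readLines(file, warn = FALSE)
  stanza_starts <- c(grep("^\\[", lines), length(lines) + 1L)
  ids <- character(0); nms <- character(0); parents <- list()
  for (i in seq_len(length(stanza_starts) - 1L)) {
    block <- lines[stanza_starts[i]:(stanza_starts[i + 1L] - 1L)]
    if (!identical(block[1L], "[Term]")) next
    get <- function(field) {
      v <- sub(paste0("^", field, ": *"), "",
               grep(paste0("^", field, ":"), block, value = TRUE))
      sub(" *!.*$", "", v)
    }
    if (any(grepl("^is_obsolete: *true", block))) next
    id <- get("id")
    if (length(id) != 1L) next
    ids <- c(ids, id)
    nm <- get("name")
    nms <- c(nms, if (length(nm)) nm[1L] else id)
    parents[[id]] <- get("is_a")
  }
  if (length(ids) == 0L) stop("no [Term] stanzas found", call. = FALSE)
  go_dag(setNames(nms, ids), parents)
}

#' Write an ontology DAG as an OBO subset
#'
#' @param dag A `go_dag`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_obo <- function(dag, file) {
  stopifnot(inherits(dag, "go_dag"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (id in names(dag$terms)) {
    p <- dag$parents[[id]]
    writeLines(c("", "[Term]", paste0("id: ", id),
                 paste0("name: ", dag$terms[[id]]),
                 if (length(p)) paste0("is_a: ", p)), con)
  }
  invisible(file)
}

#' All proper ancestors of a term
#'
#' @param dag A `go_dag`.
#' @param term Term id.
#' @return Character vector of ancestor ids (transitive `is_a` closure,
#'   excluding the term itself).
#' @export
go_ancestors <- function(dag, term) {
  stopifnot(inherits(dag, "go_dag"))
  if (!term %in% names(dag$terms)) {
    stop(sprintf("unknown term: %s", term), call. = FALSE)
  }
  seen <- character(0)
  stack <- dag$parents[[term]]
  while (length(stack)) {
    t <- stack[[1L]]; stack <- stack[-1L]
    if (t %in% seen) next
    seen <- c(seen, t)
    stack <- c(stack, dag$parents[[t]])
  }
  seen
}

#' Shortest is_a distance from a term to one of its ancestors
#'
#' Distance is the number of edges on the shortest directed `is_a` path;
#' `go_distance(dag, t, t)` is 0.
#'
#' @param dag A `go_dag`.
#' @param child Term id.
#' @param ancestor Term id reachable from `child` (or `child` itself).
#' @return Integer edge count.
#' @export
go_distance <- function(dag, child, ancestor) {
  d <- go_distances(dag, child)
  if (!ancestor %in% names(d)) {
    stop(sprintf("%s is not an ancestor of %s", ancestor, child),
         call. = FALSE)
  }
  d[[ancestor]]
}

# BFS over parent edges: named integer vector of shortest distances from
# `child` to itself (0) and every ancestor.
go_distances <- function(dag, child) {
  if (!child %in% names(dag$terms)) {
    stop(sprintf("unknown term: %s", child), call. = FALSE)
  }
  dist <- setNames(0L, child)
  frontier <- child
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- setdiff(unique(unlist(dag$parents[frontier])), names(dist))
    if (length(nxt)) dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Keep only the most-specific terms of a set
#'
#' Removes every term that is a proper ancestor of another term in the
#' set, leaving the most-specific (most-distant from the root) terms.
#'
#' @param dag A `go_dag`.
#' @param terms Character vector of term ids.
#' @return Character vector (subset of `terms`).
#' @export
most_specific <- function(dag, terms) {
  stopifnot(inherits(dag, "go_dag"))
  terms <- unique(as.character(terms))
  unknown <- setdiff(terms, names(dag$terms))
  if (length(unknown)) {
    stop(sprintf("unknown term(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  anc <- unique(unlist(lapply(terms, go_ancestors, dag = dag)))
  setdiff(terms, anc)
}

#' Common most-specific terms across enriched-term sets
#'
#' Summarizes several enriched-term sets (e.g. per starvation time point)
#' into terms shared by all of them, at the most specific level at which
#' sharing occurs:
#'
#' 1. all input sets are combined and reduced to their most-specific terms;
#' 2. for each such term, candidate terms are scanned in order of
#'    increasing shortest `is_a` distance -- starting, when
#'    `include_self = TRUE` (default), at the term itself (distance 0);
#' 3. at the first distance where at least one candidate is present in
#'    *every* input set, all equally distant qualifying candidates are
#'    marked common and the scan stops for that term;
#' 4. if no candidate at any distance is present in all sets, the term is
#'    marked non-common;
#' 5. finally the common set is reduced by removing terms that are proper
#'    ancestors of other common terms.
#'
#' @param dag A `go_dag`.
#' @param input_sets Non-empty list of character vectors of term ids.
#' @param include_self Whether the distance-0 candidate (the most-specific
#'   term itself) participates in the scan. The default treats a term
#'   present in all input sets as common by itself, which is the natural
#'   reading for summarizing shared overrepresentation; turning it off
#'   restricts the scan to proper parents.
#' @return Object of class `common_specific_result`: list with `common`,
#'   `non_common` (character vectors) and `provenance` (data frame
#'   `common_term`, `child`, `distance`: which most-specific child selected
#'   each common term and at what distance; recorded before the final
#'   ancestor reduction, so every child appears either here or in
#'   `non_common`).
#' @export
common_most_specific <- function(dag, input_sets, include_self = TRUE) {
  stopifnot(inherits(dag, "go_dag"))
  if (!is.list(input_sets) || length(input_sets) == 0L) {
    stop("`input_sets` must be a non-empty list of term-id vectors",
         call. = FALSE)
  }
  input_sets <- lapply(input_sets, function(s) unique(as.character(s)))
  all_terms <- unique(unlist(input_sets))
  unknown <- setdiff(all_terms, names(dag$terms))
  if (length(unknown)) {
    stop(sprintf("unknown term(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  children <- most_specific(dag, all_terms)
  common <- character(0)
  non_common <- character(0)
  prov <- list()
  for (child in children) {
    dist <- go_distances(dag, child)
    if (!include_self) dist <- dist[names(dist) != child]
    found <- FALSE
    for (d in sort(unique(dist))) {
      cands <- names(dist)[dist == d]
      hits <- cands[vapply(cands, function(t) {
        all(vapply(input_sets, function(s) t %in% s, logical(1)))
      }, logical(1))]
      if (length(hits)) {
        common <- union(common, hits)
        prov[[length(prov) + 1L]] <- data.frame(
          common_term = hits, child = child, distance = d
        )
        found <- TRUE
        break
      }
    }
    if (!found) non_common <- c(non_common, child)
  }
  # final redundancy reduction: drop common terms that are proper
  # ancestors of other common terms
  common <- most_specific(dag, common)
  provenance <- if (length(prov)) do.call(rbind, prov) else data.frame(
    common_term = character(0), child = character(0), distance = integer(0)
  )
  rownames(provenance) <- NULL
  structure(list(common = common, non_common = non_common,
                 provenance = provenance),
            class = "common_specific_result")
}

#' @export
print.common_specific_result <- function(x, ...) {
  cat(sprintf("<common_specific_result> %d common, %d non-common term(s)\n",
              length(x$common), length(x$non_common)))
  invisible(x)
}

#' Propagate annotations to ancestors (true-path rule)
#'
#' Closes each gene's term set under `is_a` ancestors, so a gene annotated
#' to a term counts for every ancestor of that term.
#'
#' @param dag A `go_dag`.
#' @param annotations Named list: gene -> character vector of term ids.
#' @return Annotations closed under ancestors, with attribute
#'   `propagated = TRUE`. Idempotent.
#' @export
propagate_annotations <- function(dag, annotations) {
  stopifnot(inherits(dag, "go_dag"), is.list(annotations))
  used <- unique(unlist(annotations))
  unknown <- setdiff(used, names(dag$terms))
  if (length(unknown)) {
    stop(sprintf("annotation term(s) not in ontology: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  closure <- new.env(parent = emptyenv())
  anc_of <- function(t) {
    if (!exists(t, closure, inherits = FALSE)) {
      assign(t, go_ancestors(dag, t), closure)
    }
    get(t, closure, inherits = FALSE)
  }
  out <- lapply(annotations, function(ts) {
    unique(c(ts, unlist(lapply(ts, anc_of))))
  })
  attr(out, "propagated") <- TRUE
  out
}
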