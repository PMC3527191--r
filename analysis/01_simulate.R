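#!/usr/bin/env Rscript
# Generate the synthetic study inputs: stained micrographs for a
# six-point starvation time course (thick 3 um hyphae giving way to thin
# 1 um secondary hyphae, with an increasing fraction of unstained
# ghosts), a random GO-like ontology with gene annotations, and a
# four-group expression matrix with planted fold changes.
#
# Writes under results/data/. Deterministic for a fixed SEED.

suppressMessages(library(mycostarve))
SEED <- 20260923L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## Micrographs: thin-population weight and ghost fraction increase with
## starvation time, emulating the gradual thick-to-thin transition.
schedule <- data.frame(
  time_point = c("pre_depletion", "day1", "day2", "day3", "day4", "day6"),
  thin_weight = c(0, 0.2, 0.35, 0.5, 0.65, 0.8),
  ghost_fraction = c(0, 0.1, 0.2, 0.3, 0.4, 0.5)
)
for (i in seq_len(nrow(schedule))) {
  tp <- schedule$time_point[i]
  pops <- data.frame(
    mean = c(3, 1), sd = c(0.3, 0.15),
    weight = c(1 - schedule$thin_weight[i], schedule$thin_weight[i])
  )
  pops <- pops[pops$weight > 0, ]
  for (j in 1:3) {
    b <- generate_mycelium_image(
      45, populations = pops,
      empty_ghost_fraction = schedule$ghost_fraction[i],
      seed = SEED + 100L * i + j
    )
    write_image_bundle(
      b,
      file.path(out, sprintf("%s_img%d.tif", tp, j)),
      file.path(out, sprintf("%s_img%d_truth.tsv", tp, j))
    )
  }
  message(sprintf("time point %s: 3 micrographs written", tp))
}
write.table(schedule, file.path(out, "schedule.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## Ontology + annotations with one planted term.
dag <- generate_go_dag(60, max_parents = 3, seed = SEED + 1L)
write_obo(dag, file.path(out, "ontology.obo"))
leaf <- setdiff(names(dag$terms), unlist(dag$parents))[1]
ann <- generate_annotations(
  dag, n_genes = 2000,
  planted = data.frame(term = leaf, study_fraction = 0.4,
                       background_fraction = 0.05),
  study_size = 200, seed = SEED + 2L
)
write_annotations(ann$annotations, file.path(out, "annotations.tsv"))
writeLines(ann$study, file.path(out, "study_genes.txt"))
message(sprintf("ontology: %d terms, planted term %s", 60, leaf))

## Expression study: 2000 genes, 10% DE, the study's replicate layout.
bundle <- generate_expression(2000, de_fraction = 0.1, fc_range = c(2, 8),
                              noise_sd = 0.3, seed = SEED + 3L)
write_expression(bundle, file.path(out, "expression.tsv"),
                 file.path(out, "groups.tsv"))
write.table(
  data.frame(gene = rownames(bundle$truth), bundle$truth),
  file.path(out, "expression_truth.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE
)
message(sprintf("expression: %d genes x %d samples, %d DE genes",
                nrow(bundle$matrix), ncol(bundle$matrix),
                length(bundle$de_genes)))

## Annotations over the expression universe: a second planted term marks
## the conjointly upregulated genes (a coordinated "process" induced at
## every starvation time point); all other genes draw one random term.
leaf2 <- setdiff(names(dag$terms), unlist(dag$parents))[2]
conjoint_up <- rownames(bundle$truth)[apply(bundle$truth > 1, 1, all)]
set.seed(SEED + 4L)
ann_expr <- setNames(lapply(rownames(bundle$matrix), function(g) {
  if (g %in% conjoint_up) leaf2 else sample(names(dag$terms), 1)
}), rownames(bundle$matrix))
write_annotations(ann_expr, file.path(out, "annotations_expression.tsv"))
message(sprintf("expression annotations: term %s planted on %d conjointly upregulated genes",
                leaf2, length(conjoint_up)))
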