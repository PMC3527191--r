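make_matrix <- function(values, genes, samples) {
  matrix(values, length(genes), length(samples),
         dimnames = list(genes, samples))
}

test_that("filter_rows drops listed ids and warns on absent ones", {
  m <- make_matrix(1:20, paste0("p", 1:10), c("s1", "s2"))
  expect_message(out <- filter_rows(m, character(0)), "removed 0")
  expect_equal(out, m)
  expect_message(out <- filter_rows(m, c("p1", "p5", "p9")), "removed 3")
  expect_equal(nrow(out), 7)
  expect_warning(expect_message(filter_rows(m, "nope")), "not present")
})

test_that("collapse_multiprobe averages probes per transcript", {
  m <- make_matrix(c(4, 6, 10, 2, 8, 12), paste0("p", 1:3), c("s1", "s2"))
  map <- c(p1 = "t1", p2 = "t1", p3 = "t2")
  out <- collapse_multiprobe(m, map)
  expect_equal(out["t1", "s1"], 5)
  expect_equal(out["t2", ], m["p3", ])

  # identity up to renaming when all transcripts are single-probe
  map1 <- setNames(paste0("t", 1:3), paste0("p", 1:3))
  out1 <- collapse_multiprobe(m, map1)
  expect_equal(unname(out1[order(rownames(out1)), ]), unname(m))

  expect_error(collapse_multiprobe(m, map[1:2]), "absent from the map")

  # random matrix vs an independent aggregate() oracle
  set.seed(2)
  big <- make_matrix(runif(60), paste0("p", 1:12), paste0("s", 1:5))
  mapr <- setNames(sample(paste0("t", 1:5), 12, replace = TRUE),
                   rownames(big))
  got <- collapse_multiprobe(big, mapr)
  ref <- aggregate(big, by = list(tx = unname(mapr[rownames(big)])), mean)
  refm <- as.matrix(ref[, -1]); rownames(refm) <- ref$tx
  expect_equal(got[rownames(refm), ], refm)
})

test_that("scale_to_reference pins the reference mean at 100", {
  m <- make_matrix(c(3, 1, 5, 3, 6, 9), c("actA", "g2"),
                   c("e1", "e2", "d1"))
  groups <- c(e1 = "exp", e2 = "exp", d1 = "day1")
  out <- scale_to_reference(m, groups, "actA", "exp")
  expect_equal(mean(out["actA", c("e1", "e2")]), 100)
  # g2's exponential mean (2) is half the reference mean (4): scales to 50
  expect_equal(mean(out["g2", c("e1", "e2")]), 50)
  zero <- make_matrix(c(0, 0, 1, 1), c("ref", "g"), c("e1", "d1"))
  expect_error(
    scale_to_reference(zero, c(e1 = "exp", d1 = "day1"), "ref", "exp"),
    "zero"
  )
})

test_that("fold_changes reproduce published worked examples", {
  tab <- autophagy_expression()
  # reconstruct a one-sample-per-group matrix from the printed group means
  m <- as.matrix(tab[, c("exp", "day1", "day3", "day6")])
  rownames(m) <- tab$orf
  groups <- setNames(c("exp", "day1", "day3", "day6"),
                     c("exp", "day1", "day3", "day6"))
  fc <- fold_changes(m, groups, "exp")
  atg9 <- tab$orf[tab$gene == "atg9"]
  expect_equal(unname(fc[atg9, c("day1", "day3", "day6")]),
               c(8.0, 6.6, 5.8), tolerance = 1e-9)
  atg3 <- tab$orf[tab$gene == "atg3"]
  expect_equal(unname(fc[atg3, "day1"]), 2.9, tolerance = 1e-9)
  expect_equal(unname(fc[atg3, "day6"]), 2.9, tolerance = 1e-9)

  # equal means give fold change 1
  eq <- make_matrix(rep(5, 4), "g", c("e1", "e2", "d1", "d2"))
  expect_equal(
    unname(fold_changes(eq, c(e1 = "exp", e2 = "exp", d1 = "day1",
                              d2 = "day1"), "exp")[, "day1"]), 1)
})

test_that("moderated t with d0 = 0 equals the ordinary pooled t-test", {
  set.seed(8)
  m <- make_matrix(rnorm(50 * 5, 6), paste0("g", 1:50),
                   c("e1", "e2", "e3", "d1", "d2"))
  groups <- c(e1 = "exp", e2 = "exp", e3 = "exp", d1 = "day1", d2 = "day1")
  fit <- moderated_t_fit(m, groups, c("day1", "exp"), prior_df = 0)
  for (i in c(1, 17, 50)) {
    tt <- t.test(m[i, 4:5], m[i, 1:3], var.equal = TRUE)
    expect_equal(fit$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(fit$p[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("single-gene fit matches the hand-written formula", {
  x <- c(e1 = 5.1, e2 = 4.9, e3 = 5.3, d1 = 7.2, d2 = 6.8)
  m <- matrix(x, 1, dimnames = list("g1", names(x)))
  groups <- c(e1 = "exp", e2 = "exp", e3 = "exp", d1 = "day1", d2 = "day1")
  fit <- moderated_t_fit(m, groups, c("day1", "exp"))
  m1 <- mean(x[4:5]); m0 <- mean(x[1:3])
  s2 <- (sum((x[4:5] - m1)^2) + sum((x[1:3] - m0)^2)) / 3
  t_hand <- (m1 - m0) / sqrt(s2 * (1 / 2 + 1 / 3))
  expect_equal(fit$t, t_hand, tolerance = 1e-10)
  expect_equal(fit$mean_diff, m1 - m0, tolerance = 1e-12)
})

test_that("shrinkage limits behave as expected", {
  set.seed(9)
  m <- make_matrix(rnorm(200 * 5, 6), paste0("g", 1:200),
                   c("e1", "e2", "e3", "d1", "d2"))
  groups <- c(e1 = "exp", e2 = "exp", e3 = "exp", d1 = "day1", d2 = "day1")
  f0 <- moderated_t_fit(m, groups, c("day1", "exp"), prior_df = 0)
  finf <- moderated_t_fit(m, groups, c("day1", "exp"), prior_df = Inf)
  fhat <- moderated_t_fit(m, groups, c("day1", "exp"))
  # d0 = 0: raw per-gene variances drive the statistic
  expect_equal(f0$t, f0$mean_diff / sqrt(f0$s2 * (1 / 2 + 1 / 3)),
               tolerance = 1e-12)
  # d0 = Inf: one common variance, so t is proportional to the mean diff
  se_inf <- f0$mean_diff / finf$t
  expect_lt(diff(range(se_inf)), 1e-10)
  # the estimated prior interpolates: posterior variances lie between the
  # per-gene and the pooled extremes (up to numerical slack)
  s2_post_hat <- (fhat$mean_diff / fhat$t)^2 / (1 / 2 + 1 / 3)
  expect_true(all(s2_post_hat <= pmax(f0$s2, attr(fhat, "s02")) + 1e-9))
  expect_true(all(s2_post_hat >= pmin(f0$s2, attr(fhat, "s02")) - 1e-9))
})

test_that("moderated fit agrees with the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(10)
  n <- 500
  m <- make_matrix(rnorm(n * 5, 6, 1), paste0("g", 1:n),
                   c("e1", "e2", "e3", "d1", "d2"))
  # heterogeneous gene variances so shrinkage is non-trivial
  m <- m * sqrt(rchisq(n, 4) / 4)
  groups <- c(e1 = "exp", e2 = "exp", e3 = "exp", d1 = "day1", d2 = "day1")
  fit <- moderated_t_fit(m, groups, c("day1", "exp"))
  design <- cbind(1, c(0, 0, 0, 1, 1))
  lf <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(attr(fit, "d0"), lf$df.prior, tolerance = 0.05)
  expect_equal(attr(fit, "s02"), lf$s2.prior, tolerance = 0.02)
  expect_equal(fit$t, unname(lf$t[, 2]), tolerance = 1e-6)
  expect_equal(fit$p, unname(lf$p.value[, 2]), tolerance = 1e-6)
})

test_that("call_de applies the strict q threshold with no fold-change filter", {
  res <- structure(
    data.frame(gene = c("a", "b", "c", "d"),
               mean_diff = c(1, -1, 2, 0.001),
               fold_change = 2^c(1, -1, 2, 0.001),
               s2 = rep(1, 4), t = c(5, -5, 1, 4), df = rep(10, 4),
               p = c(1e-5, 2e-5, 0.5, 3e-5)),
    class = c("contrast_result", "data.frame")
  )
  called <- call_de(res, q_crit = 0.005)
  expect_equal(called$call, c("up", "down", "ns", "up"))
  # boundary: q exactly at the threshold is not significant
  res$p <- c(0.005, 0.005, 0.005, 0.005)   # BH keeps them at 0.005
  called <- call_de(res, q_crit = 0.005)
  expect_true(all(called$q == 0.005))
  expect_true(all(called$call == "ns"))
})

test_that("venn_counts matches brute-force set algebra", {
  u <- paste0("g", 1:30)
  mk <- function(up, down) {
    calls <- setNames(rep("ns", 30), u)
    calls[up] <- "up"; calls[down] <- "down"
    calls
  }
  identical_sets <- mk(u[1:5], u[6:8])
  v <- venn_counts(identical_sets, identical_sets, identical_sets)
  expect_equal(unname(v$up["d1d3d6"]), 5)
  expect_equal(unname(v$down["d1d3d6"]), 3)
  expect_equal(sum(v$up), 5)

  disjoint <- venn_counts(mk(u[1:3], NULL), mk(u[4:6], NULL),
                          mk(u[7:9], NULL))
  expect_equal(unname(disjoint$conjoint_up), 0)
  expect_equal(sum(disjoint$up), 9)

  set.seed(12)
  for (i in 1:10) {
    s1 <- mk(sample(u, 8), sample(u, 4))
    s3 <- mk(sample(u, 8), sample(u, 4))
    s6 <- mk(sample(u, 8), sample(u, 4))
    v <- venn_counts(s1, s3, s6)
    up1 <- names(s1)[s1 == "up"]; up3 <- names(s3)[s3 == "up"]
    up6 <- names(s6)[s6 == "up"]
    expect_equal(unname(v$up["d1d3d6"]),
                 length(intersect(intersect(up1, up3), up6)))
    expect_equal(sum(v$up), length(union(union(up1, up3), up6)))
    expect_equal(v$n_de_any,
                 sum(s1 != "ns" | s3[names(s1)] != "ns" | s6[names(s1)] != "ns"))
  }

  expect_error(venn_counts(mk(u[1], NULL), mk(u[2], NULL),
                           setNames("up", "other")), "universe")
})

test_that("linear fold changes cohere with log2 differences on balanced data", {
  # when every replicate equals its group value exactly, the arithmetic
  # linear-mean ratio equals 2^(difference of log2 means)
  m <- make_matrix(c(2, 2, 2, 8, 8), "g", c("e1", "e2", "e3", "d1", "d2"))
  groups <- c(e1 = "exp", e2 = "exp", e3 = "exp", d1 = "day1", d2 = "day1")
  fc_lin <- fold_changes(m, groups, "exp")["g", "day1"]
  fit <- moderated_t_fit(log2(m), groups, c("day1", "exp"))
  expect_equal(unname(fc_lin), unname(2^fit$mean_diff), tolerance = 1e-12)
})
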