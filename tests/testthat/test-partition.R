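## Small hand-checkable phenotype matrices for partition logic.
fake_matrix <- function(states, f1 = NULL, mu = NULL) {
  n <- nrow(states)
  pts <- data.frame(f1 = f1 %||% seq(0, 1, length.out = n),
                    f2 = 1 - (f1 %||% seq(0, 1, length.out = n)),
                    mu = mu %||% seq(0, 0.2, length.out = n))
  structure(list(points = pts, states = states,
                 min = states == "x", max = states == "x", eps = 1e-9),
            class = "phenotype_matrix")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("exact partition groups identical vectors and loses nothing", {
  st <- rbind(c("0", "++"), c("0", "++"), c("-", "++"), c("0", "-+"),
              c("-", "++"))
  colnames(st) <- c("r1", "r2")
  pm <- fake_matrix(st)
  ep <- exact_partition(pm)
  expect_identical(max(ep$zone), 3L)
  expect_identical(ep$zone[1], ep$zone[2])
  expect_identical(ep$zone[3], ep$zone[5])
  ## reconstructing rows from descriptors reproduces the matrix exactly
  rec <- ep$descriptors[ep$zone, , drop = FALSE]
  dimnames(rec) <- dimnames(st)
  expect_identical(rec, st)
  ## all identical -> one zone; all distinct -> n zones
  same <- matrix("++", 4, 2, dimnames = list(NULL, c("a", "b")))
  expect_identical(max(exact_partition(fake_matrix(same))$zone), 1L)
  dif <- cbind(a = c("0", "-", "+", "-+"), b = rep("0", 4))
  expect_identical(max(exact_partition(fake_matrix(dif))$zone), 4L)
})

test_that("clustering at k = #distinct vectors reproduces the exact partition", {
  cm <- crossfeed_community
  g <- build_grid(cm, 7)
  pm <- phenotype_matrix(cm, g)
  ep <- exact_partition(pm)
  k <- nrow(unique(pm$states))
  cp <- cluster_partition(pm, k)
  ## same set partition: cluster labels are a bijection of zone labels
  tab <- table(ep$zone, cp$cluster)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  ## identical vectors always co-cluster at any k
  for (kk in c(2, 3, k)) {
    cl <- cluster_partition(pm, kk)$cluster
    key <- apply(pm$states, 1, paste, collapse = "|")
    expect_true(all(tapply(cl, key, function(x) length(unique(x))) == 1))
  }
  expect_error(cluster_partition(pm, k + 1), "distinct")
})

test_that("consensus descriptors follow the strict 80 percent rule", {
  ## constructed 20-point cluster: 17/20 = 85% agree -> consensus
  st <- cbind(r1 = c(rep("++", 17), rep("-0", 3)),
              r2 = c(rep("0", 10), rep("-", 10)),
              r3 = rep("-+", 20))
  expect_identical(unname(consensus_descriptor(st)["r1"]), "++")
  expect_true(is.na(consensus_descriptor(st)["r2"]))   # 50/50 split
  expect_identical(unname(consensus_descriptor(st)["r3"]), "-+")
  ## exactly 80% does NOT reach strictly-over consensus
  st2 <- cbind(r = c(rep("+", 16), rep("-", 4)))
  expect_true(is.na(consensus_descriptor(st2)["r"]))
  ## 81% does
  st3 <- cbind(r = c(rep("+", 81), rep("-", 19)))
  expect_identical(unname(consensus_descriptor(st3)["r"]), "+")
  ## singleton cluster keeps its own states
  expect_identical(unname(consensus_descriptor(st[1, , drop = FALSE])),
                   c("++", "0", "-+"))
  expect_error(consensus_descriptor(st[0, , drop = FALSE]), "empty")
})

test_that("changing reactions and display ordering are deterministic", {
  st <- cbind(stay = rep("++", 12),
              switch = c(rep("0", 6), rep("--", 6)),
              wobble = c(rep("+", 5), "-", rep("+", 6)))
  pm <- fake_matrix(st, mu = c(rep(0.01, 6), rep(0.2, 6)))
  cp <- cluster_partition(pm, 2)
  chg <- changing_reactions(cp)
  expect_true("switch" %in% chg)
  expect_false("stay" %in% chg)
  ## low-mu cluster is displayed first
  ord <- order_clusters(cp)
  mu_means <- tapply(pm$points$mu, cp$cluster, mean)
  expect_identical(ord, as.integer(names(sort(mu_means))))
  ## single cluster: nothing changes
  cp1 <- cluster_partition(fake_matrix(st[1:3, , drop = FALSE]), 1)
  expect_identical(changing_reactions(cp1), character(0))
  ## stable under point order permutation: two unambiguous blocks land on
  ## the same point partition regardless of row order
  st2 <- cbind(a = c(rep("0", 6), rep("--", 6)),
               b = c(rep("-", 6), rep("++", 6)))
  mu2 <- c(rep(0.01, 6), rep(0.2, 6))
  base <- cluster_partition(fake_matrix(st2, mu = mu2), 2)$cluster
  set.seed(11)
  perm <- sample(nrow(st2))
  permd <- cluster_partition(fake_matrix(st2[perm, , drop = FALSE],
                                         mu = mu2[perm]), 2)$cluster
  ## same grouping of the same points (labels may swap)
  expect_identical(permd[order(perm)][1:6], rep(permd[order(perm)][1], 6))
  expect_identical(length(unique(permd[order(perm)][7:12])), 1L)
  expect_false(permd[order(perm)][1] == permd[order(perm)][12])
  expect_identical(base[1:6], rep(base[1], 6))
})

test_that("cluster-count selection returns the smallest sufficient k", {
  ## all identical -> k = 1
  same <- matrix("++", 6, 2, dimnames = list(NULL, c("a", "b")))
  expect_identical(select_cluster_count(fake_matrix(same)), 1L)
  ## two clean blocks need k = 2
  st <- cbind(a = c(rep("0", 10), rep("++", 10)),
              b = c(rep("-", 10), rep("+", 10)))
  expect_identical(select_cluster_count(fake_matrix(st)), 2L)
  ## score threshold is inclusive (>= 0.80)
  st2 <- cbind(a = c(rep("0", 8), rep("++", 2)))   # modal share exactly 0.8
  expect_identical(select_cluster_count(fake_matrix(st2), k_range = 1), 1L)
  expect_error(select_cluster_count(fake_matrix(st), k_range = integer(0)),
               "empty")
})

test_that("consensus coverage is monotone non-decreasing in k on the toy", {
  cm <- crossfeed_community
  g <- build_grid(cm, 7)
  pm <- phenotype_matrix(cm, g)
  enc <- agspace:::onehot_states(pm$states)
  d <- round(stats::dist(enc, method = "binary"), 12)
  hc <- stats::hclust(d, method = "average")
  kmax <- nrow(unique(pm$states))
  worst <- vapply(seq_len(kmax), function(k)
    min(agspace:::reaction_scores(pm$states, stats::cutree(hc, k = k))),
    numeric(1))
  expect_true(all(diff(worst) >= -1e-12))
})
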