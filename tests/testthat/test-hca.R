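test_that("single linkage merges the unique closest pair first", {
  D <- matrix(c(0, 1, 5,
                1, 0, 5,
                5, 5, 0), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- linkage_cluster(D, "single")
  expect_equal(tree$hclust$height[1], 1)
  expect_setequal(tree$labels[tree$members[[1]]], c("A", "B"))
})

test_that("all seven linkages agree with the brute-force Lance-Williams oracle", {
  methods <- c("single", "complete", "average", "weighted", "centroid",
               "median", "ward")
  for (s in 1:12) {
    D <- random_distance_matrix(8, seed = 100 + s)
    for (m in methods) {
      tree <- linkage_cluster(D, m)
      oracle <- lw_linkage_oracle(D, m)
      expect_equal(sort(tree$hclust$height), sort(oracle$heights),
                   tolerance = 1e-9,
                   label = sprintf("heights (%s, seed %d)", m, s))
    }
  }
})

test_that("ward separates two well-separated tight groups at the root", {
  set.seed(2)
  n <- 10
  D <- matrix(0.9, n, n)
  D[1:5, 1:5] <- 0.1
  D[6:10, 6:10] <- 0.1
  D <- D + matrix(runif(n * n, 0, 0.01), n)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(paste0("c", 1:n), paste0("c", 1:n))
  tree <- linkage_cluster(D, "ward")
  top <- cutree(tree$hclust, 2)
  expect_equal(length(unique(top[1:5])), 1L)
  expect_equal(length(unique(top[6:10])), 1L)
  expect_true(top[1] != top[6])
  expect_false(tree$inversions)
})

test_that("extract_w0_w1 matches the definition and the brute-force oracle", {
  # two leaves: root at its merge height, children are leaves
  D2 <- matrix(c(0, 0.8, 0.8, 0), 2)
  t2 <- linkage_cluster(D2, "ward")
  expect_equal(unname(extract_w0_w1(t2)), c(0.8, 0))

  # 4-point fixture: W1 equals the oracle's second-highest merge creating a
  # child of the root
  D4 <- random_distance_matrix(4, seed = 9)
  t4 <- linkage_cluster(D4, "ward")
  oracle <- lw_linkage_oracle(D4, "ward")
  root_members <- oracle$members[[3]]
  child_heights <- vapply(seq_len(2), function(i) {
    # height of each root child: the oracle merge that created it, or 0 (leaf)
    hit <- which(vapply(oracle$members[1:2], function(mm) {
      length(mm) > 0 && all(mm %in% root_members) &&
        length(mm) < length(root_members)
    }, logical(1)))
    if (length(hit) == 0) 0 else max(oracle$heights[hit])
  }, numeric(1))
  expect_equal(unname(extract_w0_w1(t4))[1], oracle$heights[3], tolerance = 1e-9)
  expect_equal(unname(extract_w0_w1(t4))[2], max(child_heights, 0),
               tolerance = 1e-9)

  expect_error(extract_w0_w1(structure(list(labels = "a"),
                                       class = "iso_dendrogram")),
               class = "isoclust_data_error")
})

test_that("W1/W0 is bounded by 1 and ward heights are inversion-free on random matrices", {
  for (s in 1:100) {
    D <- random_distance_matrix(7, seed = 500 + s)
    tree <- linkage_cluster(D, "ward")
    w <- extract_w0_w1(tree)
    expect_lte(w["W1"], w["W0"])
    expect_gte(w["W1"], 0)
    expect_true(all(diff(tree$hclust$height) >= -1e-12))
  }
})

test_that("linkage_cluster is invariant to input permutation up to relabeling", {
  D <- random_distance_matrix(9, seed = 77)
  dimnames(D) <- list(paste0("c", 1:9), paste0("c", 1:9))
  t1 <- linkage_cluster(D, "ward")
  perm <- c(4, 9, 1, 7, 2, 8, 3, 6, 5)
  t2 <- linkage_cluster(D[perm, perm], "ward")
  expect_equal(sort(t1$hclust$height), sort(t2$hclust$height), tolerance = 1e-12)
  m1 <- sort(vapply(t1$members, function(ii) {
    paste(sort(t1$labels[ii]), collapse = ",")
  }, character(1)))
  m2 <- sort(vapply(t2$members, function(ii) {
    paste(sort(t2$labels[ii]), collapse = ",")
  }, character(1)))
  expect_equal(m1, m2)
})

test_that("isomorphic_threshold reproduces the reference arithmetic", {
  expect_equal(isomorphic_threshold(1.29, 0.6), 0.774)
  expect_equal(round(isomorphic_threshold(1.29, 0.6), 2), 0.77)
  expect_equal(round(isomorphic_threshold(1.29, 0.7), 2), 0.9)
  expect_equal(isomorphic_threshold(1.0, 0.6), 0.6)
  expect_equal(isomorphic_threshold(1.0, 0.7), 0.7)
  expect_equal(isomorphic_threshold(0, 0.65), 0)
  expect_error(isomorphic_threshold(1, 1.2), class = "isoclust_config_error")
  expect_error(isomorphic_threshold(1, 0), class = "isoclust_config_error")
})

test_that("nominate_polymorphs returns the two root children when both sit under the threshold", {
  # block structure: two tight groups -> both root children far below 0.6 W0
  D <- matrix(0.95, 12, 12)
  D[1:6, 1:6] <- 0.2
  D[7:12, 7:12] <- 0.2
  diag(D) <- 0
  dimnames(D) <- list(paste0("c", 1:12), paste0("c", 1:12))
  tree <- linkage_cluster(D, "ward")
  rep <- nominate_polymorphs(tree, min_cluster_fraction = 0.1)
  expect_equal(nrow(rep$candidates), 2)
  expect_setequal(unlist(rep$candidates$members[rep$candidates$n_members == 6][1]),
                  paste0("c", 1:6))
  expect_equal(rep$threshold_interval, c(0.6, 0.7) * tree$W0)
  expect_true(all(rep$candidates$height <= 0.7 * tree$W0))
})

test_that("small candidate clusters are reported as outliers, and assignments partition the leaves", {
  set.seed(4)
  # two groups of 10 plus a lone straggler far from both
  D <- matrix(0.9, 21, 21)
  D[1:10, 1:10] <- 0.2
  D[11:20, 11:20] <- 0.2
  D[21, ] <- 1.8
  D[, 21] <- 1.8
  diag(D) <- 0
  dimnames(D) <- list(paste0("c", 1:21), paste0("c", 1:21))
  tree <- linkage_cluster(D, "ward")
  rep <- nominate_polymorphs(tree, min_cluster_fraction = 0.1)
  expect_true("c21" %in% unlist(rep$outliers$members))
  asg <- tidy(rep)
  expect_setequal(asg$chunk_id, paste0("c", 1:21))
  expect_equal(anyDuplicated(asg$chunk_id), 0L)
})

test_that("single-population matrices do not mimic a two-polymorph split", {
  # on homogeneous data the sub-threshold cut produces only small fragments:
  # no pair of candidates each holding a group-sized share of the chunks, as
  # a genuine two-structure split does
  big_pairs <- 0
  model <- cc_model(within_a = c(0.974, 0.02), within_b = c(0.974, 0.02),
                    between = c(0.974, 0.02))
  for (s in 1:100) {
    D <- sample_cc_matrix(model, 10, 10, seed = 3000 + s)
    tree <- linkage_cluster(D, "ward")
    rep <- nominate_polymorphs(tree, R_low = 0.6, R_high = 0.6)
    n_big <- sum(rep$candidates$n_members >= 0.4 * 20)
    if (n_big >= 2) big_pairs <- big_pairs + 1
  }
  expect_lte(big_pairs, 5)
})

test_that("classification_score counts best-assignment accuracy", {
  D <- matrix(0.9, 8, 8)
  D[1:4, 1:4] <- 0.1
  D[5:8, 5:8] <- 0.1
  diag(D) <- 0
  dimnames(D) <- list(paste0("c", 1:8), paste0("c", 1:8))
  tree <- linkage_cluster(D, "ward")
  labels <- rep(c("A", "B"), each = 4)
  expect_equal(classification_score(tree, labels), 1)
  # flipped label names give the same score (assignment is maximised)
  expect_equal(classification_score(tree, rev(labels)), 1)
  # one leaf mislabelled -> (n-1)/n
  labels2 <- labels
  labels2[1] <- "B"
  expect_equal(classification_score(tree, labels2), 7 / 8)
  # named labels are matched by chunk id
  expect_equal(classification_score(tree, setNames(labels, paste0("c", 1:8))), 1)
  expect_error(classification_score(tree, labels, k = 9),
               class = "isoclust_config_error")
})

test_that("labels assigned independently of the tree score near one half", {
  set.seed(6)
  scores <- replicate(60, {
    D <- random_distance_matrix(40, seed = sample.int(1e6, 1))
    tree <- linkage_cluster(D, "ward")
    classification_score(tree, sample(rep(c("A", "B"), 20)))
  })
  # random balanced labels: expected best-assignment accuracy -> 0.5 + o(1)
  expect_equal(mean(scores), 0.56, tolerance = 0.06)
  expect_gt(min(scores), 0.45)
})

test_that("dendrogram exports are readable and carry the defined branch lengths", {
  D <- random_distance_matrix(6, seed = 21)
  dimnames(D) <- list(paste0("c", 1:6), paste0("c", 1:6))
  tree <- linkage_cluster(D, "ward")

  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, nwk)
  phy <- ape::read.tree(nwk)  # independent reader
  expect_setequal(phy$tip.label, paste0("c", 1:6))
  # every root-to-tip path length telescopes to W0
  depths <- ape::node.depth.edgelength(phy)[seq_len(6)]
  expect_equal(unname(depths), rep(tree$W0, 6), tolerance = 1e-9)

  js <- withr::local_tempfile(fileext = ".json")
  write_dendrogram_json(tree, js)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$W0, tree$W0)
  expect_length(parsed$nodes, 5)

  g <- glance(tree)
  expect_equal(g$W0, tree$W0)
  expect_equal(g$R_obs, tree$W1 / tree$W0)
  td <- tidy(tree)
  expect_equal(nrow(td), 5)
  expect_equal(td$height, tree$hclust$height)

  p <- autoplot(tree)
  expect_s3_class(p, "ggplot")
})
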