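test_that("euclidean distance matches hand arithmetic", {
  expect_equal(euclidean_distance(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(euclidean_distance(c(1, 0, 0), c(0, 1, 0)), sqrt(2))
  expect_equal(euclidean_distance(c(0.5, 0.5, 0), c(0.2, 0.3, 0.5)),
               sqrt(0.09 + 0.04 + 0.25))
  expect_error(euclidean_distance(c(1, 0), c(1, 0, 0)), "length")
})

test_that("distance-to-similarity fixes both simplex endpoints", {
  expect_equal(distance_to_similarity(0), 1)
  expect_equal(distance_to_similarity(sqrt(2)), 0)
  expect_equal(distance_to_similarity(sqrt(0.38)), 1 - sqrt(0.38) / sqrt(2),
               tolerance = 1e-12)
  expect_equal(distance_to_similarity(10), 0)  # clamped
  expect_error(distance_to_similarity(-0.1), "nonnegative")
  # alternative transform for sensitivity analysis
  expect_equal(distance_to_similarity(1, transform = "reciprocal"), 0.5)
})

test_that("file similarity matrix equals the double-loop oracle", {
  ident <- file_features(rbind(c(0.4, 0.6), c(0.4, 0.6)), c("A", "B"))
  expect_equal(file_similarity_matrix(ident)$values[1, 2], 1)
  orth <- file_features(rbind(c(1, 0), c(0, 1)), c("A", "B"))
  expect_equal(file_similarity_matrix(orth)$values[1, 2], 0)

  set.seed(3)
  feats <- random_features(6, 4)
  sim <- file_similarity_matrix(feats)
  expect_equal(unname(sim$values), oracle_similarity(feats$matrix))
  expect_equal(sim$values, t(sim$values))
  expect_true(all(diag(sim$values) == 1))
  expect_true(all(sim$values >= 0 & sim$values <= 1))
})

test_that("topic similarity uses renormalized column profiles", {
  # proportional columns are identical after renormalization
  m <- rbind(c(0.2, 0.4, 0.4), c(0.1, 0.2, 0.7))
  feats <- file_features(m, c("A", "B"))
  tsim <- topic_similarity_matrix(feats)
  expect_equal(tsim$values["topic1", "topic2"], 1)
  # disjoint-support columns over 2 files are maximally dissimilar
  dis <- file_features(rbind(c(1, 0), c(0, 1)), c("A", "B"))
  expect_equal(topic_similarity_matrix(dis)$values[1, 2], 0)

  set.seed(4)
  feats <- random_features(5, 4)
  prof <- apply(feats$matrix, 2, function(col) col / sum(col))
  expect_equal(unname(topic_similarity_matrix(feats)$values),
               oracle_similarity(t(prof)))
})

test_that("top_pairs filters symmetric associations at the cutoff", {
  set.seed(8)
  sim <- random_similarity(6)
  expect_true(all(vapply(top_pairs(sim, 1.01), nrow, integer(1)) == 0L))
  cutoff <- stats::median(sim$values[upper.tri(sim$values)])
  pairs <- top_pairs(sim, cutoff)
  for (i in seq_along(sim$labels)) {
    expected <- sim$labels[setdiff(which(sim$values[i, ] >= cutoff), i)]
    expect_equal(pairs[[i]]$label, expected)
    expect_equal(pairs[[i]]$score,
                 unname(round(sim$values[i, expected], 2)))
  }
  # a reported pair appears in both directions
  one <- similarity_matrix(rbind(c(1, 0.85, 0.1), c(0.85, 1, 0.2),
                                 c(0.1, 0.2, 1)), c("A", "B", "C"))
  p <- top_pairs(one, 0.8)
  expect_equal(p$A$label, "B")
  expect_equal(p$B$label, "A")
  expect_equal(p$A$score, 0.85)
  expect_equal(nrow(p$C), 0L)
})

test_that("threshold clustering yields connected components", {
  m <- similarity_matrix(rbind(c(1, 0.85, 0.10),
                               c(0.85, 1, 0.82),
                               c(0.10, 0.82, 1)), c("A", "B", "C"))
  cl <- threshold_clusters(m, 0.80)
  expect_equal(cl$clusters, list(c("A", "B", "C")))  # chained, one component

  none <- threshold_clusters(m, 0.99)
  expect_equal(none$clusters, list("A", "B", "C"))
  all_one <- threshold_clusters(m, 0)
  expect_equal(length(all_one$clusters), 1L)
})

test_that("threshold clustering matches igraph components on random matrices", {
  set.seed(12)
  for (rep in 1:10) {
    sim <- random_similarity(10)
    thr <- stats::runif(1, 0.2, 0.98)
    part <- threshold_clusters(sim, thr)
    adj <- (sim$values >= thr) * 1
    diag(adj) <- 0
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    expect_equal(canonical_partition(cluster_membership(part)[sim$labels]),
                 canonical_partition(comp))
    # partitions refine monotonically as the threshold increases
    finer <- threshold_clusters(sim, min(1, thr + 0.1))
    memb_coarse <- cluster_membership(part)
    memb_fine <- cluster_membership(finer)
    expect_equal(length(memb_fine), length(memb_coarse))
    for (cl in finer$clusters) {
      expect_equal(length(unique(memb_coarse[cl])), 1L)
    }
  }
})

test_that("similarity CSV and cluster JSON round-trip", {
  set.seed(9)
  sim <- random_similarity(5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_similarity_csv(sim, path)
  back <- read_similarity_csv(path)
  expect_equal(back$labels, sim$labels)
  expect_equal(back$values, sim$values, tolerance = 1e-12)

  cl <- threshold_clusters(sim, 0.7)
  jpath <- withr::local_tempfile(fileext = ".json")
  write_clusters_json(cl, jpath)
  parsed <- jsonlite::fromJSON(jpath, simplifyVector = FALSE)
  expect_equal(parsed$threshold, 0.7)
  expect_equal(lapply(parsed$clusters, unlist), cl$clusters)
})
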