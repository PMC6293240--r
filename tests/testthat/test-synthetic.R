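test_that("generation is deterministic and internally consistent", {
  cfg <- generator_config(seed = 5, D = 30, V = 60, doc_length_mean = 50)
  g1 <- generate_corpus(cfg)
  g2 <- generate_corpus(cfg)
  expect_identical(g1$corpus$documents, g2$corpus$documents)
  expect_identical(g1$truth$doc_topic, g2$truth$doc_topic)

  expect_true(all(abs(rowSums(g1$truth$topic_word) - 1) < 1e-12))
  expect_true(all(abs(rowSums(g1$truth$doc_topic) - 1) < 1e-12))
  expect_equal(length(g1$truth$group_of), 30L)
  # post counts follow the planted outcome floor
  expect_true(all(g1$corpus$documents$post_count >= 0))
  nonempty <- nzchar(g1$corpus$documents$text)
  expect_true(all(g1$corpus$documents$post_count[nonempty] >= 1))
})

test_that("infinite separation plants disjoint topic support per group", {
  g <- generate_corpus(generator_config(seed = 9, D = 24, K_true = 4,
                                        n_groups = 4,
                                        group_separation = Inf))
  dt <- g$truth$doc_topic
  groups <- g$truth$group_of
  for (gr in unique(groups)) {
    own <- dt[groups == gr, , drop = FALSE]
    other <- dt[groups != gr, , drop = FALSE]
    support <- colSums(own) > 0
    # groups share no planted topic mass
    expect_true(all(other[, support] == 0))
  }
})

test_that("group-level mixture means match the planted profiles", {
  cfg <- generator_config(seed = 2, D = 2000, K_true = 5, n_groups = 4,
                          group_separation = 20)
  g <- generate_corpus(cfg)
  leak <- 1 / 21
  own_of <- rep(1:4, length.out = 5)
  gm <- rowsum(g$truth$doc_topic, g$truth$group_of) /
    as.vector(table(g$truth$group_of))
  for (gr in 1:4) {
    own <- which(own_of == gr)
    prof <- rep(leak / 5, 5)
    prof[own] <- prof[own] + (1 - leak) / length(own)
    expect_lt(max(abs(gm[gr, ] - prof)), 0.02)
  }
  # mean document length tracks the Poisson mean within 3 standard errors
  len <- lengths(strsplit(g$corpus$documents$text, " ", fixed = TRUE))
  se <- sqrt(cfg$doc_length_mean / cfg$D)
  expect_lt(abs(mean(len) - cfg$doc_length_mean), 3 * se)
})

test_that("assignment solver matches exhaustive permutation search", {
  set.seed(14)
  for (n in c(2, 3, 5, 6)) {
    for (rep in 1:4) {
      cost <- matrix(runif(n * n), n, n)
      a <- solve_assignment(cost)
      expect_true(all(sort(a) == 1:n))  # a permutation
      expect_equal(sum(cost[cbind(1:n, a)]), oracle_assignment_cost(cost),
                   tolerance = 1e-12)
    }
  }
})

test_that("topic matching recovers identity and planted permutations", {
  set.seed(15)
  truth <- matrix(rgamma(4 * 30, 1), 4, 30)
  truth <- truth / rowSums(truth)
  m_id <- match_topics(truth, truth)
  expect_equal(m_id$mapping, 1:4)
  expect_equal(m_id$tv, rep(0, 4))

  perm <- c(3L, 1L, 4L, 2L)
  m_perm <- match_topics(truth[perm, ], truth)
  # estimated row matched to true topic k is the one carrying truth row k
  expect_equal(m_perm$mapping, order(perm))
  expect_equal(m_perm$total_cost, 0)

  est <- matrix(rgamma(3 * 20, 1), 3, 20)
  est <- est / rowSums(est)
  tr <- matrix(rgamma(3 * 20, 1), 3, 20)
  tr <- tr / rowSums(tr)
  m <- match_topics(est, tr)
  cost <- outer(1:3, 1:3, Vectorize(function(i, j) {
    0.5 * sum(abs(tr[i, ] - est[j, ]))
  }))
  expect_equal(m$total_cost, oracle_assignment_cost(cost), tolerance = 1e-12)
  expect_error(match_topics(est[1:2, ], tr), "differ")
})

test_that("recovery report scores clusters, rankings, and the null", {
  g <- generate_corpus(generator_config(seed = 19, D = 60))
  # truth compared against itself: clusters = planted groups
  truth_part <- structure(list(
    threshold = 0.8,
    clusters = unname(split(names(g$truth$group_of), g$truth$group_of))
  ), class = "cluster_partition")
  rep1 <- recovery_report(g$truth, partition = truth_part)
  expect_equal(rep1$ari, 1)

  # random partitions sit at the chance level
  set.seed(20)
  aris <- replicate(20, {
    rand <- sample(1:4, 60, replace = TRUE)
    adjusted_rand_index(rand, g$truth$group_of)
  })
  expect_lt(abs(mean(aris)), 0.1)

  # ranking on the true mixtures puts planted topics on top
  feats <- file_features(g$truth$doc_topic)
  rk <- rank_topics_by_aic(feats, engagement_outcome(g$corpus))
  rep2 <- recovery_report(g$truth, ranking = rk)
  expect_gte(rep2$hit_rate, 0.5)
})

test_that("ground truth serializes to JSON", {
  g <- generate_corpus(generator_config(seed = 3, D = 6, V = 30,
                                        doc_length_mean = 20))
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth_json(g$truth, path)
  parsed <- jsonlite::fromJSON(path)
  expect_equal(dim(parsed$topic_word), dim(g$truth$topic_word))
  expect_equal(unlist(parsed$group_of), g$truth$group_of)
})
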