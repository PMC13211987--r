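test_that("Jaccard distance follows the set formula", {
  expect_equal(jaccard_distance(c(1, 1, 0, 0), c(1, 1, 0, 0)), 0)
  expect_equal(jaccard_distance(c(1, 0, 0), c(0, 1, 1)), 1)
  expect_equal(jaccard_distance(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 - 1 / 3)
  expect_error(jaccard_distance(c(0, 0), c(1, 0)), "zero support")
  expect_error(jaccard_distance(c(1, 0), c(1, 0, 0)), "length")
})

test_that("support vectors flag the references attaining each read's best score", {
  tax <- taxonomy_map(c("r1", "r2", "r3"), 11:13, rep(1L, 3),
                      rep(1000000L, 3))
  tab <- data.frame(
    read = c("q1", "q1", "q2", "q2", "q3"),
    ref = c("r1", "r2", "r1", "r3", "r1"),
    score = c(0.9, 0.9, 0.95, 0.80, 0.85),
    read_len = 1000L, stringsAsFactors = FALSE)
  sup <- build_support_vectors(tab, tax)
  m <- sup[["1"]]
  expect_equal(m["r1", "q1"], 1L)  # tied best
  expect_equal(m["r2", "q1"], 1L)
  expect_equal(m["r1", "q2"], 1L)  # strict best
  expect_false("r3" %in% rownames(m))  # never attains a best score
  expect_equal(sum(m["r1", ]), 3L)
})

test_that("density clustering separates distant references and chains close ones", {
  # distance 1 - 1/13 ~ 0.92 > eps keeps two references apart
  far <- matrix(c(1, 1, 1, rep(0, 10),
                  1, 0, 0, rep(1, 10)), 2, 13, byrow = TRUE,
                dimnames = list(c("a", "b"), sprintf("q%d", 1:13)))
  expect_gt(jaccard_distance(far["a", ], far["b", ]), 0.9)
  cl_far <- density_cluster(list(`1` = far))
  expect_equal(length(unique(cl_far$cluster)), 2L)

  # a-b close, b-c close, a-c distant: one chained cluster
  chain <- matrix(c(1, 1, 1, 1, 0, 0,
                    0, 0, 1, 1, 1, 1,
                    0, 0, 0, 1, 1, 1), 3, 6, byrow = TRUE,
                  dimnames = list(c("a", "b", "c"), sprintf("q%d", 1:6)))
  cl_chain <- density_cluster(list(`1` = chain))
  expect_equal(length(unique(cl_chain$cluster)), 1L)

  single <- matrix(1L, 1, 2, dimnames = list("a", c("q1", "q2")))
  cl_one <- density_cluster(list(`1` = single))
  expect_equal(nrow(cl_one), 1L)
  expect_equal(cl_one$representative, "a")
})

test_that("with min_samples = 1 clustering equals eps-graph components", {
  for (seed in 1:20) {
    m <- random_support_matrix(seed)
    cl <- density_cluster(list(`1` = m), eps = 0.9)
    d <- strainsift:::jaccard_matrix(m[sort(rownames(m)), , drop = FALSE])
    want <- oracle_eps_components(d, 0.9)
    got <- cl$cluster[match(sort(rownames(m)), cl$ref)]
    # same partition up to label permutation
    expect_equal(length(unique(got)), length(unique(want)))
    expect_true(all(tapply(want, got, function(x) length(unique(x))) == 1L))
  }
})

test_that("clustering is invariant to reference row order", {
  m <- random_support_matrix(99)
  cl1 <- density_cluster(list(`1` = m))
  perm <- sample(nrow(m))
  cl2 <- density_cluster(list(`1` = m[perm, , drop = FALSE]))
  cl2 <- cl2[match(cl1$ref, cl2$ref), ]
  same1 <- outer(cl1$cluster, cl1$cluster, `==`)
  same2 <- outer(cl2$cluster, cl2$cluster, `==`)
  expect_equal(same1, same2)
})

test_that("min_samples above 1 can demote sparse references to singletons", {
  # b bridges a and c; with min_samples = 3 only b has 3 eps-neighbours
  chain <- matrix(c(1, 1, 1, 1, 0, 0,
                    0, 0, 1, 1, 1, 1,
                    0, 0, 0, 1, 1, 1), 3, 6, byrow = TRUE,
                  dimnames = list(c("a", "b", "c"), sprintf("q%d", 1:6)))
  cl <- density_cluster(list(`1` = chain), eps = 0.7, min_samples = 3L)
  expect_equal(nrow(cl), 3L)
  expect_true(length(unique(cl$cluster)) >= 1L)
})

test_that("cluster abundance sums members under the representative", {
  clusters <- data.frame(species_taxid = 1L, cluster = c(1L, 1L, 2L),
                         ref = c("r1", "r2", "r3"),
                         representative = c("r1", "r1", "r3"),
                         stringsAsFactors = FALSE)
  class(clusters) <- c("strain_clusters", "data.frame")
  asg <- data.frame(read_id = sprintf("q%d", 1:9),
                    ref_id = c(rep("r1", 5), rep("r2", 3), "r3"),
                    strain_taxid = NA_integer_,
                    species_taxid = NA_integer_, score = 0.9,
                    status = "unique", stringsAsFactors = FALSE)
  class(asg) <- c("read_assignments", "data.frame")
  ab <- cluster_abundance(asg, clusters)
  expect_equal(ab$read_count[ab$ref_id == "r1"], 8L)
  expect_equal(ab$read_count[ab$ref_id == "r3"], 1L)
  expect_equal(sum(ab$read_count), 9L)

  # all-singleton clustering reproduces the per-reference profile
  singletons <- clusters
  singletons$cluster <- 1:3
  singletons$representative <- singletons$ref
  ab2 <- cluster_abundance(asg, singletons)
  prof <- count_abundance(asg)
  expect_equal(ab2$read_count, prof$read_count)
})

test_that("representatives carry the largest mapping support", {
  m <- matrix(c(1, 1, 1, 1,
                1, 1, 0, 0), 2, 4, byrow = TRUE,
              dimnames = list(c("rB", "rA"), sprintf("q%d", 1:4)))
  stats <- data.frame(ref = c("rA", "rB"), species_taxid = 1L,
                      unique_count = c(0L, 2L), nonunique_count = c(2L, 2L),
                      total = c(2L, 4L), stringsAsFactors = FALSE)
  cl <- density_cluster(list(`1` = m), stats = stats)
  expect_equal(length(unique(cl$cluster)), 1L)
  expect_equal(unique(cl$representative), "rB")
})
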