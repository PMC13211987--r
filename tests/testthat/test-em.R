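toy_scores <- function(df) {
  class(df) <- c("contig_scores", "data.frame")
  df
}

test_that("EM initialization: uniform priors, row-max-normalized conditionals", {
  tab <- toy_scores(data.frame(
    contig = c("c1", "c1", "c2"), ref = c("r1", "r2", "r3"),
    score = c(150, 75, 40), stringsAsFactors = FALSE))
  st <- em_initialize(tab)
  expect_equal(unname(st$prior), rep(1 / 3, 3))
  expect_equal(st$pairs$cond[st$pairs$contig == "c1"], c(1.0, 0.5))
  expect_equal(st$pairs$cond[st$pairs$contig == "c2"], 1.0)
})

test_that("E-step posteriors follow Bayes with the current prior", {
  tab <- toy_scores(data.frame(
    contig = "c1", ref = c("r1", "r2"), score = c(100, 50),
    stringsAsFactors = FALSE))
  st <- em_initialize(tab)
  # conditionals {1.0, 0.5}, uniform priors -> posteriors {2/3, 1/3}
  expect_equal(st$pairs$posterior, c(2 / 3, 1 / 3))
})

test_that("a symmetric instance is a fixed point of the EM step", {
  tab <- toy_scores(data.frame(
    contig = "c1", ref = c("r1", "r2"), score = c(80, 80),
    stringsAsFactors = FALSE))
  st <- em_initialize(tab)
  st2 <- em_step(st)
  expect_equal(st2$pairs$posterior, c(0.5, 0.5))
  expect_equal(unname(st2$prior), c(0.5, 0.5))
  expect_equal(st2$loglik, st$loglik)
})

test_that("EM matches the brute-force oracle on random small instances", {
  for (seed in 1:25) {
    tab <- random_score_instance(seed)
    n_iter <- 7L
    got <- run_em(tab, max_iter = n_iter, tol = 0)
    want <- oracle_em(tab, n_iter)
    expect_equal(got$iterations, n_iter)
    expect_equal(em_posterior_matrix(got), want$posterior,
                 tolerance = 1e-10)
    expect_equal(got$prior, want$prior, tolerance = 1e-10)
    expect_equal(got$loglik_trace, want$loglik_trace, tolerance = 1e-10)
  }
})

test_that("the log-likelihood trace is non-decreasing", {
  for (seed in 26:35) {
    st <- run_em(random_score_instance(seed), max_iter = 40L, tol = 0)
    expect_true(all(diff(c(st$loglik_trace)) >= -1e-9))
  }
})

test_that("the literal M-step leaves priors summing to x/|M|, the default renormalizes", {
  tab <- random_score_instance(99)
  st <- em_initialize(tab)
  st_renorm <- em_step(st)
  expect_equal(sum(st_renorm$prior), 1, tolerance = 1e-12)
  st_lit <- em_step(st, literal_mstep = TRUE)
  x <- length(unique(tab$contig))
  expect_equal(sum(st_lit$prior), x / nrow(tab), tolerance = 1e-12)
})

test_that("a single-reference contig keeps posterior 1 at convergence", {
  tab <- toy_scores(data.frame(
    contig = c("c1", "c2", "c2"), ref = c("r1", "r1", "r2"),
    score = c(90, 50, 45), stringsAsFactors = FALSE))
  st <- run_em(tab)
  expect_equal(st$pairs$posterior[st$pairs$contig == "c1"], 1.0)
})

test_that("species classification sums posteriors within species", {
  tax <- taxonomy_map(c("rA1", "rA2", "rB1"), c(11L, 12L, 21L),
                      c(1L, 1L, 2L), rep(1000L, 3))
  st <- em_initialize(toy_scores(data.frame(
    contig = "c1", ref = c("rA1", "rA2", "rB1"), score = c(1, 1, 1),
    stringsAsFactors = FALSE)))
  st$pairs$posterior <- c(0.4, 0.3, 0.3)  # species A mass 0.7 vs B 0.3
  expect_equal(unname(classify_contig_species(st, tax)), 1L)

  st$pairs$posterior <- c(0.25, 0.25, 0.5)  # exact 0.5/0.5 tie -> smaller id
  expect_equal(unname(classify_contig_species(st, tax)), 1L)

  tax_bad <- taxonomy_map("rA1", 11L, 1L, 1000L)
  expect_error(classify_contig_species(st, tax_bad), "absent from taxonomy")
})

test_that("reference selection honours the estimate + offset budget", {
  tax <- taxonomy_map(sprintf("r%d", 1:5), 11:15, rep(1L, 5),
                      rep(1000L, 5))
  tab <- toy_scores(data.frame(
    contig = "c1", ref = sprintf("r%d", 1:5), score = c(100, 90, 80, 70, 60),
    stringsAsFactors = FALSE))
  st <- em_initialize(tab)
  sp <- classify_contig_species(st, tax)
  sel <- select_references(st, sp, tax, est = c(c1 = 1L), offset = 2L)
  expect_equal(sort(unique(sel$ref)), c("r1", "r2", "r3"))  # top 1+2

  # budget exceeding supply keeps everything available
  tab2 <- toy_scores(data.frame(contig = "c1", ref = c("r1", "r2"),
                                score = c(100, 90),
                                stringsAsFactors = FALSE))
  st2 <- em_initialize(tab2)
  sel2 <- select_references(st2, classify_contig_species(st2, tax), tax,
                            est = c(c1 = 3L), offset = 2L)
  expect_equal(sort(unique(sel2$ref)), c("r1", "r2"))

  expect_error(select_references(st, sp, tax, offset = -1L),
               "non-negative")
})

test_that("selection drops references outside the assigned species", {
  tax <- taxonomy_map(c("rA1", "rA2", "rB1"), c(11L, 12L, 21L),
                      c(1L, 1L, 2L), rep(1000L, 3))
  tab <- toy_scores(data.frame(
    contig = "c1", ref = c("rA1", "rA2", "rB1"), score = c(100, 95, 60),
    stringsAsFactors = FALSE))
  st <- run_em(tab)
  sp <- classify_contig_species(st, tax)
  sel <- select_references(st, sp, tax, offset = 2L)
  expect_false("rB1" %in% sel$ref)
})

test_that("top-k baselines nest and break ties deterministically", {
  tab <- toy_scores(data.frame(
    contig = c("c1", "c1", "c1", "c2", "c2"),
    ref = c("r3", "r1", "r2", "r4", "r5"),
    score = c(100, 100, 50, 70, 80), stringsAsFactors = FALSE))
  bm1 <- baseline_top_k(tab, 1L)
  bm2 <- baseline_top_k(tab, 3L)
  expect_equal(bm1, c("r1", "r5"))  # score tie 100/100 -> smaller id r1
  expect_true(all(bm1 %in% bm2))
  expect_equal(bm2, sort(unique(tab$ref)))
  expect_error(baseline_top_k(tab, 0L), ">= 1")
})

test_that("database reduction includes unique-contig targets directly", {
  tax <- taxonomy_map(c("r1", "r2", "r3"), 11:13, c(1L, 1L, 2L),
                      rep(1e6, 3))
  span <- 1000L
  paf <- paf_record(c("cU", "cN", "cN"), 2000L, 0L, span, "+",
                    c("r3", "r1", "r2"), 1e6, 0L, span,
                    c(950L, 940L, 900L), span)
  red <- reduce_database(paf, tax)
  expect_true("r3" %in% red$refs)
  expect_equal(red$unique_contigs, "cU")
  expect_equal(red$nonunique_contigs, "cN")
  expect_equal(unname(red$species["cU"]), 2L)
  expect_true(all(c("r1", "r2") %in% red$refs))
})

test_that("reduction with every contig unique skips the EM", {
  tax <- taxonomy_map(c("r1", "r2"), 11:12, c(1L, 2L), rep(1e6, 2))
  paf <- paf_record(c("c1", "c2"), 2000L, 0L, 1000L, "+",
                    c("r1", "r2"), 1e6, 0L, 1000L, 950L, 1000L)
  red <- reduce_database(paf, tax)
  expect_null(red$em)
  expect_equal(red$refs, c("r1", "r2"))
})

test_that("reduction is deterministic across reruns", {
  b <- generate_community(community_spec(seed = 5))
  r1 <- reduce_database(b$contig_paf, b$taxonomy, b$estimates)
  r2 <- reduce_database(b$contig_paf, b$taxonomy, b$estimates)
  expect_identical(r1$refs, r2$refs)
  expect_identical(r1$provenance, r2$provenance)
})
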