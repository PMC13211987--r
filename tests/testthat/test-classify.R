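two_species_tax <- function() {
  taxonomy_map(c("rA1", "rA2", "rB1", "rB2"),
               c(11L, 12L, 21L, 22L), c(1L, 1L, 2L, 2L),
               rep(1000000L, 4))
}

test_that("species assignment picks the species with the best score", {
  tax <- two_species_tax()
  tab <- data.frame(read = c("q1", "q1", "q2", "q2", "q2"),
                    ref = c("rA1", "rB1", "rA1", "rA2", "rB1"),
                    score = c(0.99, 0.95, 0.90, 0.97, 0.80),
                    stringsAsFactors = FALSE)
  sp <- assign_species(tab, tax)
  expect_equal(sp$species_taxid[sp$read == "q1"], 1L)
  expect_equal(sp$species_taxid[sp$read == "q2"], 1L)
  expect_false(any(sp$tie_broken))
})

test_that("cross-species exact ties are drawn reproducibly under a seed", {
  tax <- two_species_tax()
  tab <- data.frame(read = c("q1", "q1"), ref = c("rA1", "rB1"),
                    score = c(0.97, 0.97), stringsAsFactors = FALSE)
  s1 <- assign_species(tab, tax, seed = 7L)
  s2 <- assign_species(tab, tax, seed = 7L)
  expect_identical(s1, s2)
  expect_true(s1$tie_broken)
  expect_true(s1$species_taxid %in% c(1L, 2L))
  # within-species ties are not species ties
  tab2 <- data.frame(read = "q1", ref = c("rA1", "rA2"),
                     score = c(0.97, 0.97), stringsAsFactors = FALSE)
  s3 <- assign_species(tab2, tax)
  expect_false(s3$tie_broken)
  expect_equal(s3$species_taxid, 1L)
})

test_that("species tie draws do not disturb the caller's RNG stream", {
  tax <- two_species_tax()
  tab <- data.frame(read = "q1", ref = c("rA1", "rB1"),
                    score = c(0.9, 0.9), stringsAsFactors = FALSE)
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(assign_species(tab, tax, seed = 1L))
  expect_identical(runif(1), before)
})

test_that("reference stats count unique and tied mappings", {
  tax <- two_species_tax()
  tab <- data.frame(
    read = c("q1", "q2", "q3", "q4", "q4"),
    ref = c("rA1", "rA1", "rA1", "rA1", "rA2"),
    score = c(0.9, 0.9, 0.9, 0.8, 0.8), stringsAsFactors = FALSE)
  sp <- assign_species(tab, tax)
  st <- build_reference_stats(tab, sp, tax)
  expect_equal(st$unique_count[st$ref == "rA1"], 3L)
  expect_equal(st$nonunique_count[st$ref == "rA1"], 1L)
  expect_equal(st$nonunique_count[st$ref == "rA2"], 1L)
  expect_equal(st$total, st$unique_count + st$nonunique_count)
})

test_that("reference stats match a brute-force recount on random input", {
  set.seed(17)
  tax <- two_species_tax()
  tab <- expand.grid(read = sprintf("q%02d", 1:25),
                     ref = c("rA1", "rA2"), stringsAsFactors = FALSE)
  tab$score <- sample(seq(0.8, 1.0, by = 0.05), nrow(tab), replace = TRUE)
  sp <- assign_species(tab, tax)
  st <- build_reference_stats(tab, sp, tax)
  for (r in st$ref) {
    u <- 0L; nn <- 0L
    for (q in unique(tab$read)) {
      sub <- tab[tab$read == q, ]
      best <- max(sub$score)
      winners <- sub$ref[sub$score == best]
      if (r %in% winners) {
        if (length(winners) == 1L) u <- u + 1L else nn <- nn + 1L
      }
    }
    expect_equal(st$unique_count[st$ref == r], u)
    expect_equal(st$nonunique_count[st$ref == r], nn)
  }
})

test_that("reference grouping is the components of the tie graph", {
  tax <- taxonomy_map(sprintf("r%d", 1:4), 11:14, rep(1L, 4),
                      rep(1000000L, 4))
  # r1-r2 tied via q1, r2-r3 tied via q2, r4 isolated
  tab <- data.frame(
    read = c("q1", "q1", "q2", "q2", "q3"),
    ref = c("r1", "r2", "r2", "r3", "r4"),
    score = c(0.9, 0.9, 0.8, 0.8, 0.95), stringsAsFactors = FALSE)
  sp <- assign_species(tab, tax)
  cl <- group_species_references(tab, sp, tax)
  expect_equal(cl$cluster[cl$ref == "r1"], cl$cluster[cl$ref == "r2"])
  expect_equal(cl$cluster[cl$ref == "r2"], cl$cluster[cl$ref == "r3"])
  expect_false(cl$cluster[cl$ref == "r4"] == cl$cluster[cl$ref == "r1"])
  expect_equal(length(unique(cl$cluster)), 2L)
})

test_that("references with no shared reads stay in singleton clusters", {
  tax <- two_species_tax()
  tab <- data.frame(read = c("q1", "q2"), ref = c("rA1", "rA2"),
                    score = c(0.9, 0.9), stringsAsFactors = FALSE)
  sp <- assign_species(tab, tax)
  cl <- group_species_references(tab, sp, tax)
  expect_equal(length(unique(cl$cluster)), 2L)
})

test_that("non-unique reads go to the cluster member with maximal support", {
  tax <- taxonomy_map(c("r1", "r2"), 11:12, c(1L, 1L), rep(1000000L, 2))
  tab <- data.frame(
    read = c(sprintf("u%02d", 1:10), "t1", "t1", "t2", "t2"),
    ref = c(rep("r1", 10), "r1", "r2", "r1", "r2"),
    score = c(rep(0.9, 10), 0.95, 0.95, 0.92, 0.92),
    stringsAsFactors = FALSE)
  sp <- assign_species(tab, tax)
  st <- build_reference_stats(tab, sp, tax)
  cl <- group_species_references(tab, sp, tax)
  out <- reassign_nonunique(cl, st, tab, sp, tax)
  # r1 has M = 12 vs r2's M = 2: both tied reads go to r1
  expect_equal(out$ref[out$read == "t1"], "r1")
  expect_equal(out$ref[out$read == "t2"], "r1")
  expect_equal(out$status[out$read == "t1"], "reassigned")
  expect_equal(sum(out$status == "unique"), 10L)
})

test_that("M ties break by unique count, then by reference id", {
  tax <- taxonomy_map(c("r1", "r2", "r3"), 11:13, rep(1L, 3),
                      rep(1000000L, 3))
  # r1: U=3, N=3 (t1,t2 with r2; t3 with r3) -> M=6
  # r2: U=4, N=2 -> M=6; r3: N=1 -> M=1; all one component
  tab <- data.frame(
    read = c("a1", "a2", "a3", "b1", "b2", "b3", "b4",
             "t1", "t1", "t2", "t2", "t3", "t3"),
    ref = c("r1", "r1", "r1", "r2", "r2", "r2", "r2",
            "r1", "r2", "r1", "r2", "r1", "r3"),
    score = c(rep(0.9, 7), rep(0.95, 6)),
    stringsAsFactors = FALSE)
  sp <- assign_species(tab, tax)
  st <- build_reference_stats(tab, sp, tax)
  expect_equal(st$total[st$ref == "r1"], st$total[st$ref == "r2"])  # 6/6
  cl <- group_species_references(tab, sp, tax)
  expect_equal(length(unique(cl$cluster)), 1L)
  out <- reassign_nonunique(cl, st, tab, sp, tax)
  # M tie 6/6 between r1 and r2; U 4 vs 3 -> r2 wins despite the larger id
  expect_equal(out$ref[out$read == "t1"], "r2")
  expect_equal(out$ref[out$read == "t3"], "r2")
})

test_that("classify_reads conserves reads and is byte-identical on rerun", {
  b <- generate_community(community_spec(seed = 3))
  cls <- classify_reads(b$read_paf, b$taxonomy, seed = 3,
                        read_ids = b$truth$read_id)
  expect_setequal(cls$read_id, b$truth$read_id)
  expect_equal(nrow(cls), nrow(b$truth))
  expect_true(all(cls$status %in%
                    c("unique", "reassigned", "species_tie_random",
                      "unclassified")))
  # every classified read's reference matches its species column
  called <- cls[!is.na(cls$ref_id), ]
  sp_of_ref <- setNames(b$taxonomy$species_taxid, b$taxonomy$seq_id)
  expect_equal(called$species_taxid, unname(sp_of_ref[called$ref_id]))

  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_classification(cls, f1)
  write_classification(classify_reads(b$read_paf, b$taxonomy, seed = 3,
                                      read_ids = b$truth$read_id), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("reads mapped only to unknown references become unclassified", {
  tax <- taxonomy_map("r1", 11L, 1L, 1000000L)
  paf <- paf_record(c("q1", "q2"), 1000L, 0L, 1000L, "+",
                    c("r1", "rX"), 1000000L, 0L, 1000L, 950L, 1000L)
  expect_warning(cls <- classify_reads(paf, tax), "absent from the")
  expect_equal(cls$status[cls$read_id == "q2"], "unclassified")
  expect_equal(cls$ref_id[cls$read_id == "q1"], "r1")
})

test_that("a fully unmapped sample is entirely unclassified", {
  tax <- taxonomy_map("r1", 11L, 1L, 1000000L)
  cls <- classify_reads(empty_paf_for_tests(), tax,
                        read_ids = c("j1", "j2"))
  expect_equal(cls$status, c("unclassified", "unclassified"))
})
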