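# Independent brute-force oracles, coded straight from the model
# definitions with explicit loops; deliberately kept separate from the
# package implementation paths they check.

# Dense-matrix EM over summarized scores: uniform prior 1/G, conditionals
# S / row-max, E-step posterior = cond * prior / row sum, M-step prior =
# column sums of posteriors renormalized to 1, log-likelihood =
# sum_i log sum_j cond[i,j] * prior[j]. Runs exactly n_iter iterations.
oracle_em <- function(scores_df, n_iter) {
  contigs <- sort(unique(scores_df$contig))
  refs <- sort(unique(scores_df$ref))
  x <- length(contigs)
  g <- length(refs)
  s <- matrix(0, x, g, dimnames = list(contigs, refs))
  s[cbind(scores_df$contig, scores_df$ref)] <- scores_df$score
  cond <- matrix(0, x, g, dimnames = list(contigs, refs))
  for (i in seq_len(x)) {
    for (j in seq_len(g)) cond[i, j] <- s[i, j] / max(s[i, ])
  }
  prior <- rep(1 / g, g)
  post <- matrix(0, x, g, dimnames = list(contigs, refs))
  e_step <- function() {
    ll <- 0
    for (i in seq_len(x)) {
      denom <- 0
      for (j in seq_len(g)) denom <- denom + cond[i, j] * prior[j]
      for (j in seq_len(g)) post[i, j] <<- cond[i, j] * prior[j] / denom
      ll <- ll + log(denom)
    }
    ll
  }
  e_step()
  trace <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    for (j in seq_len(g)) prior[j] <- sum(post[, j])
    prior <- prior / sum(prior)
    trace[it] <- e_step()
  }
  list(posterior = post, prior = stats::setNames(prior, refs),
       loglik_trace = trace)
}

# Random small contig-score instance: every contig maps to a non-empty
# random subset of references with uniform scores.
random_score_instance <- function(seed, max_contigs = 6L, max_refs = 5L) {
  set.seed(seed)
  n_c <- sample(2:max_contigs, 1L)
  n_r <- sample(2:max_refs, 1L)
  contigs <- sprintf("c%02d", seq_len(n_c))
  refs <- sprintf("r%02d", seq_len(n_r))
  rows <- do.call(rbind, lapply(contigs, function(ctg) {
    hit <- sort(sample(refs, sample.int(n_r, 1L)))
    data.frame(contig = ctg, ref = hit,
               score = round(stats::runif(length(hit), 10, 1000), 3),
               stringsAsFactors = FALSE)
  }))
  class(rows) <- c("contig_scores", "data.frame")
  rows
}

# Brute-force double loop over records for the summarized score.
oracle_summarize <- function(paf) {
  contigs <- unique(paf$query_name)
  out <- list()
  for (ctg in contigs) {
    for (ref in unique(paf$target_name[paf$query_name == ctg])) {
      tot <- 0
      for (k in seq_len(nrow(paf))) {
        if (paf$query_name[k] == ctg && paf$target_name[k] == ref) {
          n <- paf$residue_matches[k]
          ml <- max(paf$query_end[k] - paf$query_start[k],
                    paf$target_end[k] - paf$target_start[k])
          if (n > 0) tot <- tot + 2 * n * ml / (n + ml)
        }
      }
      if (tot > 0) {
        out[[length(out) + 1L]] <- data.frame(contig = ctg, ref = ref,
                                              score = tot,
                                              stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, out)
  df[order(df$contig, df$ref), ]
}

# Direct Bray-Curtis formula over a shared index.
oracle_bray_curtis <- function(x, y) sum(abs(x - y)) / sum(x + y)

# Connected components of the eps-threshold graph over a distance matrix,
# via igraph (independent of the DBSCAN implementation).
oracle_eps_components <- function(d, eps) {
  n <- nrow(d)
  adj <- (d <= eps) * 1
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  as.integer(igraph::components(g)$membership)
}

# Zero-record PAF for degenerate-input tests.
empty_paf_for_tests <- function() {
  tf <- tempfile(fileext = ".paf")
  file.create(tf)
  on.exit(unlink(tf))
  read_paf(tf)
}

# Random binary support matrix with no all-zero rows.
random_support_matrix <- function(seed, max_refs = 8L, max_reads = 15L) {
  set.seed(seed)
  n_ref <- sample(2:max_refs, 1L)
  n_read <- sample(3:max_reads, 1L)
  m <- matrix(rbinom(n_ref * n_read, 1L, 0.35), n_ref, n_read,
              dimnames = list(sprintf("r%02d", seq_len(n_ref)),
                              sprintf("q%02d", seq_len(n_read))))
  empty <- rowSums(m) == 0L
  m[cbind(which(empty), sample.int(n_read, sum(empty), replace = TRUE))] <- 1L
  m
}
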