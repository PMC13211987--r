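#' Initialize the contig-reassignment EM
#'
#' Sets up the soft clustering of contigs over candidate references from the
#' summarized score table S. Priors start uniform over the g mapped
#' references, P(r) = 1/g. The fixed conditionals are the row-max-normalized
#' scores, P(c | r) = S(c, r) / max_j S(c, r_j), so every contig has at
#' least one conditional equal to 1 and all conditionals lie in (0, 1].
#'
#' @param table A \code{contig_scores} data frame (see
#'   [summarize_contig_scores()]).
#' @return An object of class \code{strainsift_em}: a list with the long-form
#'   pair table (\code{contig}, \code{ref}, \code{score}, \code{cond},
#'   \code{posterior}), the prior vector \code{prior} (named by reference),
#'   the per-iteration log-likelihood \code{loglik_trace}, \code{n_mappings}
#'   (|M|), and \code{iterations}.
#' @export
em_initialize <- function(table) {
  if (nrow(table) == 0L) stop("empty score table")
  zero <- tapply(table$score, table$contig, max) == 0
  if (any(zero)) {
    warning("excluding ", sum(zero), " contig(s) with all-zero scores")
    table <- table[!table$contig %in% names(zero)[zero], , drop = FALSE]
    if (nrow(table) == 0L) stop("no contig with a positive score")
  }
  refs <- sort(unique(table$ref))
  prior <- stats::setNames(rep(1 / length(refs), length(refs)), refs)
  row_max <- tapply(table$score, table$contig, max)
  pairs <- data.frame(contig = table$contig, ref = table$ref,
                      score = table$score,
                      cond = table$score / as.numeric(row_max[table$contig]),
                      posterior = NA_real_, stringsAsFactors = FALSE)
  state <- list(pairs = pairs, prior = prior,
                loglik_trace = numeric(), n_mappings = nrow(pairs),
                iterations = 0L)
  class(state) <- "strainsift_em"
  e_step(state)
}

# E-step: posterior P(r | c) = P(c | r) P(r) / sum_j P(c | r_j) P(r_j),
# and the log-likelihood L(C) = sum_c log sum_j P(c | r_j) P(r_j).
e_step <- function(state) {
  p <- state$pairs
  w <- p$cond * state$prior[p$ref]
  denom <- tapply(w, p$contig, sum)
  state$pairs$posterior <- as.numeric(w / denom[p$contig])
  state$loglik <- sum(log(denom))
  state
}

#' One EM iteration
#'
#' M-step followed by E-step. The M-step prior update sums posteriors per
#' reference; by default the summed vector is renormalized to total 1 (the
#' standard mixture-weight update, which keeps the prior proper and the
#' likelihood non-decreasing). With \code{literal_mstep = TRUE} the sum is
#' divided by the total number of mappings |M| instead, in which case priors
#' total x/|M| and monotonicity is not guaranteed.
#'
#' @param state A \code{strainsift_em} state.
#' @param literal_mstep Divide the prior update by |M| instead of
#'   renormalizing; default FALSE.
#' @return The updated state, with the likelihood appended to the trace.
#' @export
em_step <- function(state, literal_mstep = FALSE) {
  p <- state$pairs
  post_sum <- tapply(p$posterior, p$ref, sum)
  prior <- stats::setNames(rep(0, length(state$prior)), names(state$prior))
  prior[names(post_sum)] <- as.numeric(post_sum)
  if (literal_mstep) {
    prior <- prior / state$n_mappings
  } else {
    prior <- prior / sum(prior)
  }
  state$prior <- prior
  state <- e_step(state)
  state$iterations <- state$iterations + 1L
  state$loglik_trace <- c(state$loglik_trace, state$loglik)
  state
}

#' Run the contig-reassignment EM to convergence
#'
#' Iterates [em_step()] until the absolute change in the log-likelihood
#' falls below \code{tol} or \code{max_iter} iterations are reached.
#'
#' @param table A \code{contig_scores} data frame.
#' @param max_iter Maximum iterations (default 100).
#' @param tol Absolute log-likelihood convergence threshold (default 1e-6).
#' @param literal_mstep See [em_step()].
#' @return The converged \code{strainsift_em} state with the full
#'   log-likelihood trace.
#' @export
run_em <- function(table, max_iter = 100L, tol = 1e-6,
                   literal_mstep = FALSE) {
  state <- em_initialize(table)
  ll_prev <- state$loglik
  for (it in seq_len(max_iter)) {
    state <- em_step(state, literal_mstep = literal_mstep)
    if (abs(state$loglik - ll_prev) < tol) break
    ll_prev <- state$loglik
  }
  state
}

#' Posterior matrix of an EM state
#'
#' @param state A \code{strainsift_em} state.
#' @return A dense contig x reference matrix of posteriors P(r | c); zero
#'   for unmapped pairs. Rows sum to 1.
#' @export
em_posterior_matrix <- function(state) {
  p <- state$pairs
  contigs <- sort(unique(p$contig))
  refs <- names(state$prior)
  m <- matrix(0, length(contigs), length(refs),
              dimnames = list(contigs, refs))
  m[cbind(p$contig, p$ref)] <- p$posterior
  m
}

#' @export
print.strainsift_em <- function(x, ...) {
  cat("Contig-reassignment EM state\n")
  cat("  contigs:    ", length(unique(x$pairs$contig)), "\n")
  cat("  references: ", length(x$prior), "\n")
  cat("  mappings:   ", x$n_mappings, "\n")
  cat("  iterations: ", x$iterations, "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8), "\n")
  invisible(x)
}

#' @export
logLik.strainsift_em <- function(object, ...) {
  structure(object$loglik, df = length(object$prior) - 1L,
            class = "logLik")
}

#' Classify contigs at the species level from EM posteriors
#'
#' Each contig is assigned the species whose references carry the largest
#' summed posterior probability; exact ties go to the smaller species taxid.
#'
#' @param state A converged \code{strainsift_em} state.
#' @param tax A \code{taxonomy_map}.
#' @return Named integer vector: contig id -> species taxid.
#' @export
classify_contig_species <- function(state, tax) {
  p <- state$pairs
  missing <- setdiff(unique(p$ref), tax$seq_id)
  if (length(missing)) {
    stop("reference(s) absent from taxonomy: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  }
  sp <- stats::setNames(tax$species_taxid, tax$seq_id)[p$ref]
  key <- paste(p$contig, sp, sep = "\r")
  mass <- rowsum(p$posterior, key)
  parts <- strsplit(rownames(mass), "\r", fixed = TRUE)
  tab <- data.frame(contig = vapply(parts, `[`, "", 1L),
                    species = as.integer(vapply(parts, `[`, "", 2L)),
                    mass = as.numeric(mass), stringsAsFactors = FALSE)
  # max mass per contig, ties to the smaller species taxid
  tab <- tab[order(tab$contig, -tab$mass, tab$species), ]
  tab <- tab[!duplicated(tab$contig), ]
  stats::setNames(tab$species, tab$contig)
}

#' Select the reduced reference set from EM posteriors
#'
#' For each contig, posteriors are restricted to the contig's assigned
#' species, ranked in decreasing order, and the top (estimate + offset)
#' references are retained, where the estimate is the contig's
#' collapsed-strain count (default 1 when absent from \code{est}) and
#' \code{offset} is a safety margin against dropping a true strain. Rank
#' ties are broken by larger summarized score S, then smaller reference id.
#' The reduced database is the union over contigs.
#'
#' @param state A converged \code{strainsift_em} state.
#' @param species Named vector contig -> species taxid
#'   (from [classify_contig_species()]).
#' @param tax A \code{taxonomy_map} giving each reference's species.
#' @param est Named integer vector of collapsed-strain estimates (may be
#'   empty; missing contigs default to 1).
#' @param offset Extra references added per contig beyond the estimate
#'   (default 2).
#' @return A data frame of class \code{selection_provenance}: one row per
#'   retained (contig, reference) with \code{posterior}, \code{score},
#'   \code{rank}, \code{budget}, \code{species_taxid}. The selected set is
#'   \code{sort(unique(x$ref))}.
#' @export
select_references <- function(state, species, tax, est = integer(),
                              offset = 2L) {
  if (offset < 0) stop("offset must be non-negative")
  p <- state$pairs
  miss <- setdiff(unique(p$contig), names(species))
  if (length(miss)) {
    stop("contig(s) without species assignment: ",
         paste(utils::head(miss, 3L), collapse = ", "))
  }
  sp_of_ref <- stats::setNames(tax$species_taxid, tax$seq_id)
  keep <- sp_of_ref[p$ref] == as.integer(species[p$contig])
  sub <- p[keep, , drop = FALSE]
  # rank within contig: posterior desc, then score desc, then id asc
  sub <- sub[order(sub$contig, -sub$posterior, -sub$score, sub$ref), ]
  rank_in_contig <- stats::ave(seq_len(nrow(sub)), sub$contig,
                               FUN = seq_along)
  n_est <- rep(1L, nrow(sub))
  known <- sub$contig %in% names(est)
  n_est[known] <- as.integer(est[sub$contig[known]])
  budget <- n_est + as.integer(offset)
  sel <- sub[rank_in_contig <= budget, , drop = FALSE]
  prov <- data.frame(contig = sel$contig, ref = sel$ref,
                     posterior = sel$posterior, score = sel$score,
                     rank = rank_in_contig[rank_in_contig <= budget],
                     budget = budget[rank_in_contig <= budget],
                     species_taxid = as.integer(species[sel$contig]),
                     stringsAsFactors = FALSE)
  rownames(prov) <- NULL
  class(prov) <- c("selection_provenance", "data.frame")
  prov
}
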