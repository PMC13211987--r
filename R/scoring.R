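#' Mapping length of an alignment
#'
#' The mapping length ml is the larger of the query span and the target span
#' (end - start, half-open coordinates). Taking the maximum penalizes
#' alignments that cover one sequence well but the other poorly.
#'
#' @param paf A \code{paf} data frame.
#' @return Integer vector of mapping lengths, one per record.
#' @export
mapping_length <- function(paf) {
  pmax(paf$query_end - paf$query_start, paf$target_end - paf$target_start)
}

#' Harmonic-mean mapping score
#'
#' H = 2 N ml / (N + ml), the harmonic mean of the exact match count N and
#' the mapping length ml. The harmonic mean emphasizes the smaller of the
#' two, so a long but low-identity alignment cannot score highly.
#'
#' @param n Non-negative exact match counts.
#' @param ml Positive mapping lengths.
#' @return Numeric scores; 0 where \code{n} is 0.
#' @examples
#' harmonic_score(50, 150)  # 75
#' @export
harmonic_score <- function(n, ml) {
  if (any(ml <= 0)) stop("mapping length must be positive")
  if (any(n < 0)) stop("match count must be non-negative")
  ifelse(n == 0, 0, 2 * n * ml / (n + ml))
}

#' Summarize contig-to-reference mapping scores
#'
#' For every (contig, reference) pair, sums the harmonic-mean score H over
#' all alignments of that contig to that reference, capturing split and
#' secondary alignments alike. Pairs with no alignment are absent.
#'
#' @param paf A \code{paf} data frame of contig-to-database alignments.
#' @return A data frame of class \code{contig_scores} with columns
#'   \code{contig}, \code{ref}, \code{score} (S > 0), one row per mapped pair.
#' @export
summarize_contig_scores <- function(paf) {
  h <- harmonic_score(paf$residue_matches, mapping_length(paf))
  keep <- h > 0
  if (!all(keep)) {
    paf <- paf[keep, , drop = FALSE]
    h <- h[keep]
  }
  if (nrow(paf) == 0L) {
    tab <- data.frame(contig = character(), ref = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  } else {
    key <- paste(paf$query_name, paf$target_name, sep = "\r")
    s <- rowsum(h, key)
    parts <- strsplit(rownames(s), "\r", fixed = TRUE)
    tab <- data.frame(contig = vapply(parts, `[`, "", 1L),
                      ref = vapply(parts, `[`, "", 2L),
                      score = as.numeric(s), stringsAsFactors = FALSE)
    tab <- tab[order(tab$contig, tab$ref), ]
    rownames(tab) <- NULL
  }
  class(tab) <- c("contig_scores", "data.frame")
  tab
}

#' Match-ratio score of read alignments
#'
#' S = N / ml per alignment record, in [0, 1]; 0 only when no residue
#' matches at all (such records never win a best-hit comparison).
#'
#' @param paf A \code{paf} data frame of read alignments.
#' @return Numeric vector of scores, one per record.
#' @export
read_score <- function(paf) {
  paf$residue_matches / mapping_length(paf)
}

#' Per-read match-ratio scores against each reference
#'
#' The read-level score of an alignment is S = N / ml, the ratio of exact
#' matches to mapping length, in (0, 1]. A read may align several times to
#' the same reference; only the highest-scoring alignment per
#' (read, reference) pair is retained (first in file order among equals).
#'
#' @param paf A \code{paf} data frame of read-to-database alignments.
#' @return A data frame of class \code{read_scores} with columns \code{read},
#'   \code{ref}, \code{score}, \code{read_len} (full query length, bp), one
#'   row per mapped (read, reference) pair.
#' @export
read_score_table <- function(paf) {
  if (nrow(paf) == 0L) {
    tab <- data.frame(read = character(), ref = character(),
                      score = numeric(), read_len = integer(),
                      stringsAsFactors = FALSE)
    class(tab) <- c("read_scores", "data.frame")
    return(tab)
  }
  s <- read_score(paf)
  key <- paste(paf$query_name, paf$target_name, sep = "\r")
  # stable max: order by key then descending score, keep first per key
  ord <- order(key, -s)
  first <- !duplicated(key[ord])
  idx <- ord[first]
  tab <- data.frame(read = paf$query_name[idx], ref = paf$target_name[idx],
                    score = s[idx], read_len = paf$query_len[idx],
                    stringsAsFactors = FALSE)
  tab <- tab[tab$score > 0, , drop = FALSE]
  tab <- tab[order(tab$read, tab$ref), ]
  rownames(tab) <- NULL
  class(tab) <- c("read_scores", "data.frame")
  tab
}

#' Split reads (or contigs) into unique and non-unique by best score
#'
#' A query is unique when exactly one reference attains its maximum score
#' (within tolerance \code{tol}); it is non-unique when two or more
#' references tie at the top. Queries with no retained mapping appear in
#' neither set.
#'
#' @param table A \code{read_scores} data frame (columns \code{read},
#'   \code{ref}, \code{score}).
#' @param tol Non-negative score tolerance for calling a tie; default 0
#'   (exact equality of the best score).
#' @return A list with character vectors \code{unique} and \code{nonunique}
#'   of read ids, plus \code{best}, a data frame of the rows attaining each
#'   read's maximum (within tol).
#' @export
partition_reads <- function(table, tol = 0) {
  if (tol < 0) stop("tol must be non-negative")
  if (nrow(table) == 0L) {
    return(list(unique = character(), nonunique = character(),
                best = table))
  }
  best_by_read <- tapply(table$score, table$read, max)
  thr <- best_by_read[table$read] - tol
  is_best <- table$score >= thr
  best <- table[is_best, , drop = FALSE]
  n_best <- table(best$read)
  uniq <- names(n_best)[n_best == 1L]
  nonu <- names(n_best)[n_best >= 2L]
  list(unique = uniq, nonunique = nonu, best = best)
}

#' @export
print.contig_scores <- function(x, ...) {
  cat("Contig-reference summarized scores:", nrow(x), "mapped pairs,",
      length(unique(x$contig)), "contigs,",
      length(unique(x$ref)), "references\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' @export
print.read_scores <- function(x, ...) {
  cat("Read-reference best scores:", nrow(x), "pairs,",
      length(unique(x$read)), "reads,",
      length(unique(x$ref)), "references\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6L))
  invisible(x)
}
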