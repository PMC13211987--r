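#' Read-count abundance profile
#'
#' Counts the reads assigned to each reference; unclassified reads are
#' excluded. Relative counts (fractions of classified reads) are included
#' for downstream dissimilarity calculations.
#'
#' @param assignments A \code{read_assignments} data frame.
#' @return A data frame of class \code{abundance_profile} with columns
#'   \code{ref_id}, \code{read_count}, \code{relative_count}, sorted by
#'   \code{ref_id}.
#' @export
count_abundance <- function(assignments) {
  called <- assignments[!is.na(assignments$ref_id), , drop = FALSE]
  if (nrow(called) == 0L) {
    out <- data.frame(ref_id = character(), read_count = integer(),
                      relative_count = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("abundance_profile", "data.frame")
    return(out)
  }
  counts <- table(called$ref_id)
  out <- data.frame(ref_id = names(counts),
                    read_count = as.integer(counts),
                    relative_count = as.integer(counts) / sum(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(out$ref_id), ]
  rownames(out) <- NULL
  class(out) <- c("abundance_profile", "data.frame")
  out
}

#' Length-normalized abundance profile
#'
#' Abundance(r) = sum of the full lengths of the reads classified under
#' reference r, divided by the length of r. Using both read and reference
#' lengths makes abundances comparable across references of different
#' genome sizes; the result is approximately the mean coverage depth
#' contributed by the assigned reads.
#'
#' @param assignments A \code{read_assignments} data frame.
#' @param read_lengths Named integer vector: read id -> full read length in
#'   bp (PAF column 2). Every classified read must be present.
#' @param tax A \code{taxonomy_map} supplying reference lengths.
#' @return An \code{abundance_profile} data frame with the additional
#'   column \code{length_normalized}.
#' @export
length_normalized <- function(assignments, read_lengths, tax) {
  out <- count_abundance(assignments)
  called <- assignments[!is.na(assignments$ref_id), , drop = FALSE]
  if (nrow(called) == 0L) {
    out$length_normalized <- numeric(0)
    return(out)
  }
  missing <- setdiff(called$read_id, names(read_lengths))
  if (length(missing)) {
    stop("classified read(s) with unknown length: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  }
  len_sum <- rowsum(as.numeric(read_lengths[called$read_id]),
                    called$ref_id)
  ref_len <- stats::setNames(as.numeric(tax$length), tax$seq_id)
  missing_ref <- setdiff(out$ref_id, tax$seq_id)
  if (length(missing_ref)) {
    stop("reference(s) absent from taxonomy: ",
         paste(utils::head(missing_ref, 3L), collapse = ", "))
  }
  out$length_normalized <-
    as.numeric(len_sum[out$ref_id, 1L]) / ref_len[out$ref_id]
  out
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat("Abundance profile:", nrow(x), "references,",
      sum(x$read_count), "classified reads\n")
  if (nrow(x)) {
    print.data.frame(utils::head(
      as.data.frame(x)[order(-x$read_count), ], 8L))
  }
  invisible(x)
}
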