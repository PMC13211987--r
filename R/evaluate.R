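#' Confusion counts against ground truth
#'
#' A read counts as a true positive when it is classified under its
#' expected strain (or, in cluster mode, under any reference in the same
#' cluster as the expected one); as a true negative when it is
#' unclassified and its simulator label is \code{random} or \code{junk};
#' as a false negative when it is unclassified but carries any other
#' label; and as a false positive otherwise (classified under the wrong
#' strain/cluster, including classified random/junk reads). Chimeric reads
#' are scored against their single recorded source.
#'
#' @param assignments A \code{read_assignments} data frame; every read must
#'   be present in \code{truth}.
#' @param truth A \code{truth_table}.
#' @param clusters Optional \code{strain_clusters}; when supplied, scoring
#'   is cluster-level.
#' @param species_level Uplift strain calls to species before scoring
#'   (requires \code{tax}).
#' @param tax A \code{taxonomy_map}; needed for \code{species_level}.
#' @return An object of class \code{confusion_counts}: list with integer
#'   \code{tp}, \code{fp}, \code{tn}, \code{fn} and derived
#'   \code{precision}, \code{recall}, \code{f1}, \code{accuracy}
#'   (0/0 ratios are 0).
#' @export
score_reads <- function(assignments, truth, clusters = NULL,
                        species_level = FALSE, tax = NULL) {
  missing <- setdiff(assignments$read_id, truth$read_id)
  if (length(missing)) {
    stop("assignment read(s) absent from truth: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  }
  idx <- match(assignments$read_id, truth$read_id)
  true_ref <- truth$true_ref_id[idx]
  label <- truth$badread_label[idx]
  called <- !is.na(assignments$ref_id)

  if (species_level) {
    if (is.null(tax)) stop("species_level scoring needs a taxonomy map")
    sp_of_ref <- stats::setNames(tax$species_taxid, tax$seq_id)
    same <- called & !is.na(true_ref) &
      sp_of_ref[assignments$ref_id] == sp_of_ref[true_ref]
  } else if (!is.null(clusters)) {
    cl_of_ref <- stats::setNames(clusters$cluster, clusters$ref)
    ca <- cl_of_ref[assignments$ref_id]
    ct <- cl_of_ref[true_ref]
    same <- called & !is.na(true_ref) &
      ((!is.na(ca) & !is.na(ct) & ca == ct) |
         assignments$ref_id == true_ref)
  } else {
    same <- called & !is.na(true_ref) & assignments$ref_id == true_ref
  }
  same[is.na(same)] <- FALSE
  noise <- label %in% c("random", "junk")
  tp <- sum(called & same)
  fp <- sum(called & !same)
  tn <- sum(!called & noise)
  fn <- sum(!called & !noise)
  confusion_counts(tp, fp, tn, fn)
}

#' Construct confusion counts with derived metrics
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return A \code{confusion_counts} object.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  rat <- function(num, den) if (den == 0) 0 else num / den
  p <- rat(tp, tp + fp)
  r <- rat(tp, tp + fn)
  out <- list(tp = as.integer(tp), fp = as.integer(fp),
              tn = as.integer(tn), fn = as.integer(fn),
              precision = p, recall = r,
              f1 = rat(2 * p * r, p + r),
              accuracy = rat(tp + tn, tp + fp + tn + fn))
  class(out) <- "confusion_counts"
  out
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("precision %.4f  recall %.4f  F1 %.4f  accuracy %.4f\n",
              x$precision, x$recall, x$f1, x$accuracy))
  invisible(x)
}

#' Organism-level detection
#'
#' An organism is considered identified when at least one read is
#' classified under it. False-positive detections are identified organisms
#' absent from the ground-truth community, reported at both strain
#' (reference) and species level.
#'
#' @param assignments A \code{read_assignments} data frame.
#' @param truth A \code{truth_table}.
#' @param tax Optional \code{taxonomy_map} for the species-level roll-up.
#' @return List with \code{detected} (reference ids), \code{expected}
#'   (truth reference ids), \code{fp_strains}, \code{fn_strains}, and —
#'   when \code{tax} is given — \code{fp_species}.
#' @export
organism_detection <- function(assignments, truth, tax = NULL) {
  detected <- sort(unique(assignments$ref_id[!is.na(assignments$ref_id)]))
  expected <- sort(unique(truth$true_ref_id[!is.na(truth$true_ref_id)]))
  out <- list(detected = detected, expected = expected,
              fp_strains = setdiff(detected, expected),
              fn_strains = setdiff(expected, detected))
  if (!is.null(tax)) {
    sp <- stats::setNames(tax$species_taxid, tax$seq_id)
    det_sp <- sort(unique(as.integer(sp[detected])))
    exp_sp <- sort(unique(as.integer(sp[expected])))
    out$fp_species <- setdiff(det_sp, exp_sp)
    out$fn_species <- setdiff(exp_sp, det_sp)
  }
  out
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i) over a shared strain
#' index: 0 for identical composition, 1 for completely disjoint support.
#' Vectors are aligned by name when named; unnamed vectors must have equal
#' length.
#'
#' @param x,y Non-negative abundance vectors (e.g. read counts); not both
#'   all-zero.
#' @return The dissimilarity in [0, 1].
#' @export
bray_curtis <- function(x, y) {
  if (!is.null(names(x)) || !is.null(names(y))) {
    ids <- sort(union(names(x), names(y)))
    xx <- stats::setNames(rep(0, length(ids)), ids)
    yy <- xx
    xx[names(x)] <- x
    yy[names(y)] <- y
    x <- xx
    y <- yy
  } else if (length(x) != length(y)) {
    stop("unnamed abundance vectors must have equal length")
  }
  if (sum(x) + sum(y) == 0) stop("both abundance vectors are all-zero")
  as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
}

#' Percentile-normalized rank-abundance table
#'
#' Strains sorted by decreasing abundance; x is the rank expressed as a
#' percentile of the number of strains, y the relative abundance. The
#' table feeds rank-abundance (Whittaker) plots on a log ordinate.
#'
#' @param profile An \code{abundance_profile} (or any data frame with
#'   \code{ref_id} and \code{read_count}).
#' @return Data frame with columns \code{ref_id}, \code{rank},
#'   \code{rank_percentile} (in (0, 100]), \code{relative_abundance}, rows
#'   in strictly increasing rank order.
#' @export
rank_abundance_curve <- function(profile) {
  if (nrow(profile) == 0L) stop("empty abundance profile")
  tab <- as.data.frame(profile)[order(-profile$read_count,
                                      profile$ref_id), ]
  n <- nrow(tab)
  data.frame(ref_id = tab$ref_id,
             rank = seq_len(n),
             rank_percentile = 100 * seq_len(n) / n,
             relative_abundance = tab$read_count / sum(tab$read_count),
             stringsAsFactors = FALSE, row.names = NULL)
}
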