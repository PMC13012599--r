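#' Adjusted Rand Index
#'
#' Chance-corrected agreement between two partitions of the same cells
#' (Hubert-Arabie form, computed from the contingency table). 1 means the
#' partitions are identical up to relabeling; 0 is the expectation for
#' independent labelings. Doublet and unassigned barcodes should be excluded
#' upstream. When both partitions are degenerate (the chance-agreement
#' denominator is zero, e.g. all cells in one class on both sides), 1 is
#' returned with a warning.
#'
#' @param truth_labels,predicted_labels equal-length label vectors (any
#'   atomic type; compared as factors).
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(truth_labels, predicted_labels) {
  if (length(truth_labels) != length(predicted_labels)) {
    .stopf("label vectors differ in length: %d vs %d",
           length(truth_labels), length(predicted_labels))
  }
  n <- length(truth_labels)
  if (n < 2) .stopf("ARI needs at least 2 cells")
  tab <- table(truth_labels, predicted_labels)
  nij <- sum(choose(as.numeric(tab), 2))
  a <- sum(choose(as.numeric(rowSums(tab)), 2))
  b <- sum(choose(as.numeric(colSums(tab)), 2))
  expected <- a * b / choose(as.numeric(n), 2)
  maxidx <- (a + b) / 2
  if (maxidx == expected) {
    warning("degenerate partitions: chance-agreement denominator is zero; ",
            "returning 1", call. = FALSE)
    return(1)
  }
  (nij - expected) / (maxidx - expected)
}

#' Map each true donor to its modal predicted cluster
#'
#' @param truth_labels,predicted_labels equal-length label vectors.
#' @return data frame with `donor`, `modal_cluster`, `n_cells` (donor size),
#'   `n_modal` (cells in the modal cluster). Ties go to the lowest cluster
#'   (by sorted label order).
#' @export
donor_modal_map <- function(truth_labels, predicted_labels) {
  tab <- table(truth_labels, predicted_labels)
  modal <- apply(tab, 1, which.max)           # first (lowest) on ties
  data.frame(donor = rownames(tab),
             modal_cluster = colnames(tab)[modal],
             n_cells = as.integer(rowSums(tab)),
             n_modal = as.integer(tab[cbind(seq_len(nrow(tab)), modal)]),
             stringsAsFactors = FALSE)
}

#' Count incorrectly merged clusters
#'
#' Maps each true donor to its modal predicted cluster and counts the
#' predicted clusters that are modal for two or more donors — the signature
#' of two donors collapsed into one cluster.
#'
#' @inheritParams adjusted_rand_index
#' @return Nonnegative integer, at most `n_donors - 1`.
#' @export
incorrectly_merged_count <- function(truth_labels, predicted_labels) {
  if (length(truth_labels) != length(predicted_labels)) {
    .stopf("label vectors differ in length: %d vs %d",
           length(truth_labels), length(predicted_labels))
  }
  if (length(truth_labels) < 2) .stopf("need at least 2 cells")
  mm <- donor_modal_map(truth_labels, predicted_labels)
  sum(table(mm$modal_cluster) >= 2)
}

#' Count split donors (secondary diagnostic)
#'
#' Donors whose cells are spread so thin that fewer than `min_concentration`
#' of them sit in the donor's modal cluster — the signature of one donor
#' split across several clusters.
#'
#' @inheritParams adjusted_rand_index
#' @param min_concentration concentration threshold (default 0.6).
#' @export
split_donor_count <- function(truth_labels, predicted_labels,
                              min_concentration = 0.6) {
  mm <- donor_modal_map(truth_labels, predicted_labels)
  sum(mm$n_modal / mm$n_cells < min_concentration)
}

#' Evaluate cell calls against simulation truth
#'
#' Computes the ARI and merged/split-cluster diagnostics on singlet cells,
#' plus doublet precision and recall. By default the ARI is computed on the
#' intersection of true singlets and predicted singlets; set
#' `all_true_singlets = TRUE` to score every true singlet, counting
#' mis-called ones against the clustering.
#'
#' @param calls calls data frame from [call_cells] (or [read_cell_calls]).
#' @param truth truth data frame from [simulate_cells] (or [read_truth]).
#' @param all_true_singlets logical; see above.
#' @return List with `ari`, `incorrectly_merged`, `split_donors`, `n_eval`,
#'   `doublet_precision`, `doublet_recall`, `n_one_to_one` (donors in a
#'   one-to-one donor-cluster modal mapping).
#' @export
evaluate_calls <- function(calls, truth, all_true_singlets = FALSE) {
  if (!setequal(calls$barcode, truth$barcode)) {
    extra <- setdiff(calls$barcode, truth$barcode)
    miss <- setdiff(truth$barcode, calls$barcode)
    .stopf("barcode sets differ (e.g. only in calls: %s; only in truth: %s)",
           paste(utils::head(extra, 3), collapse = ","),
           paste(utils::head(miss, 3), collapse = ","))
  }
  truth <- truth[match(calls$barcode, truth$barcode), ]
  true_singlet <- !truth$is_doublet
  pred_singlet <- calls$status == "singlet"
  keep <- if (all_true_singlets) true_singlet else true_singlet & pred_singlet
  pred_label <- if (!is.null(calls$primary_cluster)) {
    calls$primary_cluster
  } else {
    calls$assignment
  }
  ari <- adjusted_rand_index(truth$donor[keep], pred_label[keep])
  merged <- incorrectly_merged_count(truth$donor[keep], pred_label[keep])
  split <- split_donor_count(truth$donor[keep], pred_label[keep])
  mm <- donor_modal_map(truth$donor[keep], pred_label[keep])
  one2one <- sum(!(mm$modal_cluster %in%
                     mm$modal_cluster[duplicated(mm$modal_cluster)]))
  called_dbl <- calls$status == "doublet"
  true_dbl <- truth$is_doublet
  list(ari = ari, incorrectly_merged = merged, split_donors = split,
       n_eval = sum(keep),
       doublet_precision = if (any(called_dbl))
         sum(called_dbl & true_dbl) / sum(called_dbl) else NA_real_,
       doublet_recall = if (any(true_dbl))
         sum(called_dbl & true_dbl) / sum(true_dbl) else NA_real_,
       n_one_to_one = one2one)
}
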