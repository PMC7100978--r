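#' Mean absolute error of ordered dosage labels
#'
#' Because dosage labels are intrinsically ordered, MAE penalizes a 0-vs-2
#' confusion twice as hard as an adjacent one, giving a stable accuracy
#' measure for this multiclass problem. Ranges over \[0, 2\] and is 0 iff
#' every label is correct.
#'
#' @param true_dosages,predicted_dosages Integer vectors of equal length.
#' @return Mean of `|true - predicted|`.
#' @export
mae <- function(true_dosages, predicted_dosages) {
  if (length(true_dosages) != length(predicted_dosages)) {
    qm_stop("label vectors differ in length", "qmosaic_dimension_error")
  }
  mean(abs(true_dosages - predicted_dosages))
}

#' Benchmark annotation over a clone-size by ambiguity grid
#'
#' For every combination of recombination onset (the clone-size control)
#' and fluorescence ambiguity, grows `n_replicates` independent cultures,
#' samples marker fluorescence, annotates each replicate with a freshly
#' trained model, and scores both the full (context-aware) and the marginal
#' classifier by MAE and accuracy against the ground-truth dosages. Border
#' cells are not excluded, so the scores bound performance from below.
#' Realized mean clone size is recorded per replicate, since clone size is
#' an emergent property of the recombination timing rather than a direct
#' parameter. Replicates whose annotation fails are recorded with `NA`
#' scores rather than aborting the grid.
#'
#' @param clone_size_levels Integer vector of `recombination_start_size`
#'   values (smaller = earlier onset = larger clones).
#' @param sigma_levels Fluorescence ambiguity values.
#' @param n_replicates Replicates per condition.
#' @param seed Master seed; every replicate derives its own.
#' @param final_size Culture size at termination.
#' @param recombination_duration Window length in generations.
#' @param ... Further arguments to [annotate()].
#' @return Data.frame with one row per condition x replicate x classifier:
#'   `rec_start`, `sigma_alpha`, `replicate`, `seed`, `mean_clone_size`,
#'   `classifier`, `mae`, `accuracy`.
#' @export
run_grid <- function(clone_size_levels, sigma_levels, n_replicates,
                     seed = 1, final_size = 2048,
                     recombination_duration = 4, ...) {
  if (length(clone_size_levels) == 0 || length(sigma_levels) == 0) {
    qm_stop("empty condition levels", "qmosaic_parameter_error")
  }
  rows <- list()
  counter <- 0L
  for (cs in clone_size_levels) {
    for (sg in sigma_levels) {
      for (rep_i in seq_len(n_replicates)) {
        counter <- counter + 1L
        rep_seed <- (seed * 10007L + counter * 97L) %% .Machine$integer.max
        culture <- grow_culture(final_size = final_size,
                                recombination_start_size = cs,
                                recombination_duration = recombination_duration,
                                seed = rep_seed)
        tab <- synthesize_measurements(culture, sigma_alpha = sg,
                                       seed = rep_seed + 1L)
        res <- tryCatch(
          annotate(tab, marker_channel = "ch1", seed = rep_seed + 2L,
                   details = TRUE, ...),
          error = function(e) NULL)
        truth <- tab$dosage_true
        mcs <- mean_clone_size(culture)
        score <- function(pred) {
          if (is.null(pred)) return(c(NA_real_, NA_real_))
          c(mae(truth, pred), mean(truth == pred))
        }
        full <- score(if (is.null(res)) NULL else res$table$dosage)
        marg <- score(if (is.null(res)) NULL else res$marginal_dosage)
        rows[[length(rows) + 1L]] <- data.frame(
          rec_start = cs, sigma_alpha = sg, replicate = rep_i,
          seed = rep_seed, mean_clone_size = mcs,
          classifier = c("full", "marginal"),
          mae = c(full[1], marg[1]),
          accuracy = c(full[2], marg[2]))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Log2 fold-change in MAE when spatial context is neglected
#'
#' Aggregates a [run_grid()] result to mean MAE per condition and
#' classifier and reports `log2(marginal / full)` per condition. Positive
#' values mean the context-aware classifier outperforms the marginal one.
#' MAEs are floored at single-cell resolution (`1 / n_cells`) so a perfect
#' replicate does not divide by zero.
#'
#' @param results Data.frame from [run_grid()].
#' @param n_cells Cell count used for the MAE floor.
#' @return Data.frame with `rec_start`, `sigma_alpha`, `mae_full`,
#'   `mae_marginal`, `log2_fold_change`.
#' @export
compare_to_marginal <- function(results, n_cells = 2048) {
  agg <- stats::aggregate(mae ~ rec_start + sigma_alpha + classifier,
                          data = results, FUN = mean, na.rm = TRUE)
  full <- agg[agg$classifier == "full", ]
  marg <- agg[agg$classifier == "marginal", ]
  m <- merge(full[, c("rec_start", "sigma_alpha", "mae")],
             marg[, c("rec_start", "sigma_alpha", "mae")],
             by = c("rec_start", "sigma_alpha"),
             suffixes = c("_full", "_marginal"))
  if (nrow(m) < nrow(full)) {
    qm_stop("unpaired condition in results", "qmosaic_pairing_error")
  }
  floor_val <- 1 / n_cells
  m$log2_fold_change <- log2(pmax(m$mae_marginal, floor_val) /
                               pmax(m$mae_full, floor_val))
  m
}

#' Agreement between two label sets
#'
#' Percent of identically labeled cells plus a column-normalized confusion
#' matrix (columns = first label set, taken as reference; each non-empty
#' column sums to 1). Used e.g. to compare automated with manual
#' annotation.
#'
#' @param labels_a,labels_b Integer label vectors over the same cells.
#' @param exclude Optional logical vector of cells to drop (e.g. clone
#'   borders).
#' @param levels Label universe for the confusion matrix.
#' @return List with `percent_agreement` and `confusion` (rows = labels_b,
#'   columns = labels_a, column-normalized).
#' @export
agreement <- function(labels_a, labels_b, exclude = NULL, levels = 0:2) {
  if (length(labels_a) != length(labels_b)) {
    qm_stop("label vectors differ in length", "qmosaic_alignment_error")
  }
  if (!is.null(exclude)) {
    labels_a <- labels_a[!exclude]
    labels_b <- labels_b[!exclude]
  }
  fa <- factor(labels_a, levels = levels)
  fb <- factor(labels_b, levels = levels)
  tab <- table(b = fb, a = fa)
  colsum <- colSums(tab)
  conf <- sweep(tab, 2, ifelse(colsum == 0, 1, colsum), "/")
  list(percent_agreement = 100 * mean(labels_a == labels_b),
       confusion = conf)
}
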