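# Cross-model compatibility: apply every trained model to every sample's
# surrogate dataset, collect the RMSE matrix, and greedily pick
# representative models that cover as many samples as possible below an
# error threshold.

#' RMSE matrix of models x samples
#'
#' Entry `(i, j)` is [evaluate_rmse()] of model `i` on sample `j`'s full
#' surrogate dataset — the all-against-all screening that asks whether any
#' model copes with data it was not trained on.
#'
#' @param models named list of trained `porosity_model`s (names = source
#'   sample ids).
#' @param sample_datasets named list of `training_dataset`s.
#' @return numeric matrix with model rows and sample columns.
#' @export
rmse_matrix <- function(models, sample_datasets) {
  stopifnot(length(models) > 0L, length(sample_datasets) > 0L)
  m <- matrix(NA_real_, length(models), length(sample_datasets),
              dimnames = list(names(models) %||%
                                paste0("model", seq_along(models)),
                              names(sample_datasets) %||%
                                paste0("sample", seq_along(sample_datasets))))
  for (i in seq_along(models))
    for (j in seq_along(sample_datasets))
      m[i, j] <- evaluate_rmse(models[[i]], sample_datasets[[j]])
  m
}

#' Greedy selection of representative models
#'
#' Model `i` is compatible with sample `j` iff `matrix[i, j] < threshold`
#' (strict). Each round picks the model compatible with the most remaining
#' samples (ties broken by lowest mean RMSE over its covered set, then by
#' model name), records the covered set, removes those samples, and repeats
#' until no remaining sample is covered by any model. Samples never covered
#' are reported explicitly as uncovered.
#'
#' @param matrix an RMSE matrix from [rmse_matrix()] (or any numeric matrix
#'   with model rows and sample columns).
#' @param threshold compatibility cutoff; default 0.04.
#' @param include_self whether a model's own source sample counts toward its
#'   coverage (default TRUE, the natural reading of "number of similar
#'   datasets").
#' @return a `compatibility_report`: list with `rounds` (data.frame: model,
#'   n_covered, covered as comma-joined names), `covered` (named list of
#'   character vectors), `uncovered` (character), `threshold`.
#' @export
select_representatives <- function(matrix, threshold = 0.04,
                                   include_self = TRUE) {
  if (length(matrix) == 0L) stop("empty matrix")
  if (threshold <= 0) stop("threshold must be > 0")
  if (is.null(rownames(matrix)))
    rownames(matrix) <- paste0("model", seq_len(nrow(matrix)))
  if (is.null(colnames(matrix)))
    colnames(matrix) <- paste0("sample", seq_len(ncol(matrix)))
  comp <- matrix < threshold
  if (!include_self && !is.null(rownames(matrix)) &&
      !is.null(colnames(matrix)))
    for (id in intersect(rownames(matrix), colnames(matrix)))
      comp[id, id] <- FALSE
  model_ids <- rownames(comp)
  sample_ids <- colnames(comp)
  remaining <- seq_len(ncol(comp))
  rounds <- data.frame(model = character(0), n_covered = integer(0),
                       covered = character(0), mean_rmse = numeric(0))
  covered_sets <- list()
  repeat {
    counts <- rowSums(comp[, remaining, drop = FALSE])
    if (length(remaining) == 0L || max(counts) == 0L) break
    cand <- which(counts == max(counts))
    if (length(cand) > 1L) {
      mean_err <- vapply(cand, function(i) {
        cov <- remaining[comp[i, remaining]]
        mean(matrix[i, cov])
      }, 0)
      cand <- cand[mean_err == min(mean_err)]
      if (length(cand) > 1L) cand <- cand[order(model_ids[cand])][1]
    }
    pick <- cand[1]
    cov <- remaining[comp[pick, remaining]]
    covered_sets[[model_ids[pick]]] <- sample_ids[cov]
    rounds <- rbind(rounds,
                    data.frame(model = model_ids[pick],
                               n_covered = length(cov),
                               covered = paste(sample_ids[cov],
                                               collapse = ","),
                               mean_rmse = mean(matrix[pick, cov])))
    remaining <- setdiff(remaining, cov)
  }
  structure(list(rounds = rounds, covered = covered_sets,
                 uncovered = sample_ids[remaining], threshold = threshold),
            class = "compatibility_report")
}

#' @export
print.compatibility_report <- function(x, ...) {
  cat(sprintf("compatibility report (RMSE < %g)\n", x$threshold))
  cat("model (sample)        number of similar datasets\n")
  for (i in seq_len(nrow(x$rounds)))
    cat(sprintf("%-22s%d\n", x$rounds$model[i], x$rounds$n_covered[i]))
  if (length(x$uncovered))
    cat("uncovered:", paste(x$uncovered, collapse = ", "), "\n")
  invisible(x)
}

#' Write a compatibility report (and optionally the matrix) as CSV
#' @param report a `compatibility_report`.
#' @param path CSV output path for the per-round summary.
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(report$rounds, path, row.names = FALSE)
  invisible(path)
}
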