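#' Corrected Akaike information criterion
#'
#' `AIC = 2k + n ln(RSS/n) + 2k (k + 1) / (n - k - 1)`, balancing model-data
#' agreement (residual sum of squares over the calibration window) against
#' the number of individually calibrated parameters (each coarse-grid k_pV
#' value counts). The small-sample correction term requires `n > k + 1`.
#'
#' @param RSS residual sum of squares (> 0; an exact zero returns `-Inf`
#'   with a warning).
#' @param k number of calibrated parameters.
#' @param n number of data points used to calibrate.
#' @return scalar AIC.
#' @export
aic <- function(RSS, k, n) {
  if (n <= k + 1)
    validation_error("AIC correction term undefined: need n > k + 1 (n = %d, k = %d)", n, k)
  if (RSS < 0) validation_error("RSS must be nonnegative")
  if (RSS == 0) {
    warning("RSS is exactly zero; AIC is -Inf")
    return(-Inf)
  }
  2 * k + n * log(RSS / n) + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank models within subjects and select by average rank
#'
#' Computes the AIC for every (subject, model) calibration, ranks the models
#' within each subject (rank 1 = lowest AIC; exact ties get the mean of the
#' tied ranks), averages the ranks across subjects, and selects the model
#' with the lowest average rank. Ties on average rank are broken by the
#' number of first-place finishes, then by the lower mean AIC.
#'
#' @param results nested list: `results[[subject]][[model_id]]` is a
#'   [calibrate()] result (or any list with `RSS`, `k`, `n`). Every subject
#'   must have every model; gaps raise a structured error.
#' @return An object of class `selection_table`: a data frame `table` with
#'   one row per subject x model (AIC, RSS, k, n, rank), a data frame
#'   `summary` with per-model average rank and times-ranked-first count, and
#'   `selected`, the winning model id.
#' @export
rank_and_select <- function(results) {
  subjects <- names(results) %||% as.character(seq_along(results))
  models <- unique(unlist(lapply(results, names)))
  gaps <- character(0)
  for (s in seq_along(results))
    for (m in models)
      if (is.null(results[[s]][[m]]))
        gaps <- c(gaps, sprintf("%s x %s", subjects[s], m))
  if (length(gaps))
    validation_error("missing calibrations: %s", paste(gaps, collapse = ", "))

  rows <- list()
  for (s in seq_along(results)) {
    aics <- vapply(models, function(m) {
      r <- results[[s]][[m]]
      aic(r$RSS, r$k, r$n)
    }, numeric(1))
    rk <- rank(aics, ties.method = "average")
    rows[[s]] <- data.frame(
      subject = subjects[s], model = models,
      AIC = aics,
      RSS = vapply(models, function(m) results[[s]][[m]]$RSS, numeric(1)),
      k = vapply(models, function(m) results[[s]][[m]]$k, numeric(1)),
      n = vapply(models, function(m) results[[s]][[m]]$n, numeric(1)),
      rank = rk, row.names = NULL, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(models, function(m) {
    sel <- tab$model == m
    data.frame(model = m,
               avg_rank = mean(tab$rank[sel]),
               times_first = sum(tab$rank[sel] == 1),
               mean_AIC = mean(tab$AIC[sel]),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  ord <- order(summ$avg_rank, -summ$times_first, summ$mean_AIC)
  summ <- summ[ord, , drop = FALSE]
  rownames(summ) <- NULL
  structure(list(table = tab, summary = summ, selected = summ$model[1]),
            class = "selection_table")
}

#' @export
#' @method print selection_table
print.selection_table <- function(x, ...) {
  cat("<selection_table> average rank (times ranked first):\n")
  with(x$summary,
       cat(paste(sprintf("  %-10s %.2f (%d)", model, avg_rank, times_first),
                 collapse = "\n"), "\n"))
  cat(sprintf("selected: %s\n", x$selected))
  invisible(x)
}
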