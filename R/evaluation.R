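# Scoring and report rendering: accuracy, confusion matrices,
# under/correct/over collapses and table-style outputs.

#' Classification accuracy
#'
#' @param pred,truth equal-length label vectors.
#' @return fraction of positions where `pred == truth`.
#' @export
accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("`pred` and `truth` must have equal length")
  }
  if (length(pred) == 0L) stop("empty label vectors")
  mean(as.character(pred) == as.character(truth))
}

#' Confusion matrix
#'
#' @param pred,truth label vectors.
#' @param classes class order; every label must be a member.
#' @return K x K integer matrix of counts, rows = truth, columns =
#'   predictions.
#' @export
confusion <- function(pred, truth, classes) {
  pred <- as.character(pred)
  truth <- as.character(truth)
  bad <- setdiff(unique(c(pred, truth)), classes)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  table(factor(truth, levels = classes),
        factor(pred, levels = classes))
}

#' Collapse an ordered confusion matrix to under/correct/over rows
#'
#' For each true-intensity row of a confusion matrix over the ordered
#' intensity classes, reports the percentage of mass below the diagonal
#' (underestimated), on it (correct) and above it (overestimated). The
#' lowest class has no "under" cell and the highest no "over" cell
#' (structurally absent, `NA`); empty rows are all-`NA`.
#'
#' @param conf confusion matrix over classes ordered from lowest to
#'   highest intensity (rows = truth).
#' @return data.frame with `intensity`, `under`, `correct`, `over`
#'   (percentages) and `n` (row support).
#' @export
collapse_under_over <- function(conf) {
  conf <- as.matrix(conf)
  k <- nrow(conf)
  out <- data.frame(intensity = rownames(conf), under = NA_real_,
                    correct = NA_real_, over = NA_real_,
                    n = rowSums(conf))
  for (i in seq_len(k)) {
    n <- out$n[i]
    if (n == 0) next
    under <- if (i > 1) sum(conf[i, seq_len(i - 1L)]) / n * 100 else NA_real_
    over <- if (i < k) sum(conf[i, seq(i + 1L, k)]) / n * 100 else NA_real_
    out$under[i] <- under
    out$correct[i] <- conf[i, i] / n * 100
    out$over[i] <- over
  }
  rownames(out) <- NULL
  out
}

#' Full evaluation report for one prediction task
#'
#' @param pred,truth label vectors.
#' @param classes class order (for intensity tasks, lowest to highest).
#' @param metadata optional named list stored with the report.
#' @return a `wearsite_report`: `overall_accuracy`, `confusion`,
#'   `per_class` (sensitivity/specificity), `under_correct_over` (ordinal
#'   tasks only) and `metadata`.
#' @export
evaluation_report <- function(pred, truth, classes, metadata = list()) {
  conf <- confusion(pred, truth, classes)
  n <- sum(conf)
  per_class <- data.frame(
    class = classes,
    sensitivity = diag(conf) / pmax(rowSums(conf), 1),
    specificity = vapply(seq_along(classes), function(i) {
      tn <- n - sum(conf[i, ]) - sum(conf[, i]) + conf[i, i]
      fp <- sum(conf[, i]) - conf[i, i]
      if (tn + fp == 0) NA_real_ else tn / (tn + fp)
    }, numeric(1)))
  rownames(per_class) <- NULL
  structure(list(
    overall_accuracy = sum(diag(conf)) / n,
    confusion = conf,
    per_class = per_class,
    under_correct_over = if (identical(classes, .INTENSITIES))
      collapse_under_over(conf) else NULL,
    metadata = metadata), class = "wearsite_report")
}

#' @export
print.wearsite_report <- function(x, ...) {
  cat(sprintf("<wearsite_report> overall accuracy %.1f%% (n = %d)\n",
              100 * x$overall_accuracy, sum(x$confusion)))
  print(x$confusion)
  invisible(x)
}

fmt_pct <- function(x, digits = 0) {
  ifelse(is.na(x), "-", paste0(formatC(x, format = "f", digits = digits),
                               "%"))
}

#' Render a counts-baseline misspecification table
#'
#' Formats the under/correct/over table of one or more
#' [misspecification_report()] results side by side (one column triple per
#' wear-site), percentages rounded to integers, structurally absent cells
#' printed as "-". Raw fractions are written unrounded to the CSV.
#'
#' @param reports named list of misspecification reports (names = applied
#'   wear-site).
#' @param path optional base path (without extension); writes `<path>.csv`
#'   and `<path>.txt`.
#' @return the formatted wide data.frame, invisibly when writing.
#' @export
render_table2 <- function(reports, path = NULL) {
  base <- reports[[1]]$table[, c("group", "intensity")]
  wide <- base
  raw <- base
  for (nm in names(reports)) {
    tb <- reports[[nm]]$table
    stopifnot(identical(tb$group, base$group))
    k <- nrow(tb)
    blank_under <- tb$intensity == "sedentary"
    blank_over <- tb$intensity == "vigorous"
    u <- ifelse(blank_under, NA, tb$under)
    o <- ifelse(blank_over, NA, tb$over)
    wide[[paste0(nm, "_under")]] <- fmt_pct(round(u))
    wide[[paste0(nm, "_correct")]] <- fmt_pct(round(tb$correct))
    wide[[paste0(nm, "_over")]] <- fmt_pct(round(o))
    raw[[paste0(nm, "_under")]] <- u
    raw[[paste0(nm, "_correct")]] <- tb$correct
    raw[[paste0(nm, "_over")]] <- o
  }
  if (!is.null(path)) {
    utils::write.csv(raw, paste0(path, ".csv"), row.names = FALSE,
                     na = "")
    writeLines(c("Counts-baseline intensity classification",
                 "(- under / = correct / + over, percent of epochs)", "",
                 utils::capture.output(print(wide, row.names = FALSE))),
               paste0(path, ".txt"))
    return(invisible(wide))
  }
  wide
}

#' Render a network performance grid
#'
#' Formats a [run_experiment_grid()] result as a purpose x group table with
#' one column per wear-site scope and architecture, accuracies in percent
#' with one decimal.
#'
#' @param grid data.frame from [run_experiment_grid()].
#' @param path optional base path (without extension); writes `<path>.csv`
#'   and `<path>.txt`.
#' @return the formatted wide data.frame, invisibly when writing.
#' @export
render_table3 <- function(grid, path = NULL) {
  grid$cell <- paste(ifelse(grid$site_scope == "two", "two_site",
                            "three_site"), grid$architecture, sep = "_")
  purposes <- unique(grid$purpose)
  groups <- unique(grid$group)
  cells <- unique(grid$cell)
  wide <- expand.grid(purpose = purposes, group = groups,
                      stringsAsFactors = FALSE)
  raw <- wide
  for (cl in cells) {
    v <- vapply(seq_len(nrow(wide)), function(r) {
      w <- grid$purpose == wide$purpose[r] & grid$group == wide$group[r] &
        grid$cell == cl
      if (!any(w)) NA_real_ else 100 * grid$accuracy[w][1]
    }, numeric(1))
    wide[[cl]] <- fmt_pct(v, digits = 1)
    raw[[cl]] <- v
  }
  if (!is.null(path)) {
    utils::write.csv(raw, paste0(path, ".csv"), row.names = FALSE, na = "")
    writeLines(c("Validation accuracy of the sequence classifiers (%)", "",
                 utils::capture.output(print(wide, row.names = FALSE))),
               paste0(path, ".txt"))
    return(invisible(wide))
  }
  wide
}

#' Render both report styles to a directory
#'
#' @param baseline_reports named list for [render_table2()] (or `NULL`).
#' @param network_grid data.frame for [render_table3()] (or `NULL`).
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
render_reports <- function(baseline_reports = NULL, network_grid = NULL,
                           dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (!is.null(baseline_reports)) {
    render_table2(baseline_reports, file.path(dir, "counts_baseline"))
    paths <- c(paths, file.path(dir, c("counts_baseline.csv",
                                       "counts_baseline.txt")))
  }
  if (!is.null(network_grid)) {
    render_table3(network_grid, file.path(dir, "network_grid"))
    paths <- c(paths, file.path(dir, c("network_grid.csv",
                                       "network_grid.txt")))
  }
  invisible(paths)
}
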