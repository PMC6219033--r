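#' Long-format panel container for semicontinuous outcomes
#'
#' Builds the internal data structure used by all model fits: one row per
#' subject-visit with a non-negative outcome, a design matrix `Z` for the
#' zero (logistic) part, `X` for the continuous part and `W` for the
#' one-part model.  An intercept column is prepended to every role.  Rows
#' with missing values in any used column are dropped (with a message);
#' subjects are ordered by first appearance and each subject's records are
#' kept contiguous.
#'
#' @param data a data frame in long format, one row per subject-visit.
#' @param subject name of the subject-identifier column.
#' @param time name of the visit-time column.
#' @param outcome name of the non-negative outcome column.
#' @param z,x,w character vectors of covariate column names for the zero
#'   part, the continuous part and the one-part model (`w` defaults to `x`).
#'   The intercept is implicit and always added.
#' @param zero_threshold outcome values `<=` this value are treated as
#'   zeros (default 0, an exact point mass).
#'
#' @return An object of class `panel_data`: a list with the outcome vector
#'   `y`, design matrices `Z`, `X`, `W`, `subject` and `time` vectors, the
#'   zero threshold, and the per-subject record index.
#' @export
panel_data <- function(data, subject, time, outcome,
                       z = character(), x = character(), w = x,
                       zero_threshold = 0) {
  stopifnot(is.data.frame(data))
  used <- unique(c(subject, time, outcome, z, x, w))
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols))
    stop("column(s) not found in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  keep <- stats::complete.cases(data[used])
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("dropping ", n_dropped, " row(s) with missing values in used columns")
    data <- data[keep, , drop = FALSE]
  }
  if (nrow(data) == 0L) stop("no complete rows in 'data'", call. = FALSE)

  y <- as.numeric(data[[outcome]])
  if (any(!is.finite(y)) || any(y < 0)) {
    bad <- which(!is.finite(y) | y < 0)[1]
    stop("outcome must be finite and >= 0 (first offending row: ", bad, ")",
         call. = FALSE)
  }

  # subjects in order of first appearance, records contiguous per subject
  sid <- as.character(data[[subject]])
  levels <- unique(sid)
  ord <- order(match(sid, levels))
  data <- data[ord, , drop = FALSE]
  y <- y[ord]
  sid <- sid[ord]

  design <- function(cols) {
    m <- cbind(`(Intercept)` = 1, as.matrix(data[cols]))
    storage.mode(m) <- "double"
    if (any(!is.finite(m))) stop("non-finite covariate value", call. = FALSE)
    m
  }

  idx <- split(seq_along(sid), factor(sid, levels = levels))
  structure(list(
    y = y,
    Z = design(z), X = design(x), W = design(w),
    subject = sid, time = as.numeric(data[[time]]),
    zero_threshold = zero_threshold,
    subject_levels = levels,
    subject_index = idx,
    n_dropped = n_dropped
  ), class = "panel_data")
}

#' @export
print.panel_data <- function(x, ...) {
  nz <- mean(x$y > x$zero_threshold)
  cat("Longitudinal semicontinuous panel\n")
  cat(sprintf("  %d subjects, %d records (%.1f per subject)\n",
              length(x$subject_levels), length(x$y),
              length(x$y) / length(x$subject_levels)))
  cat(sprintf("  non-zero fraction: %.3f (zero threshold %g)\n",
              nz, x$zero_threshold))
  cat(sprintf("  zero-part covariates: %s\n", paste(colnames(x$Z), collapse = ", ")))
  cat(sprintf("  continuous-part covariates: %s\n", paste(colnames(x$X), collapse = ", ")))
  invisible(x)
}

n_subjects <- function(panel) length(panel$subject_levels)

# records of one subject as plain matrices/vectors
subject_records <- function(panel, i) {
  idx <- panel$subject_index[[i]]
  list(y = panel$y[idx],
       Z = panel$Z[idx, , drop = FALSE],
       X = panel$X[idx, , drop = FALSE],
       W = panel$W[idx, , drop = FALSE])
}

#' Column mapping for delimited panel files
#'
#' Describes how the columns of a delimited text file map onto the roles of
#' a [panel_data] object.
#'
#' @inheritParams panel_data
#' @return An object of class `column_mapping`.
#' @export
column_mapping <- function(subject, time, outcome,
                           z = character(), x = character(), w = x,
                           zero_threshold = 0) {
  structure(list(subject = subject, time = time, outcome = outcome,
                 z = z, x = x, w = w, zero_threshold = zero_threshold),
            class = "column_mapping")
}

#' Read a long-format panel from a delimited text file
#'
#' Reads a comma-separated file (header row required, decimal point) and
#' assembles a [panel_data] object according to a [column_mapping].
#'
#' @param path path to a CSV file.
#' @param mapping a [column_mapping].
#' @return A [panel_data] object.
#' @export
read_panel_table <- function(path, mapping) {
  stopifnot(inherits(mapping, "column_mapping"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  panel_data(df, subject = mapping$subject, time = mapping$time,
             outcome = mapping$outcome, z = mapping$z, x = mapping$x,
             w = mapping$w, zero_threshold = mapping$zero_threshold)
}
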