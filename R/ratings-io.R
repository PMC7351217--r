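# Long-format ratings tables: subject x rater/trial grids per parameter.

#' Construct a complete ratings table
#'
#' Holds one parameter's measurements as a complete subjects x raters grid,
#' the shape every two-way ANOVA-based statistic here consumes.
#'
#' @param values Numeric `n x k` matrix, `n >= 2` subjects, `k >= 2`
#'   raters/trials, no missing cells.
#' @param subject_ids,rater_ids Optional identifier vectors.
#' @param parameter Optional parameter name the values belong to.
#' @return An object of class `ratings_table`.
#' @export
ratings_table <- function(values, subject_ids = NULL, rater_ids = NULL,
                          parameter = "") {
  v <- as.matrix(values)
  storage.mode(v) <- "double"
  if (nrow(v) < 2L || ncol(v) < 2L)
    stop_validation("a ratings table needs >= 2 subjects and >= 2 raters")
  if (anyNA(v) || any(!is.finite(v)))
    stop_validation("ratings table has missing or non-finite cells")
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(nrow(v)))
  if (is.null(rater_ids)) rater_ids <- paste0("R", seq_len(ncol(v)))
  stopifnot(length(subject_ids) == nrow(v), length(rater_ids) == ncol(v))
  dimnames(v) <- list(as.character(subject_ids), as.character(rater_ids))
  structure(list(values = unname(v),
                 subject_ids = as.character(subject_ids),
                 rater_ids = as.character(rater_ids),
                 parameter = as.character(parameter)[1]),
            class = "ratings_table")
}

#' @export
print.ratings_table <- function(x, ...) {
  cat(sprintf("<ratings_table> %s%d subjects x %d raters\n",
              if (nzchar(x$parameter)) paste0(x$parameter, ": ") else "",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read a long-format ratings CSV
#'
#' Expects columns `subject`, `rater_or_trial`, `parameter`, `value`
#' (header required, UTF-8).  One complete two-way table is pivoted per
#' parameter; a parameter with missing (subject, rater) cells is returned
#' as an incomplete placeholder that downstream statistics refuse, listing
#' the missing cells.
#'
#' @param path CSV file.
#' @return A named list (class `ratings_set`), one entry per parameter:
#'   either a [ratings_table()] or, when cells are missing, a list of class
#'   `incomplete_ratings` with a `missing` data frame.
#' @export
read_ratings_table <- function(path) {
  if (!file.exists(path)) stop_io("ratings file not found: %s", path)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character"),
                 error = function(e) stop_io("cannot read CSV %s: %s",
                                             path, conditionMessage(e)))
  need <- c("subject", "rater_or_trial", "parameter", "value")
  if (!all(need %in% names(df)))
    stop_validation("ratings CSV must have columns %s (got: %s)",
                    paste(need, collapse = ", "),
                    paste(names(df), collapse = ", "))
  vals <- suppressWarnings(as.numeric(df$value))
  if (anyNA(vals))
    stop_validation("non-numeric value(s) in ratings CSV at row(s) %s",
                    paste(head(which(is.na(vals)), 5), collapse = ", "))
  df$value <- vals
  key <- paste(df$subject, df$rater_or_trial, df$parameter, sep = "\r")
  if (anyDuplicated(key))
    stop_validation("duplicate (subject, rater, parameter) rows in %s", path)
  out <- list()
  for (p in unique(df$parameter)) {
    sub <- df[df$parameter == p, ]
    subjects <- sort(unique(sub$subject))
    raters <- sort(unique(sub$rater_or_trial))
    m <- matrix(NA_real_, length(subjects), length(raters),
                dimnames = list(subjects, raters))
    m[cbind(match(sub$subject, subjects),
            match(sub$rater_or_trial, raters))] <- sub$value
    if (anyNA(m)) {
      idx <- which(is.na(m), arr.ind = TRUE)
      out[[p]] <- structure(
        list(parameter = p,
             missing = data.frame(subject = subjects[idx[, 1]],
                                  rater_or_trial = raters[idx[, 2]],
                                  stringsAsFactors = FALSE)),
        class = "incomplete_ratings")
    } else {
      out[[p]] <- ratings_table(m, subjects, raters, parameter = p)
    }
  }
  structure(out, class = "ratings_set")
}

#' Write ratings tables to a long-format CSV
#'
#' Inverse of [read_ratings_table()].
#'
#' @param tables A [ratings_table()], or a (possibly named) list of them.
#' @param path Destination CSV.
#' @export
write_ratings_table <- function(tables, path) {
  if (inherits(tables, "ratings_table")) tables <- list(tables)
  rows <- lapply(tables, function(tb) {
    stopifnot(inherits(tb, "ratings_table"))
    expand <- expand.grid(si = seq_along(tb$subject_ids),
                          ri = seq_along(tb$rater_ids))
    data.frame(subject = tb$subject_ids[expand$si],
               rater_or_trial = tb$rater_ids[expand$ri],
               parameter = tb$parameter,
               value = tb$values[cbind(expand$si, expand$ri)],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
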