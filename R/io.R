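# Delimited-text readers for the two input tables and JSON writers for fit
# and cross-validation results. No imputation anywhere: the model assumes
# complete data, so a missing cell is an error that names its location.

infer_sep <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a baseline feature table
#'
#' Expects delimited text with a header row; the first column is
#' `subject_id`, every remaining column one numeric feature. Column order is
#' preserved. Duplicate subject ids, missing cells and non-numeric cells are
#' errors reporting the offending row/column.
#'
#' @param path CSV (or TSV, by extension) file path.
#' @param sep field separator; inferred from the extension by default.
#' @return numeric S x F matrix with subject ids as rownames and feature
#'   names as colnames.
#' @export
read_feature_table <- function(path, sep = infer_sep(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.table(path, header = TRUE, sep = sep, colClasses = "character",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = NULL, quote = "\"")
  if (ncol(raw) < 2) stop("expected subject_id plus at least one feature column")
  ids <- trimws(raw[[1]])
  if (anyDuplicated(ids))
    stop("duplicate subject_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- matrix(NA_real_, nrow(raw), ncol(raw) - 1,
                dimnames = list(ids, colnames(raw)[-1]))
  for (j in seq_len(ncol(raw) - 1)) {
    v <- trimws(raw[[j + 1]])
    bad <- which(v == "" | toupper(v) == "NA")
    if (length(bad))
      stop("missing value at row ", bad[1], ", column '",
           colnames(raw)[j + 1], "'")
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num))
    if (length(bad))
      stop("non-numeric value '", v[bad[1]], "' at row ", bad[1],
           ", column '", colnames(raw)[j + 1], "'")
    out[, j] <- num
  }
  out
}

#' Read a long-format clinical score table
#'
#' Expects columns `subject_id`, `time_label`, `score_name`, `value`; every
#' (subject, time, score) combination must appear exactly once. Row order is
#' irrelevant. Time points are ordered by `time_levels` when given, else by
#' first appearance in the file; likewise for scores.
#'
#' @param path CSV/TSV file path.
#' @param subject_ids subject ordering to align with (e.g. rownames of the
#'   feature matrix); defaults to first appearance. Unknown subjects in the
#'   file are an error when this is supplied.
#' @param time_levels,score_levels optional orderings of the time and score
#'   labels.
#' @param sep field separator; inferred from the extension by default.
#' @return T x S x C numeric array with dimnames (time, subject, score).
#' @export
read_scores <- function(path, subject_ids = NULL, time_levels = NULL,
                        score_levels = NULL, sep = infer_sep(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.table(path, header = TRUE, sep = sep, colClasses = "character",
                  check.names = FALSE, stringsAsFactors = FALSE,
                  na.strings = NULL, quote = "\"")
  need <- c("subject_id", "time_label", "score_name", "value")
  if (!all(need %in% colnames(d)))
    stop("score table must have columns: ", paste(need, collapse = ", "))
  for (cn in need) d[[cn]] <- trimws(d[[cn]])
  if (is.null(subject_ids)) subject_ids <- unique(d$subject_id)
  unknown <- setdiff(unique(d$subject_id), subject_ids)
  if (length(unknown))
    stop("unknown subject(s) in score table: ",
         paste(head(unknown, 5), collapse = ", "))
  time_levels <- time_levels %||% unique(d$time_label)
  score_levels <- score_levels %||% unique(d$score_name)
  bad_t <- setdiff(unique(d$time_label), time_levels)
  if (length(bad_t)) stop("unknown time label(s): ", paste(bad_t, collapse = ", "))
  bad_c <- setdiff(unique(d$score_name), score_levels)
  if (length(bad_c)) stop("unknown score name(s): ", paste(bad_c, collapse = ", "))

  val <- suppressWarnings(as.numeric(d$value))
  bad <- which(is.na(val) | d$value == "")
  if (length(bad))
    stop("missing or non-numeric value at data row ", bad[1],
         " (subject ", d$subject_id[bad[1]], ", time ", d$time_label[bad[1]],
         ", score ", d$score_name[bad[1]], ")")

  ti <- match(d$time_label, time_levels)
  si <- match(d$subject_id, subject_ids)
  ci <- match(d$score_name, score_levels)
  key <- paste(ti, si, ci)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate entry for (", d$subject_id[dup[1]], ", ",
         d$time_label[dup[1]], ", ", d$score_name[dup[1]], ")")
  arr <- array(NA_real_, c(length(time_levels), length(subject_ids),
                           length(score_levels)),
               dimnames = list(time_levels, subject_ids, score_levels))
  arr[cbind(ti, si, ci)] <- val
  if (anyNA(arr)) {
    miss <- which(is.na(arr), arr.ind = TRUE)
    msgs <- apply(head(miss, 5), 1, function(i)
      paste0("(", subject_ids[i[2]], ", ", time_levels[i[1]], ", ",
             score_levels[i[3]], ")"))
    stop("missing (subject, time, score) combination(s): ",
         paste(msgs, collapse = ", "),
         if (nrow(miss) > 5) sprintf(" and %d more", nrow(miss) - 5) else "")
  }
  arr
}

#' Serialize a fit's weights and diagnostics as JSON
#'
#' @param fit an `smtl_fit`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_weights <- function(fit, path) {
  stopifnot(inherits(fit, "smtl_fit"))
  payload <- list(
    schema = "smtl_weights/1",
    dims = fit$dims,
    lambda1 = fit$lambda1, lambda2 = fit$lambda2,
    feature_names = fit$feature_names,
    weights = lapply(fit$weights$per_time, unname),
    row_norms = as.numeric(fit$row_norms),
    objective_trace = fit$objective_trace,
    n_iter = fit$n_iter, converged = fit$converged)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize a cross-validation report as JSON
#'
#' The payload contains no timestamps or environment-dependent fields, so a
#' rerun with the same data and seed is byte-identical.
#'
#' @param report an `smtl_cv_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "smtl_cv_report"))
  payload <- unclass(report)
  payload$per_fold <- lapply(payload$per_fold, function(pf) {
    pf$center <- as.numeric(pf$center)
    pf$scale <- as.numeric(pf$scale)
    pf
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Reload a serialized cross-validation report
#'
#' @param path JSON path written by [write_report()].
#' @return list mirroring the report (data.frames restored).
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, "smtl_cv_report/1"))
    stop("not an smtl_cv_report JSON file")
  for (nm in c("per_cell", "predictions", "summary"))
    payload[[nm]] <- as.data.frame(payload[[nm]], stringsAsFactors = FALSE)
  # jsonlite simplifies the per-fold records into a nested data.frame;
  # restore the list-of-lists shape the in-memory report uses
  pf <- payload$per_fold
  if (is.data.frame(pf)) {
    payload$per_fold <- lapply(seq_len(nrow(pf)), function(i) {
      lapply(pf, function(col) {
        if (is.data.frame(col))
          lapply(col, function(sub) if (is.list(sub)) sub[[i]] else sub[i])
        else if (is.list(col)) col[[i]] else col[i]
      })
    })
  }
  payload
}
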