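#' Validate a per-participant count table
#'
#' The canonical input is one row per participant with columns
#' \code{participant_id}, \code{hits}, \code{false_alarms},
#' \code{signal_trials}, \code{noise_trials}.  Counts must be non-negative
#' integers bounded by their trial totals; trial totals must be at least 1.
#'
#' @param counts data.frame to validate.
#' @param allow_zero_trials permit 0 signal/noise trials (used internally for
#'   prior-recovery runs where the data carry no information).
#' @return the validated data.frame (row names dropped, columns ordered).
#' @export
validateCounts <- function(counts, allow_zero_trials = FALSE) {
  required <- c("participant_id", "hits", "false_alarms",
                "signal_trials", "noise_trials")
  if (!is.data.frame(counts))
    stop("'counts' must be a data.frame")
  missing_cols <- setdiff(required, names(counts))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  counts <- counts[required]
  num <- required[-1]
  bad <- !vapply(counts[num], function(x) is.numeric(x) && all(is.finite(x)) &&
                   all(x == round(x)), logical(1))
  if (any(bad))
    stop("non-integer values in: ", paste(num[bad], collapse = ", "))
  min_trials <- if (allow_zero_trials) 0L else 1L
  problems <- with(counts,
    hits < 0 | false_alarms < 0 |
    signal_trials < min_trials | noise_trials < min_trials |
    hits > signal_trials | false_alarms > noise_trials)
  if (any(problems))
    stop("invalid rows (counts out of bounds): ",
         paste(utils::head(which(problems), 5), collapse = ", "),
         if (sum(problems) > 5) " ..." else "")
  if (anyDuplicated(counts$participant_id))
    stop("duplicated participant_id values")
  rownames(counts) <- NULL
  counts
}

#' Read a count table from a delimited file
#'
#' Accepts comma- or tab-separated UTF-8 text with the header
#' \code{participant_id,hits,false_alarms,signal_trials,noise_trials}.
#' Malformed rows are reported with their line numbers before aborting.
#'
#' @param path file path.
#' @param sep field separator; \code{NULL} (default) sniffs comma vs tab from
#'   the header line.
#' @return validated counts data.frame.
#' @export
readCounts <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  counts <- utils::read.table(path, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE, encoding = "UTF-8")
  tryCatch(validateCounts(counts),
           error = function(e) stop("in ", path, ": ", conditionMessage(e),
                                    call. = FALSE))
}

#' Write a count table
#'
#' @param counts validated counts data.frame.
#' @param path output file path.
#' @param sep field separator (default comma).
#' @export
writeCounts <- function(counts, path, sep = ",") {
  counts <- validateCounts(counts, allow_zero_trials = TRUE)
  utils::write.table(counts, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Dichotomise confidence ratings into yes/no counts
#'
#' Confidence-rating studies score each trial on a Likert scale (for a
#' 1--6 recognition scale: 1 = "sure old" ... 6 = "sure new", with "old"
#' the signal response).  Ratings at or below \code{threshold} are counted
#' as a Yes; the default threshold of 3 is the scale midpoint for a 6-point
#' scale.  Input is long format with one row per trial.
#'
#' @param ratings data.frame with columns \code{participant_id},
#'   \code{trial_type} ("signal"/"noise"), \code{rating} (integer codes).
#' @param threshold ratings \code{<= threshold} become Yes responses.
#' @return counts data.frame suitable for [fitSDT()].
#' @export
dichotomizeRatings <- function(ratings, threshold = 3) {
  required <- c("participant_id", "trial_type", "rating")
  missing_cols <- setdiff(required, names(ratings))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (!all(ratings$trial_type %in% c("signal", "noise")))
    stop("trial_type must be 'signal' or 'noise'")
  yes <- ratings$rating <= threshold
  ids <- unique(ratings$participant_id)
  tab <- function(type, fun) {
    sel <- ratings$trial_type == type
    vapply(ids, function(id) {
      rows <- sel & ratings$participant_id == id
      fun(rows)
    }, numeric(1))
  }
  counts <- data.frame(
    participant_id = ids,
    hits           = tab("signal", function(r) sum(yes[r])),
    false_alarms   = tab("noise",  function(r) sum(yes[r])),
    signal_trials  = tab("signal", sum),
    noise_trials   = tab("noise",  sum))
  validateCounts(counts)
}
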