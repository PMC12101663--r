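#' Construct a longitudinal series for one subject
#'
#' A `longitudinal_series` holds one subject's ordered biomarker
#' measurements \eqn{Y_{i1}, \dots, Y_{in_i}}. Occasions are 1-based and
#' re-pack: a missing visit is simply an absent value, not an `NA` slot.
#'
#' @param subject_id Opaque subject identifier (coerced to character).
#' @param values Numeric vector of finite measurements, in occasion order.
#' @param labels Optional per-value truth mark, each one of `"normal"`,
#'   `"abnormal"` or `"unlabelled"`. Recycled `NULL` means unlabelled.
#' @param context Optional per-value free-string tag (e.g. `"pre"`/`"post"`).
#'
#' @return An object of class `longitudinal_series`.
#' @export
#' @examples
#' longitudinal_series("A", c(4, 6, 8))
longitudinal_series <- function(subject_id, values, labels = NULL,
                                context = NULL) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("'values' must be non-empty")
  if (!all(is.finite(values))) stop("'values' must be finite reals")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != length(values))
      stop("'labels' must align 1:1 with 'values'")
    bad <- setdiff(unique(labels), c("normal", "abnormal", "unlabelled"))
    if (length(bad))
      stop("invalid label(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(context)) {
    context <- as.character(context)
    if (length(context) != length(values))
      stop("'context' must align 1:1 with 'values'")
  }
  structure(
    list(subject_id = as.character(subject_id)[1L], values = values,
         labels = labels, context = context),
    class = "longitudinal_series"
  )
}

#' @export
print.longitudinal_series <- function(x, ...) {
  cat("<longitudinal_series> subject", x$subject_id, "-",
      length(x$values), "occasions\n")
  cat("  values:", paste(utils::head(signif(x$values, 4), 8), collapse = " "),
      if (length(x$values) > 8) "...\n" else "\n")
  if (!is.null(x$labels))
    cat("  abnormal occasions:",
        paste(which(x$labels == "abnormal"), collapse = " "), "\n")
  invisible(x)
}

#' @export
length.longitudinal_series <- function(x) length(x$values)

#' Bundle several longitudinal series into a collection
#'
#' @param series A list of [longitudinal_series()] objects with distinct
#'   subject identifiers.
#' @param transform Scale the values live on: `"identity"` (raw) or `"log"`
#'   (natural-log transformed at read time; see [read_long_table()]).
#'
#' @return A named list of class `series_collection` (names are subject ids).
#' @export
series_collection <- function(series, transform = c("identity", "log")) {
  transform <- match.arg(transform)
  if (!length(series)) stop("empty collection")
  ok <- vapply(series, inherits, logical(1), "longitudinal_series")
  if (!all(ok)) stop("all elements must be longitudinal_series")
  ids <- vapply(series, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate subject ids in collection")
  names(series) <- ids
  structure(series, class = "series_collection", transform = transform)
}

#' @export
print.series_collection <- function(x, ...) {
  n <- vapply(x, function(s) length(s$values), integer(1))
  cat("<series_collection>", length(x), "subjects,",
      sum(n), "measurements (n_i:", min(n), "-", max(n), ")\n")
  if (identical(attr(x, "transform"), "log"))
    cat("  values are log-transformed\n")
  invisible(x)
}

#' @export
`[.series_collection` <- function(x, i) {
  out <- NextMethod()
  structure(out, class = "series_collection",
            transform = attr(x, "transform"))
}

#' Read long-format repeated measurements from delimited text
#'
#' Expects a header and one row per (subject, occasion) pair. Occasions are
#' sorted per subject and re-packed to 1-based indices; duplicate
#' (subject, occasion) pairs and unparseable values are errors, not silently
#' dropped.
#'
#' @param source Path to a delimited text file (field separator sniffed from
#'   the header among comma/tab/semicolon) or a `data.frame`.
#' @param columns Named character vector remapping the required columns
#'   `subject`, `occasion`, `value` and the optional `label`, `context` to
#'   the names actually present in `source`.
#' @param transform `"identity"` or `"log"`. With `"log"`, values must be
#'   strictly positive and are natural-log transformed; downstream reports
#'   can back-transform ranges to the original scale (right-skewed
#'   biomarkers are usually closer to normal after a log).
#'
#' @return A [series_collection()].
#' @export
read_long_table <- function(source,
                            columns = c(subject = "subject",
                                        occasion = "occasion",
                                        value = "value",
                                        label = "label",
                                        context = "context"),
                            transform = c("identity", "log")) {
  transform <- match.arg(transform)
  defaults <- c(subject = "subject", occasion = "occasion", value = "value",
                label = "label", context = "context")
  defaults[names(columns)] <- columns
  columns <- defaults

  if (is.character(source)) {
    header <- readLines(source, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else if (grepl(";", header)) ";" else ","
    df <- utils::read.csv(source, sep = sep, colClasses = "character",
                          check.names = FALSE)
  } else if (is.data.frame(source)) {
    df <- source
  } else stop("'source' must be a file path or a data.frame")

  for (req in c("subject", "occasion", "value")) {
    if (!columns[[req]] %in% names(df))
      stop("required column '", columns[[req]], "' (", req,
           ") not found in input")
  }

  subject <- as.character(df[[columns[["subject"]]]])
  occ_raw <- df[[columns[["occasion"]]]]
  occasion <- suppressWarnings(as.integer(occ_raw))
  if (anyNA(occasion)) {
    # fall back to sortable timestamps / ordered factors
    ord <- order(subject, occ_raw)
    occasion <- stats::ave(seq_along(subject)[ord], subject[ord],
                           FUN = seq_along)[order(ord)]
  }
  val_raw <- df[[columns[["value"]]]]
  value <- suppressWarnings(as.numeric(as.character(val_raw)))
  bad <- which(!is.finite(value))
  if (length(bad))
    stop("non-numeric or missing value in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (anyDuplicated(cbind(subject, occasion)))
    stop("duplicate (subject, occasion) pair(s) in input")
  if (transform == "log") {
    if (any(value <= 0))
      stop("log transform requires strictly positive values")
    value <- log(value)
  }

  has_label <- columns[["label"]] %in% names(df)
  has_context <- columns[["context"]] %in% names(df)
  series <- lapply(split(seq_len(nrow(df)), subject), function(idx) {
    idx <- idx[order(occasion[idx])]
    longitudinal_series(
      subject_id = subject[idx[1L]],
      values = value[idx],
      labels = if (has_label) as.character(df[[columns[["label"]]]][idx]),
      context = if (has_context) as.character(df[[columns[["context"]]]][idx])
    )
  })
  series_collection(series, transform = transform)
}

#' Write a series collection as long-format delimited text
#'
#' Inverse of [read_long_table()]: emits columns `subject`, `occasion`,
#' `value` plus `label`/`context` when any series carries them. Values held
#' on the log scale are written back-transformed so the file round-trips.
#'
#' @param collection A [series_collection()].
#' @param path Output file path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_long_table <- function(collection, path, sep = ",") {
  stopifnot(inherits(collection, "series_collection"))
  df <- as.data.frame(collection)
  if (identical(attr(collection, "transform"), "log"))
    df$value <- exp(df$value)
  if (all(is.na(df$label))) df$label <- NULL
  if (all(is.na(df$context))) df$context <- NULL
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
as.data.frame.series_collection <- function(x, ...) {
  do.call(rbind, lapply(unname(x), function(s) {
    data.frame(subject = s$subject_id,
               occasion = seq_along(s$values),
               value = s$values,
               label = if (is.null(s$labels)) NA_character_ else s$labels,
               context = if (is.null(s$context)) NA_character_ else s$context,
               stringsAsFactors = FALSE)
  }))
}

# ---- running per-subject summaries -----------------------------------------

#' Running summary of one subject's history
#'
#' Tracks the count, running mean \eqn{\bar{y}_n} and running sum of squared
#' deviations (so the unbiased SD \eqn{\hat\sigma_n = \sqrt{ss/(n-1)}} is
#' available without revisiting the data). Updates use Welford's one-pass
#' scheme, so streaming one value at a time agrees with a batch computation
#' to numerical tolerance.
#'
#' @param values Optional numeric vector to consume immediately.
#' @return An object of class `subject_summary` with fields `n`, `mean`, `ss`.
#' @export
#' @examples
#' s <- update_summary(subject_summary(), c(4, 6))
#' s$mean      # 5
#' summary_sd(s)  # sqrt(2)
subject_summary <- function(values = NULL) {
  s <- structure(list(n = 0L, mean = NA_real_, ss = 0), class = "subject_summary")
  if (!is.null(values)) s <- update_summary(s, values)
  s
}

#' Consume one or more values into a running summary
#'
#' @param summary A [subject_summary()].
#' @param y Finite numeric value(s) to consume, in order.
#' @return The updated `subject_summary`.
#' @export
update_summary <- function(summary, y) {
  stopifnot(inherits(summary, "subject_summary"))
  y <- as.numeric(y)
  if (!all(is.finite(y))) stop("'y' must be finite")
  n <- summary$n; m <- if (n == 0L) 0 else summary$mean; ss <- summary$ss
  for (yi in y) {              # Welford
    n <- n + 1L
    d <- yi - m
    m <- m + d / n
    ss <- ss + d * (yi - m)
  }
  structure(list(n = n, mean = m, ss = ss), class = "subject_summary")
}

#' Unbiased standard deviation of a running summary
#'
#' Defined only once two observations have been consumed; `NA_real_` (not
#' zero) before that.
#'
#' @param summary A [subject_summary()].
#' @return `sqrt(ss / (n - 1))`, or `NA_real_` when `n < 2`.
#' @export
summary_sd <- function(summary) {
  stopifnot(inherits(summary, "subject_summary"))
  if (summary$n < 2L) return(NA_real_)
  sqrt(max(summary$ss, 0) / (summary$n - 1L))
}

#' @export
print.subject_summary <- function(x, ...) {
  cat("<subject_summary> n =", x$n, " mean =", format(x$mean),
      " sd =", format(summary_sd(x)), "\n")
  invisible(x)
}

# ---- reference ranges and flags --------------------------------------------

#' Construct a reference range
#'
#' The interval against which one future observation is judged: the
#' \eqn{(1-\alpha)} percentile range of the predictive distribution of the
#' next value, given the history consumed so far.
#'
#' @param lower,upper Interval limits (`lower <= upper`; `-Inf`/`Inf` allowed).
#' @param alpha Significance level in (0, 1).
#' @param sidedness `"two_sided"` or `"upper_only"` (one-sided upper interval
#'   with the lower limit clamped to 0, as used for nonnegative inflammation
#'   markers where low values are not clinically significant).
#' @param occasion 1-based index of the observation the range applies to.
#' @param method Generating method, `"zscore"` or `"lmm"`.
#' @return An object of class `reference_range`.
#' @export
reference_range <- function(lower, upper, alpha, sidedness = "two_sided",
                            occasion = NA_integer_, method = NA_character_) {
  if (!(alpha > 0 && alpha < 1) && alpha != 1)
    stop("'alpha' must lie in (0, 1)")
  if (is.na(lower) || is.na(upper) || lower > upper)
    stop("malformed range: need lower <= upper")
  if (!sidedness %in% c("two_sided", "upper_only"))
    stop("'sidedness' must be 'two_sided' or 'upper_only'")
  structure(list(lower = lower, upper = upper, alpha = alpha,
                 sidedness = sidedness, occasion = as.integer(occasion),
                 method = method),
            class = "reference_range")
}

#' @export
print.reference_range <- function(x, ...) {
  cat(sprintf("<reference_range> [%s, %s]  alpha = %g, %s, method = %s\n",
              format(x$lower), format(x$upper), x$alpha, x$sidedness,
              x$method))
  invisible(x)
}

#' Classify an observation against a reference range
#'
#' An observation is abnormal iff it falls strictly outside the range;
#' values exactly on a limit are classified normal (conservative flagging).
#'
#' @param y Observed value.
#' @param range A [reference_range()].
#' @return An object of class `flag` with fields `occasion`, `observed`,
#'   `range` and `verdict` (`"normal"` or `"abnormal"`).
#' @export
#' @examples
#' classify(9, reference_range(2, 8, alpha = 0.05))$verdict  # "abnormal"
classify <- function(y, range) {
  stopifnot(inherits(range, "reference_range"), is.finite(y))
  verdict <- if (y < range$lower || y > range$upper) "abnormal" else "normal"
  structure(list(occasion = range$occasion, observed = y, range = range,
                 verdict = verdict),
            class = "flag")
}

#' @export
print.flag <- function(x, ...) {
  cat(sprintf("<flag> occasion %s: %s -> %s in [%s, %s]\n",
              format(x$occasion), format(x$observed), x$verdict,
              format(x$range$lower), format(x$range$upper)))
  invisible(x)
}
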