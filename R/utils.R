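`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "reefshift_error")))
}

#' @keywords internal
as_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(x, format = "%Y-%m-%d")
  if (anyNA(out) && !anyNA(x)) {
    stop_("unparseable date(s): ", paste(utils::head(x[is.na(out)], 3), collapse = ", "),
          class = "reefshift_validation_error")
  }
  out
}

# decimal years since epoch; leap-safe predictor for per-decade slopes
year_fraction <- function(dates) as.numeric(as_date(dates)) / 365.25

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_(what, ": missing column(s) ", paste(missing, collapse = ", "),
          class = "reefshift_validation_error")
  }
  invisible(df)
}
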