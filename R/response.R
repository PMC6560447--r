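#' Response observations for a mixture design
#'
#' Holds observations of one quality property (batter stickiness, loaf
#' specific volume, crumb hardness, crumb-grain features, ...) for each
#' formulation of a design, either as replicate-level values or as published
#' summaries (mean, SD, replicate count).
#'
#' @param name response name (e.g. `"SVO"`, `"HARbr"`).
#' @param data data frame. Replicate level: columns `formulation_id`, `value`.
#'   Summary level: columns `formulation_id`, `mean`, `sd` and optionally `n`.
#' @param units measurement units (free text).
#' @return Object of class `response_set` with a `level` element
#'   (`"replicate"` or `"summary"`).
#' @export
response_set <- function(name, data, units = "") {
  data <- as.data.frame(data)
  if (all(c("formulation_id", "value") %in% names(data))) {
    level <- "replicate"
    if (anyNA(data$value)) stop("missing replicate values")
  } else if (all(c("formulation_id", "mean", "sd") %in% names(data))) {
    level <- "summary"
    if (any(data$sd < 0, na.rm = TRUE)) stop("negative SD")
    if (is.null(data$n)) data$n <- NA_real_
    if (any(data$n < 1, na.rm = TRUE)) stop("replicate count below 1")
    if (anyNA(data$mean)) stop("missing means")
  } else {
    stop("data must have (formulation_id, value) or (formulation_id, mean, sd[, n])")
  }
  structure(list(name = name, data = data, units = units, level = level),
            class = "response_set")
}

#' @export
print.response_set <- function(x, ...) {
  cat("Response '", x$name, "' (", x$level, " level",
      if (nzchar(x$units)) paste0(", ", x$units), "): ",
      nrow(x$data), " rows, ",
      length(unique(x$data$formulation_id)), " formulations\n", sep = "")
  invisible(x)
}

#' Collapse replicate-level observations to per-formulation summaries
#'
#' @param response a replicate-level `response_set`.
#' @return A summary-level `response_set` (mean, sd, n per formulation).
#' @export
summarize_response <- function(response) {
  stopifnot(inherits(response, "response_set"))
  if (response$level == "summary") return(response)
  sp <- split(response$data$value, response$data$formulation_id)
  out <- data.frame(
    formulation_id = as.integer(names(sp)),
    mean = vapply(sp, mean, numeric(1)),
    sd = vapply(sp, stats::sd, numeric(1)),
    n = vapply(sp, length, numeric(1))
  )
  out <- out[order(out$formulation_id), ]
  rownames(out) <- NULL
  response_set(response$name, out, response$units)
}
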