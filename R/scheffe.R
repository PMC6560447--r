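#' Scheffe mixture model from known coefficients
#'
#' Builds a prediction-only model object from published (or otherwise known)
#' coefficients of a Scheffe polynomial in actual-dose units, e.g. the fitted
#' equations a study prints. Interaction terms are named `"a:b"`.
#'
#' @param coefficients named numeric vector; names are term labels over the
#'   region components.
#' @param region the `mixture_region` the model lives on.
#' @param name optional response name.
#' @param units optional response units.
#' @return Object of class `scheffe_model`.
#' @examples
#' reg <- hydrocolloid_region()
#' svo <- scheffe_model(c(xanthan = 1.38, guar = -1.03, hpmc = 0.59,
#'                        "xanthan:guar" = 0.44, "guar:hpmc" = 0.49), reg)
#' predict(svo, c(0.24, 0.60, 3.16))
#' @export
scheffe_model <- function(coefficients, region, name = "", units = "") {
  terms <- names(coefficients)
  if (is.null(terms)) stop("coefficients must be named by term")
  lin <- terms[!grepl(":", terms)]
  if (!all(lin %in% region$components)) {
    stop("unknown linear terms: ", paste(setdiff(lin, region$components),
                                         collapse = ", "))
  }
  structure(
    list(coefficients = coefficients, terms = terms, region = region,
         name = name, units = units),
    class = "scheffe_model"
  )
}

#' @export
coef.scheffe_model <- function(object, ...) object$coefficients

#' Predict from a Scheffe mixture model
#'
#' Evaluates sum(beta_i x_i) + sum(beta_ij x_i x_j) at the given blends
#' (actual-dose units). Points outside the model's region trigger a warning,
#' not an error — extrapolation is the caller's responsibility.
#'
#' @param object a `scheffe_model` or `scheffe_fit`.
#' @param newdata blends: numeric vector, matrix or data frame of doses.
#' @param warn_outside warn when a point leaves the region.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.scheffe_model <- function(object, newdata, warn_outside = TRUE, ...) {
  m <- as_dose_matrix(newdata, object$region)
  if (warn_outside && !all(region_contains(object$region, m, tol = 1e-6))) {
    warning("predicting outside the mixture region")
  }
  X <- scheffe_model_matrix(m, object$region, object$terms)
  drop(X %*% object$coefficients)
}

#' @export
print.scheffe_model <- function(x, ...) {
  cat("Scheffe mixture model",
      if (nzchar(x$name)) paste0(" for ", x$name), ":\n", sep = "")
  b <- signif(x$coefficients, 4)
  cat("  y =", paste(paste0(b, "*", names(b)), collapse = " + "), "\n")
  invisible(x)
}

# align response rows with design rows; returns list(y, w, X, id)
assemble_fit_data <- function(design, response, terms, scale) {
  comps <- design$region$components
  pts <- design$points
  if (response$level == "replicate") {
    d <- response$data
    idx <- match(d$formulation_id, pts$formulation_id)
    if (anyNA(idx)) stop("response refers to unknown formulation ids")
    y <- d$value
    w <- rep(1, length(y))
  } else {
    d <- response$data
    idx <- match(d$formulation_id, pts$formulation_id)
    if (anyNA(idx)) stop("response refers to unknown formulation ids")
    y <- d$mean
    if (anyNA(d$n)) {
      message("replicate counts unknown for '", response$name,
              "'; using equal weights")
      w <- rep(1, length(y))
    } else {
      w <- d$n
    }
  }
  X <- scheffe_model_matrix(pts[idx, comps], design$region, terms, scale)
  list(y = y, w = w, X = X, id = d$formulation_id)
}

#' Fit a Scheffe mixture polynomial
#'
#' Least-squares fit of the no-intercept Scheffe model. Replicate-level data
#' are fit by ordinary least squares; summary-level data (formulation means)
#' are fit with weights equal to the replicate counts, which reproduces the
#' replicate-level coefficients exactly when replication is balanced. When
#' counts are unknown, equal weights are used with a message.
#'
#' @param design a `mixture_design`.
#' @param response a `response_set` paired with the design.
#' @param terms model terms (default: full two-factor-interaction set).
#' @param scale `"actual"` or `"coded"` dose scale for the model matrix.
#' @return Object of class `c("scheffe_fit", "scheffe_model")` carrying the
#'   underlying `lm` fit, the design, the response and elimination/outlier
#'   bookkeeping.
#' @export
scheffe_fit <- function(design, response,
                        terms = scheffe_terms(design$region$components),
                        scale = c("actual", "coded")) {
  scale <- match.arg(scale)
  stopifnot(inherits(design, "mixture_design"),
            inherits(response, "response_set"))
  fd <- assemble_fit_data(design, response, terms, scale)
  if (length(fd$y) < length(terms)) {
    stop("fewer observations (", length(fd$y), ") than model terms (",
         length(terms), ")")
  }
  if (qr(fd$X)$rank < ncol(fd$X)) stop("rank-deficient model matrix")
  df <- data.frame(.y = fd$y, fd$X, check.names = FALSE)
  fm <- stats::as.formula(paste(
    ".y ~ 0 +", paste(sprintf("`%s`", colnames(fd$X)), collapse = " + ")))
  lmfit <- stats::lm(fm, data = df, weights = fd$w)
  structure(
    list(coefficients = stats::setNames(stats::coef(lmfit), terms),
         terms = terms, region = design$region, name = response$name,
         units = response$units, design = design, response = response,
         scale = scale, lm = lmfit, weights = fd$w,
         formulation_id = fd$id,
         removed_terms = data.frame(term = character(0), p = numeric(0)),
         outliers = data.frame(row = integer(0), formulation_id = integer(0),
                               value = numeric(0), t = numeric(0))),
    class = c("scheffe_fit", "scheffe_model")
  )
}

#' @export
print.scheffe_fit <- function(x, ...) {
  cat("Scheffe mixture fit for '", x$name, "' (", x$response$level,
      "-level, ", x$scale, " scale)\n", sep = "")
  print(signif(x$coefficients, 4))
  if (nrow(x$removed_terms)) {
    cat("terms removed:", paste(x$removed_terms$term, collapse = ", "), "\n")
  }
  if (nrow(x$outliers)) {
    cat("outlying observations removed:", nrow(x$outliers), "\n")
  }
  invisible(x)
}

# p-values of interaction terms via partial (Type III) F tests
interaction_pvalues <- function(fit) {
  ints <- fit$terms[grepl(":", fit$terms)]
  if (length(ints) == 0) return(stats::setNames(numeric(0), character(0)))
  sm <- summary(fit$lm)$coefficients
  rn <- gsub("`", "", rownames(sm))
  stats::setNames(sm[match(ints, rn), 4], ints)
}

#' Backward elimination of non-significant interactions
#'
#' Removes, one per pass, the least significant interaction term with
#' p > `alpha` (partial F test) and refits, until all remaining interactions
#' are significant. Linear terms are always retained, so a non-significant
#' linear blending term stays in the model whenever it takes part in a
#' retained interaction (and, being a mixture model, also when it does not).
#'
#' @param fit a `scheffe_fit`.
#' @param alpha significance level (default 0.05).
#' @return A refit `scheffe_fit` whose `removed_terms` records the removal
#'   order and the p-value each term had when removed.
#' @export
backward_eliminate <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "scheffe_fit"))
  removed <- fit$removed_terms
  repeat {
    pv <- interaction_pvalues(fit)
    pv <- pv[!is.na(pv)]
    if (length(pv) == 0 || max(pv) <= alpha) break
    worst <- names(pv)[which.max(pv)]
    removed <- rbind(removed, data.frame(term = worst, p = max(pv)))
    new_terms <- setdiff(fit$terms, worst)
    fit <- scheffe_fit(fit$design, fit$response, new_terms, fit$scale)
    fit$removed_terms <- removed
  }
  fit
}

# residual/total sums of squares about the weighted grand mean
weighted_ss <- function(fit) {
  y <- fit$lm$model$.y
  w <- fit$weights
  ybar <- sum(w * y) / sum(w)
  list(y = y, w = w, ybar = ybar,
       ss_tot = sum(w * (y - ybar)^2),
       ss_res = sum(w * stats::residuals(fit$lm)^2))
}

#' Mixture ANOVA for a Scheffe fit
#'
#' Decomposition used for no-intercept mixture models: the total sum of
#' squares is corrected for the grand mean; the whole-model test compares the
#' fitted model against the grand mean; "linear mixture" tests the improvement
#' of the linear blending model over the grand mean; each retained interaction
#' gets a partial (Type III) F test; and, when replicate-level data are
#' available, the residual is split into lack-of-fit and pure error pooled
#' within formulations.
#'
#' @param object a `scheffe_fit`.
#' @param ... unused.
#' @return Object of class `scheffe_anova`: a data frame with columns
#'   `source`, `df`, `ss`, `ms`, `f`, `p`. Lack-of-fit rows are `NA` (with a
#'   message) for summary-level fits, and the lack-of-fit F is `Inf` when the
#'   pure-error sum of squares is zero.
#' @export
anova.scheffe_fit <- function(object, ...) {
  fit <- object
  ss <- weighted_ss(fit)
  p <- length(fit$terms)
  n_obs <- length(ss$y)
  df_model <- p - 1
  df_res <- n_obs - p
  ms_res <- ss$ss_res / df_res
  ss_model <- ss$ss_tot - ss$ss_res
  rows <- data.frame(
    source = "model", df = df_model, ss = ss_model, ms = ss_model / df_model,
    f = (ss_model / df_model) / ms_res,
    p = stats::pf((ss_model / df_model) / ms_res, df_model, df_res,
                  lower.tail = FALSE)
  )
  # linear mixture: improvement of linear blending over the grand mean
  lin_terms <- fit$terms[!grepl(":", fit$terms)]
  lin_fit <- scheffe_fit(fit$design, fit$response, lin_terms, fit$scale)
  ss_lin <- ss$ss_tot - weighted_ss(lin_fit)$ss_res
  df_lin <- length(lin_terms) - 1
  rows <- rbind(rows, data.frame(
    source = "linear mixture", df = df_lin, ss = ss_lin, ms = ss_lin / df_lin,
    f = (ss_lin / df_lin) / ms_res,
    p = stats::pf((ss_lin / df_lin) / ms_res, df_lin, df_res,
                  lower.tail = FALSE)))
  for (tm in fit$terms[grepl(":", fit$terms)]) {
    sub <- scheffe_fit(fit$design, fit$response, setdiff(fit$terms, tm),
                       fit$scale)
    ss_drop <- weighted_ss(sub)$ss_res - ss$ss_res
    rows <- rbind(rows, data.frame(
      source = tm, df = 1, ss = ss_drop, ms = ss_drop,
      f = ss_drop / ms_res,
      p = stats::pf(ss_drop / ms_res, 1, df_res, lower.tail = FALSE)))
  }
  # lack of fit / pure error need replicate-level data
  if (fit$response$level == "replicate") {
    groups <- split(ss$y, fit$formulation_id)
    m_distinct <- length(groups)
    ss_pe <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
    df_pe <- n_obs - m_distinct
    ss_lof <- ss$ss_res - ss_pe
    df_lof <- m_distinct - p
    if (df_pe <= 0) {
      message("no replication: lack-of-fit test undefined")
      f_lof <- NA_real_
      p_lof <- NA_real_
    } else if (df_lof <= 0) {
      f_lof <- NA_real_
      p_lof <- NA_real_
    } else if (ss_pe <= 0) {
      f_lof <- Inf
      p_lof <- 0
    } else {
      f_lof <- (ss_lof / df_lof) / (ss_pe / df_pe)
      p_lof <- stats::pf(f_lof, df_lof, df_pe, lower.tail = FALSE)
    }
    if (df_lof <= 0) {
      f_lof <- NA_real_
      p_lof <- NA_real_
      ss_lof <- max(ss_lof, 0)
    }
    rows <- rbind(rows,
      data.frame(source = "lack of fit", df = df_lof, ss = ss_lof,
                 ms = if (df_lof > 0) ss_lof / df_lof else NA_real_,
                 f = f_lof, p = p_lof),
      data.frame(source = "pure error", df = df_pe, ss = ss_pe,
                 ms = if (df_pe > 0) ss_pe / df_pe else NA_real_,
                 f = NA_real_, p = NA_real_))
  } else {
    message("summary-level fit: lack-of-fit requires replicate data")
  }
  rows <- rbind(rows, data.frame(
    source = "residual", df = df_res, ss = ss$ss_res, ms = ms_res,
    f = NA_real_, p = NA_real_))
  rownames(rows) <- NULL
  class(rows) <- c("scheffe_anova", "data.frame")
  rows
}

#' Fit-quality summary (R2 family, PRESS, CV, adequate precision)
#'
#' PRESS uses the leave-one-out hat-matrix identity e_i / (1 - h_ii); the
#' predicted R2 is 1 - PRESS / SS_total. CV is 100 sqrt(MSE) / mean(y).
#' Adequate precision is the signal-to-noise ratio
#' (max(yhat) - min(yhat)) / sqrt(p MSE / n) over the fitted design points;
#' values above 4 indicate a model able to navigate the design space.
#'
#' @param fit a `scheffe_fit`.
#' @return List with `r2`, `adj_r2`, `pred_r2`, `press`, `cv`, `adeq_precision`
#'   plus `press_undefined` flagging observations with leverage 1.
#' @export
fit_quality <- function(fit) {
  stopifnot(inherits(fit, "scheffe_fit"))
  ss <- weighted_ss(fit)
  p <- length(fit$terms)
  n_obs <- length(ss$y)
  df_res <- n_obs - p
  ms_res <- ss$ss_res / df_res
  h <- stats::hatvalues(fit$lm)
  e <- stats::residuals(fit$lm)
  at_one <- h > 1 - 1e-10
  press_terms <- ss$w * (e / (1 - h))^2
  press <- if (any(at_one)) NA_real_ else sum(press_terms)
  yhat <- stats::fitted(fit$lm)
  adeq <- (max(yhat) - min(yhat)) / sqrt(p * ms_res / n_obs)
  list(
    r2 = 1 - ss$ss_res / ss$ss_tot,
    adj_r2 = 1 - (ss$ss_res / df_res) / (ss$ss_tot / (n_obs - 1)),
    pred_r2 = if (is.na(press)) NA_real_ else 1 - press / ss$ss_tot,
    press = press,
    cv = 100 * sqrt(ms_res) / ss$ybar,
    adeq_precision = adeq,
    press_undefined = which(at_one)
  )
}

#' Iterative screening of outlying observations
#'
#' Computes externally studentized residuals (the variance estimate excludes
#' the observation itself), removes observations beyond the threshold, refits
#' and repeats, up to `max_passes` passes. Applies to replicate-level fits.
#'
#' @param fit a replicate-level `scheffe_fit`.
#' @param threshold absolute studentized-residual cutoff (default 4, the
#'   screening rule of the reference study).
#' @param max_passes maximum screening passes (default 3).
#' @return A refit `scheffe_fit`; removed observations are recorded in
#'   `$outliers`.
#' @export
screen_outliers <- function(fit, threshold = 4, max_passes = 3) {
  stopifnot(inherits(fit, "scheffe_fit"))
  if (fit$response$level != "replicate") {
    stop("outlier screening requires replicate-level data")
  }
  removed <- fit$outliers
  data <- fit$response$data
  for (pass in seq_len(max_passes)) {
    t_ext <- stats::rstudent(fit$lm)
    bad <- which(abs(t_ext) > threshold)
    if (length(bad) == 0) break
    keep <- setdiff(seq_len(nrow(data)), bad)
    for (fid in unique(data$formulation_id)) {
      if (!fid %in% data$formulation_id[keep]) {
        stop("outlier screening would remove every observation of formulation ",
             fid)
      }
    }
    removed <- rbind(removed, data.frame(
      row = bad, formulation_id = data$formulation_id[bad],
      value = data$value[bad], t = t_ext[bad]))
    data <- data[keep, , drop = FALSE]
    rownames(data) <- NULL
    resp <- response_set(fit$response$name, data, fit$response$units)
    fit <- scheffe_fit(fit$design, resp, fit$terms, fit$scale)
  }
  fit$outliers <- removed
  fit
}
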