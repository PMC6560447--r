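#' Scheffe term sets
#'
#' Terms of a Scheffe mixture polynomial: one linear term per component and,
#' for the two-factor-interaction (2FI) form, one term per unordered component
#' pair written `"a:b"`. There is no intercept — linear blending plays that
#' role under the fixed-total constraint.
#'
#' @param components character vector of component names.
#' @param model `"2fi"` or `"linear"`.
#' @return Character vector of term labels.
#' @examples
#' scheffe_terms(c("xanthan", "guar", "hpmc"))
#' @export
scheffe_terms <- function(components, model = c("2fi", "linear")) {
  model <- match.arg(model)
  terms <- components
  if (model == "2fi" && length(components) > 1) {
    pairs <- utils::combn(components, 2)
    terms <- c(terms, apply(pairs, 2, paste, collapse = ":"))
  }
  terms
}

# split "a:b" into c("a","b"); linear terms return length-1
term_parts <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

#' Model matrix for a Scheffe mixture polynomial
#'
#' One column per term, no intercept. Interaction columns are elementwise
#' products of the component doses. On the coded scale the linear columns of
#' any blend sum to one.
#'
#' @param points design points (vector, matrix or data frame of doses).
#' @param region a `mixture_region` (supplies component names and the total
#'   for coded scaling).
#' @param terms character vector of term labels, e.g. from [scheffe_terms()];
#'   linear terms must be present whenever an interaction involving them is.
#' @param scale `"actual"` (doses as given) or `"coded"` (doses / total).
#' @return Numeric matrix with `length(terms)` columns.
#' @export
scheffe_model_matrix <- function(points, region,
                                 terms = scheffe_terms(region$components),
                                 scale = c("actual", "coded")) {
  scale <- match.arg(scale)
  if (length(terms) == 0) stop("empty term set")
  lin <- terms[!grepl(":", terms)]
  for (tm in setdiff(terms, lin)) {
    if (!all(term_parts(tm) %in% lin)) {
      stop("interaction ", tm, " present without its linear terms")
    }
  }
  m <- as_dose_matrix(points, region)
  if (scale == "coded") m <- m / region$total
  X <- vapply(terms, function(tm) {
    p <- term_parts(tm)
    apply(m[, p, drop = FALSE], 1, prod)
  }, numeric(nrow(m)))
  X <- matrix(X, nrow = nrow(m), dimnames = list(NULL, terms))
  X
}

#' Construct a mixture design
#'
#' @param points data frame of design points (doses per component, optional
#'   `role` column).
#' @param region the `mixture_region`.
#' @param model target model, `"2fi"` or `"linear"`.
#' @param check_rank error if the model matrix is column-rank deficient.
#' @return Object of class `mixture_design`: list with `region`, `points`
#'   (data frame with `formulation_id`, `role`, doses), `model`.
#' @export
mixture_design <- function(points, region, model = c("2fi", "linear"),
                           check_rank = TRUE) {
  model <- match.arg(model)
  m <- as_dose_matrix(points, region)
  if (!all(region_contains(region, m, tol = 1e-6))) {
    stop("some design points fall outside the region")
  }
  role <- if (is.data.frame(points) && "role" %in% names(points)) {
    points$role
  } else {
    rep("other", nrow(m))
  }
  pts <- data.frame(formulation_id = seq_len(nrow(m)), role = role)
  pts <- cbind(pts, as.data.frame(m))
  if (check_rank) {
    X <- scheffe_model_matrix(m, region, scheffe_terms(region$components, model))
    if (qr(X)$rank < ncol(X)) {
      stop("design matrix is rank deficient for the ", model, " model")
    }
  }
  structure(list(region = region, points = pts, model = model),
            class = "mixture_design")
}

#' @export
print.mixture_design <- function(x, ...) {
  cat("Mixture design: ", nrow(x$points), " runs, ", x$model,
      " model, total = ", x$region$total, "\n", sep = "")
  print(design_table(x), digits = 4)
  invisible(x)
}

#' Design table in actual doses and coded fractions
#'
#' @param design a `mixture_design`.
#' @param digits rounding for display/export (the reference study prints two
#'   decimals); `NULL` keeps full precision.
#' @return Data frame with formulation id, role, doses and coded fractions.
#' @export
design_table <- function(design, digits = NULL) {
  comps <- design$region$components
  doses <- as.matrix(design$points[, comps])
  coded <- doses / design$region$total
  colnames(coded) <- paste0(comps, "_coded")
  out <- cbind(design$points[, c("formulation_id", "role")],
               as.data.frame(doses), as.data.frame(coded))
  if (!is.null(digits)) {
    num <- vapply(out, is.numeric, logical(1)) & names(out) != "formulation_id"
    out[num] <- lapply(out[num], round, digits = digits)
  }
  rownames(out) <- NULL
  out
}

# log-determinant of X'X; -Inf when singular
log_det_xtx <- function(X) {
  d <- determinant(crossprod(X), logarithm = TRUE)
  if (d$sign <= 0) -Inf else as.numeric(d$modulus)
}

#' D-optimal design selection by Fedorov point exchange
#'
#' Selects `n_runs` rows (repeats allowed) from a candidate set so as to
#' maximize det(X'X) of the Scheffe model matrix, using single-point Fedorov
#' exchange from seeded random starts with multiple restarts. Deterministic
#' for a given seed.
#'
#' @param candidates data frame of candidate points (e.g.
#'   [candidate_points()]).
#' @param region the `mixture_region`.
#' @param n_runs number of runs; must be at least the number of model terms.
#' @param model `"2fi"` or `"linear"`.
#' @param seed integer seed for the random starts.
#' @param n_starts number of random restarts.
#' @param max_iter exchange passes per start.
#' @return A `mixture_design` whose `d_efficiency` attribute holds
#'   det(X'X)^(1/p) / n and `log_det` the attained log-determinant.
#' @export
d_optimal <- function(candidates, region, n_runs, model = c("2fi", "linear"),
                      seed = 1L, n_starts = 20L, max_iter = 100L) {
  model <- match.arg(model)
  terms <- scheffe_terms(region$components, model)
  Xc <- scheffe_model_matrix(candidates, region, terms)
  p <- length(terms)
  if (n_runs < p) stop("n_runs must be >= number of model terms (", p, ")")
  if (qr(Xc)$rank < p) {
    stop("singular design: candidate set does not span the ", model,
         " model space")
  }
  nc <- nrow(Xc)
  best_rows <- NULL
  best_ld <- -Inf
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  for (s in seq_len(n_starts)) {
    rows <- sample.int(nc, n_runs, replace = n_runs > nc)
    ld <- log_det_xtx(Xc[rows, , drop = FALSE])
    # restart from a fresh sample if the random start is singular
    tries <- 0
    while (!is.finite(ld) && tries < 20) {
      rows <- sample.int(nc, n_runs, replace = n_runs > nc)
      ld <- log_det_xtx(Xc[rows, , drop = FALSE])
      tries <- tries + 1
    }
    for (it in seq_len(max_iter)) {
      improved <- FALSE
      for (i in seq_len(n_runs)) {
        for (j in seq_len(nc)) {
          if (j == rows[i]) next
          # keep the design a subset of distinct candidates unless the run
          # count forces replication
          if (n_runs <= nc && j %in% rows[-i]) next
          trial <- rows
          trial[i] <- j
          ld_t <- log_det_xtx(Xc[trial, , drop = FALSE])
          if (ld_t > ld + 1e-12) {
            rows <- trial
            ld <- ld_t
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    if (ld > best_ld + 1e-12) {
      best_ld <- ld
      best_rows <- rows
    }
  }
  if (!is.finite(best_ld)) stop("singular design: exchange found no non-singular subset")
  comps <- region$components
  sel <- candidates[sort(best_rows), , drop = FALSE]
  des <- mixture_design(sel, region, model)
  attr(des, "log_det") <- best_ld
  attr(des, "d_efficiency") <- exp(best_ld / p) / n_runs
  des
}
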