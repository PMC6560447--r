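#' Tukey HSD comparison of formulation means from summary statistics
#'
#' One-way ANOVA across formulations followed by Tukey's honest significant
#' difference test, computed directly from per-group means, SDs and replicate
#' counts (the form in which designed food-science experiments are usually
#' published). The pooled error mean square is the replication-weighted
#' average of the group variances; unequal group sizes use the Tukey-Kramer
#' harmonic form. Letters are assigned in descending-mean order with a greedy
#' insert-and-absorb pass, so two groups share a letter exactly when their
#' adjusted p-value is at least `alpha`.
#'
#' @param means numeric vector of group means (optionally named).
#' @param sds numeric vector of group SDs.
#' @param ns integer vector (or scalar) of replicate counts, each >= 2.
#' @param alpha familywise significance level (default 0.05).
#' @param labels group labels; defaults to names of `means` or 1..k.
#' @return Object of class `tukey_hsd`: list with `groups` (data frame of
#'   mean, sd, n, letters), `p_adj` (symmetric matrix of adjusted p-values),
#'   `ms_error`, `df_error`, `alpha`.
#' @examples
#' tukey_from_summary(c(a = 10, b = 10.1, c = 14), c(1, 1, 1), ns = 5)
#' @export
tukey_from_summary <- function(means, sds, ns, alpha = 0.05, labels = NULL) {
  k <- length(means)
  if (k < 2) stop("need at least two groups")
  if (length(ns) == 1) ns <- rep(ns, k)
  stopifnot(length(sds) == k, length(ns) == k)
  if (any(ns < 2)) stop("each group needs n >= 2 for a pooled error")
  if (is.null(labels)) {
    labels <- if (!is.null(names(means))) names(means) else as.character(seq_len(k))
  }
  df_err <- sum(ns - 1)
  ms_err <- sum((ns - 1) * sds^2) / df_err
  p_adj <- matrix(1, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      se <- sqrt(ms_err / 2 * (1 / ns[i] + 1 / ns[j]))
      if (se == 0) {
        p <- if (abs(means[i] - means[j]) > 0) 0 else 1
      } else {
        q <- abs(means[i] - means[j]) / se
        p <- stats::ptukey(q, nmeans = k, df = df_err, lower.tail = FALSE)
      }
      p_adj[i, j] <- p_adj[j, i] <- p
    }
  }
  letters <- compact_letters(means, p_adj >= alpha, labels)
  groups <- data.frame(group = labels, mean = as.numeric(means),
                       sd = as.numeric(sds), n = ns, letters = letters)
  structure(list(groups = groups, p_adj = p_adj, ms_error = ms_err,
                 df_error = df_err, alpha = alpha),
            class = "tukey_hsd")
}

#' Tukey HSD from replicate-level observations
#'
#' @param values numeric vector of observations.
#' @param group group membership (factor-like), one entry per observation.
#' @param alpha familywise significance level.
#' @return A `tukey_hsd` (see [tukey_from_summary()]).
#' @export
tukey_from_data <- function(values, group, alpha = 0.05) {
  sp <- split(values, group)
  tukey_from_summary(
    means = vapply(sp, mean, numeric(1)),
    sds = vapply(sp, stats::sd, numeric(1)),
    ns = vapply(sp, length, numeric(1)),
    alpha = alpha, labels = names(sp))
}

# insert-and-absorb compact letter display.
# same_mat[i, j] TRUE when groups i and j are NOT significantly different.
# Start from one letter covering all groups; for every significant pair,
# split each letter set containing both; absorb sets contained in others.
compact_letters <- function(means, same_mat, labels) {
  k <- length(means)
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (same_mat[i, j]) next
      hit <- vapply(sets, function(s) i %in% s && j %in% s, logical(1))
      if (!any(hit)) next
      new_sets <- sets[!hit]
      for (s in sets[hit]) {
        new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
      }
      # absorb sets fully contained in another set
      new_sets <- new_sets[lengths(new_sets) > 0]
      keep <- rep(TRUE, length(new_sets))
      for (a in seq_along(new_sets)) {
        for (b in seq_along(new_sets)) {
          if (a != b && keep[a] &&
              all(new_sets[[a]] %in% new_sets[[b]]) &&
              (length(new_sets[[a]]) < length(new_sets[[b]]) || a > b)) {
            keep[a] <- FALSE
          }
        }
      }
      sets <- new_sets[keep]
    }
  }
  # order letter sets by the best (largest) mean they contain
  sets <- sets[order(vapply(sets, function(s) -max(means[s]), numeric(1)))]
  out <- character(k)
  for (s in seq_along(sets)) {
    for (i in sets[[s]]) out[i] <- paste0(out[i], letters[s])
  }
  out
}

#' @export
print.tukey_hsd <- function(x, ...) {
  cat("Tukey HSD (alpha = ", x$alpha, ", pooled MS = ",
      signif(x$ms_error, 4), ", df = ", x$df_error, ")\n", sep = "")
  g <- x$groups[order(-x$groups$mean), ]
  rownames(g) <- NULL
  print(g, digits = 4)
  invisible(x)
}
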