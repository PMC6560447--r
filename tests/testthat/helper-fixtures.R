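# shared builders for the test suite; everything is generated in code

# random bounded 3-component region with a guaranteed non-empty interior
random_region <- function(seed) {
  set.seed(seed)
  total <- runif(1, 2, 10)
  mid <- as.numeric(stats::rmultinom(1, 100, rep(1, 3))) / 100 * total
  lower <- pmax(mid - runif(3, 0.05, 0.4) * total, 0)
  upper <- pmin(mid + runif(3, 0.05, 0.4) * total, total)
  names(lower) <- names(upper) <- c("a", "b", "c")
  mixture_region(lower, upper, total)
}

# independent vertex oracle: intersect all pairs of the six bound lines in
# the (x1, x2) plane (x3 eliminated through the total), keep feasible points
oracle_vertices <- function(region, tol = 1e-9) {
  l <- region$lower; u <- region$upper; Tt <- region$total
  # lines: x1 = l1, x1 = u1, x2 = l2, x2 = u2, x1 + x2 = T - u3, x1 + x2 = T - l3
  lines <- list(
    c(1, 0, l[1]), c(1, 0, u[1]), c(0, 1, l[2]), c(0, 1, u[2]),
    c(1, 1, Tt - u[3]), c(1, 1, Tt - l[3])
  )
  pts <- list()
  for (i in 1:5) {
    for (j in (i + 1):6) {
      A <- rbind(lines[[i]][1:2], lines[[j]][1:2])
      if (abs(det(A)) < 1e-12) next
      xy <- solve(A, c(lines[[i]][3], lines[[j]][3]))
      p <- c(xy, Tt - sum(xy))
      if (all(p >= l - tol) && all(p <= u + tol)) {
        pts[[length(pts) + 1L]] <- pmin(pmax(p, l), u)
      }
    }
  }
  if (!length(pts)) return(matrix(numeric(0), ncol = 3))
  m <- unique(round(do.call(rbind, pts), 9))
  m[do.call(order, as.data.frame(m)), , drop = FALSE]
}

# sorted dose matrix for set comparison
dose_set <- function(points, region, digits = 9) {
  m <- round(as.matrix(as.data.frame(points)[, region$components]), digits)
  m <- m[do.call(order, as.data.frame(m)), , drop = FALSE]
  dimnames(m) <- NULL
  m
}

# replicate-level gaussian data around a known model, as a response_set
sim_response <- function(design, beta, sigma, reps, seed, name = "y") {
  simulate_responses(design, scheffe_model(beta, design$region),
                     sigma, reps, seed, name = name)
}

ref_beta_svo <- c(xanthan = 1.38, guar = -1.03, hpmc = 0.59,
                  "xanthan:guar" = 0.44, "guar:hpmc" = 0.49)

full_beta <- function(region, lin = c(2, 1, 0.5), int = c(0.3, -0.2, 0.1)) {
  stats::setNames(
    c(lin, int),
    scheffe_terms(region$components))
}
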