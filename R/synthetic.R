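#' Simulate replicate-level responses from a Scheffe model
#'
#' Generates y_ij = prediction at formulation i + Normal(0, sigma) noise —
#' the statistical structure the fitting machinery assumes (iid Gaussian
#' replicates within formulation). Used to validate parameter recovery,
#' elimination and outlier screening without the study's raw data.
#'
#' @param design a `mixture_design`.
#' @param model a `scheffe_model` (or `scheffe_fit`) supplying the true
#'   coefficients, or a named coefficient vector.
#' @param sigma noise SD in response units; either a scalar or one value per
#'   formulation.
#' @param reps replicates per formulation.
#' @param seed integer seed.
#' @param name response name for the returned set.
#' @return A replicate-level `response_set`.
#' @examples
#' des <- reference_study()$design
#' svo <- reference_study()$models$SVO
#' sim <- simulate_responses(des, svo, sigma = 0.06, reps = 3, seed = 7)
#' @export
simulate_responses <- function(design, model, sigma, reps, seed = 1L,
                               name = "simulated") {
  stopifnot(inherits(design, "mixture_design"))
  if (is.numeric(model) && !is.null(names(model))) {
    model <- scheffe_model(model, design$region)
  }
  if (any(sigma < 0)) stop("noise SD must be non-negative")
  if (reps < 1) stop("need at least one replicate")
  comps <- design$region$components
  mu <- predict(model, design$points[, comps], warn_outside = FALSE)
  n_form <- nrow(design$points)
  sigma <- rep(sigma, length.out = n_form)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  out <- data.frame(
    formulation_id = rep(design$points$formulation_id, each = reps),
    value = rep(mu, each = reps) +
      stats::rnorm(n_form * reps, 0, rep(sigma, each = reps))
  )
  response_set(name, out, if (inherits(model, "scheffe_model")) model$units else "")
}

# expected md5 digests of the shipped reference tables
.fixture_md5 <- c(
  design.csv = "2338fb74d65c9f76a36f7d16bc5efe2c",
  response_summary.csv = "76c8c5af1f35dd3ba5025cdc7715b37b",
  model_coefficients.csv = "65300a0a49b6126952496e0a8032e6ee",
  optimum.csv = "fa7fc48a302abbc61539d4ccf8e64908"
)

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "breadmix")
  if (p == "") stop("reference table ", file, " not found in the package")
  p
}

#' Published tables of the reference hydrocolloid study
#'
#' Loads the study's printed experimental design, per-formulation response
#' summaries (means, SDs and replicate counts where stated), fitted model
#' coefficients and reported optimum, shipped as plain-text package data and
#' checksum-verified on load.
#'
#' @param check verify md5 checksums of the shipped files (default `TRUE`).
#' @return List with:
#'   \describe{
#'     \item{region}{the bounded `mixture_region` (total 4\%).}
#'     \item{design}{the 11-run `mixture_design` (doses as printed, 2 dp).}
#'     \item{responses}{named list of summary-level `response_set`s.}
#'     \item{models}{named list of `scheffe_model`s built from the printed
#'       coefficients (actual-dose units).}
#'     \item{optimum}{list with the reported optimal composition,
#'       desirability and predicted values there.}
#'   }
#' @export
reference_study <- function(check = TRUE) {
  files <- names(.fixture_md5)
  paths <- vapply(files, fixture_path, character(1))
  if (check) {
    got <- tools::md5sum(paths)
    names(got) <- files
    bad <- files[got != .fixture_md5 & .fixture_md5 != "UNSET"]
    if (length(bad)) {
      stop("corrupted package data: checksum mismatch for ",
           paste(bad, collapse = ", "))
    }
  }
  region <- hydrocolloid_region()
  des_tab <- utils::read.csv(paths[["design.csv"]])
  design <- mixture_design(des_tab, region, model = "2fi")
  resp_tab <- utils::read.csv(paths[["response_summary.csv"]])
  responses <- lapply(split(resp_tab, resp_tab$response), function(d) {
    response_set(d$response[1],
                 d[, c("formulation_id", "mean", "sd", "n")],
                 units = ifelse(is.na(d$units[1]), "", d$units[1]))
  })
  coef_tab <- utils::read.csv(paths[["model_coefficients.csv"]])
  models <- lapply(split(coef_tab, coef_tab$response), function(d) {
    resp <- responses[[d$response[1]]]
    scheffe_model(stats::setNames(d$estimate, d$term), region,
                  name = d$response[1],
                  units = if (!is.null(resp)) resp$units else "")
  })
  opt_tab <- utils::read.csv(paths[["optimum.csv"]])
  opt <- stats::setNames(opt_tab$value, opt_tab$quantity)
  optimum <- list(
    composition = opt[c("xanthan", "guar", "hpmc")],
    desirability = unname(opt["desirability"]),
    predictions = c(SVO = unname(opt["pred_SVO"]),
                    crust_L = unname(opt["pred_crust_L"]),
                    HARbr = unname(opt["pred_HARbr"]),
                    CDE = unname(opt["pred_CDE"]))
  )
  list(region = region, design = design, responses = responses,
       models = models, optimum = optimum)
}
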