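# Central composite design construction, factor coding, response-surface
# OLS with PRESS-based predicted R-squared, hierarchical backward
# elimination, and Pearson correlation matrices.
#
# The packaged study design has four factors: x1 particle size (um,
# center 725, step 375), x2 moisture content (%, center 2, step 1),
# x3 glidant/lubricant ratio (already coded) and the categorical
# x4 granule (-1) / pellet (+1).

#' Code a factor level
#'
#' Standard CCD coding: `(actual - center) / step`, so that the factorial
#' levels map to -1/+1.
#'
#' @param actual actual factor level(s).
#' @param center design center on the actual scale.
#' @param step half-range between the factorial levels.
#' @return Coded level(s).
#' @examples
#' code_factor(1100, 725, 375)   # +1
#' code_factor(0.6, 2, 1)        # -1.4 (axial)
#' @export
code_factor <- function(actual, center, step) {
  if (!is.numeric(step) || any(step == 0)) {
    stop("`step` must be nonzero", call. = FALSE)
  }
  (actual - center) / step
}

# coded half-fraction 2^(3-1) factorial block (x3 = -x1 * x2)
.ccd_fraction <- function() {
  rbind(c( 1,  1, -1),
        c( 1, -1,  1),
        c(-1,  1,  1),
        c(-1, -1, -1))
}

#' Build the central composite design
#'
#' Constructs the study's CCD for three numeric factors and one
#' two-level categorical factor: per categorical block, a half-fraction
#' `2^(3-1)` factorial (defining relation `x3 = -x1*x2`), six axial runs
#' and `n_center` center points, the whole block duplicated across the
#' categorical levels. The defaults reproduce the packaged 24-run
#' pellet/granule design (12 runs per categorical level, all coded
#' columns summing to zero).
#'
#' @param centers numeric centers of the three numeric factors
#'   (default particle size 725 um, moisture 2%, glidant ratio 0).
#' @param steps factorial half-ranges (default 375, 1, 1).
#' @param axial axial distances in coded units, one per numeric factor
#'   (default `c(sqrt(2), 1.4, 1.4)`, the study's values); must exceed 1.
#' @param n_center center points per categorical block (default 2).
#' @param factor_names names for the actual-scale columns.
#' @return A `data.frame` of class `"ccd_design"` with columns `sample`,
#'   the actual factor levels, `type` (`"granule"`/`"pellet"`) and coded
#'   columns `x1`..`x4`.
#' @export
build_ccd <- function(centers = c(725, 2, 0), steps = c(375, 1, 1),
                      axial = c(sqrt(2), 1.4, 1.4), n_center = 2,
                      factor_names = c("particle_size", "moisture",
                                       "glidant_ratio")) {
  if (any(axial <= 1)) stop("`axial` distances must exceed 1", call. = FALSE)
  if (length(axial) == 1) axial <- rep(axial, 3)
  fact <- .ccd_fraction()
  ax <- matrix(0, 6, 3)
  for (j in 1:3) {
    ax[2 * j - 1, j] <- -axial[j]
    ax[2 * j, j] <- axial[j]
  }
  block <- rbind(fact, ax, matrix(0, n_center, 3))
  # the packaged study lists one center run mid-block and one at the end;
  # run order within a block is not statistically meaningful, keep simple
  coded <- rbind(block, block)
  x4 <- rep(c(-1, 1), each = nrow(block))
  actual <- sweep(sweep(coded, 2, steps, `*`), 2, centers, `+`)
  out <- data.frame(sample = seq_len(nrow(coded)))
  for (j in 1:3) out[[factor_names[j]]] <- actual[, j]
  out$type <- ifelse(x4 < 0, "granule", "pellet")
  out$x1 <- coded[, 1]
  out$x2 <- coded[, 2]
  out$x3 <- coded[, 3]
  out$x4 <- x4
  class(out) <- c("ccd_design", "data.frame")
  out
}

#' Path to a packaged data file
#'
#' @param file file name under the package's `extdata` directory; with
#'   no argument, lists the available files.
#' @return Full path (or a character vector of file names).
#' @export
flowcone_example <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "flowcone")))
  }
  path <- system.file("extdata", file, package = "flowcone")
  if (path == "") stop("no packaged file ", file, call. = FALSE)
  path
}

#' Read the packaged study design and response tables
#'
#' `read_design_table()` loads the 24-run CCD of the pellet/granule
#' flowability study and derives the coded factors from the actual
#' levels (particle size 725 +/- 375 um, moisture 2 +/- 1%, glidant
#' ratio already coded, granule/pellet as -1/+1).
#' `read_response_table()` loads one of the per-sample response tables:
#' `"saor_ft"` (static angle of repose and flow time), `"avalanche"`
#' (amplitude, wavelength, count) or `"fit_params"` (power-law a, b, c,
#' a + b, AUFC). `study_data()` merges design and all responses into one
#' 24-row data frame.
#'
#' @param path optional path to a CSV with the same schema; defaults to
#'   the packaged file.
#' @param name which response table to read.
#' @return A data frame; the design additionally has class
#'   `"ccd_design"`.
#' @export
read_design_table <- function(path = flowcone_example("table1_design.csv")) {
  df <- utils::read.csv(path)
  need <- c("sample", "particle_size_um", "moisture_pct", "glidant_coded",
            "type")
  if (!all(need %in% names(df))) {
    stop("design table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) != 24) stop("design table must have 24 runs, found ",
                           nrow(df), call. = FALSE)
  df$x1 <- code_factor(df$particle_size_um, 725, 375)
  df$x2 <- code_factor(df$moisture_pct, 2, 1)
  df$x3 <- df$glidant_coded
  df$x4 <- ifelse(df$type == "pellet", 1, -1)
  class(df) <- c("ccd_design", "data.frame")
  df
}

#' @rdname read_design_table
#' @export
read_response_table <- function(name = c("saor_ft", "avalanche",
                                         "fit_params"), path = NULL) {
  name <- match.arg(name)
  file <- switch(name, saor_ft = "table3_saor_ft.csv",
                 avalanche = "table4_avalanche.csv",
                 fit_params = "table5_fit_params.csv")
  if (is.null(path)) path <- flowcone_example(file)
  df <- utils::read.csv(path)
  need <- switch(name,
                 saor_ft = c("sample", "saor_deg", "ft_s"),
                 avalanche = c("sample", "amplitude_px", "wavelength_frames",
                               "count"),
                 fit_params = c("sample", "a", "b", "c", "a_plus_b", "aufc"))
  if (!all(need %in% names(df))) {
    stop("table '", name, "' must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) != 24) stop("response table must have 24 rows, found ",
                           nrow(df), call. = FALSE)
  df
}

#' @rdname read_design_table
#' @export
study_data <- function() {
  d <- read_design_table()
  for (nm in c("saor_ft", "avalanche", "fit_params")) {
    d <- merge(d, read_response_table(nm), by = "sample", sort = TRUE)
  }
  d <- d[order(d$sample), ]
  class(d) <- c("ccd_design", "data.frame")
  d
}

# ---- model terms ---------------------------------------------------------

.rs_terms <- function(form) {
  main <- paste0("x", 1:4)
  tfi <- utils::combn(main, 2, FUN = paste, collapse = ":")
  sq <- paste0("I(x", 1:3, "^2)")   # x4 is categorical: no square term
  switch(form,
         linear = main,
         `2FI` = c(main, tfi),
         quadratic = c(main, tfi, sq),
         stop("unknown model form: ", form, call. = FALSE))
}

# model matrix for named terms on the coded columns of a design
.term_matrix <- function(design, terms) {
  one <- function(term) {
    if (term == "(Intercept)") return(rep(1, nrow(design)))
    if (grepl("^x[1-4]$", term)) {
      if (is.null(design[[term]])) stop("design lacks column ", term,
                                        call. = FALSE)
      return(design[[term]])
    }
    m <- regmatches(term, regexec("^(x[1-4]):(x[1-4])$", term))[[1]]
    if (length(m) == 3) return(design[[m[2]]] * design[[m[3]]])
    m <- regmatches(term, regexec("^I\\((x[1-4])\\^2\\)$", term))[[1]]
    if (length(m) == 2) return(design[[m[2]]]^2)
    stop("unknown model term: ", term, call. = FALSE)
  }
  X <- vapply(terms, one, numeric(nrow(design)))
  dimnames(X) <- list(NULL, terms)
  X
}

# ---- response-surface fit ------------------------------------------------

#' Fit a response surface on coded CCD factors
#'
#' Ordinary least squares of a response on the coded model terms, with
#' per-coefficient t-tests, an overall F-test, R-squared and the
#' PRESS-based predicted R-squared (leave-one-out closed form,
#' `PRESS = sum((e_i / (1 - h_ii))^2)`,
#' `pred R^2 = 1 - PRESS / SS_tot`; it can be negative, in which case
#' the response mean predicts better than the model).
#'
#' @param design a coded design ([build_ccd()], [read_design_table()]).
#' @param response numeric response vector, one value per run.
#' @param form `"linear"` (main effects), `"2FI"` (+ all two-factor
#'   interactions) or `"quadratic"` (+ squares of the numeric factors;
#'   the categorical `x4` enters linearly throughout).
#' @param terms instead of `form`, an explicit character vector of model
#'   terms (e.g. `c("x1", "x4", "I(x1^2)")`); the intercept is always
#'   included.
#' @return Object of class `"response_surface"`: list with `coefficients`
#'   (matrix of estimates, standard errors, t and p values), `terms`,
#'   `form`, `r_squared`, `pred_r_squared`, `press`, `f_statistic`,
#'   `f_pvalue`, `sigma`, `df_residual`, `fitted`, `residuals`, plus the
#'   `design` and `response` for refitting during model reduction.
#' @examples
#' d <- study_data()
#' fit <- fit_response_surface(d, d$saor_deg, form = "2FI")
#' coef(fit)["x4"]   # sphericity effect on the angle of repose
#' @export
fit_response_surface <- function(design, response,
                                 form = c("linear", "2FI", "quadratic"),
                                 terms = NULL) {
  if (is.null(terms)) {
    form <- match.arg(form)
    terms <- .rs_terms(form)
  } else {
    form <- "custom"
    terms <- setdiff(terms, "(Intercept)")
  }
  n <- nrow(design)
  if (length(response) != n) {
    stop("`response` must have one value per design run", call. = FALSE)
  }
  if (n < length(terms) + 2) {
    stop("too few runs (", n, ") for ", length(terms) + 1,
         " coefficients", call. = FALSE)
  }
  X <- .term_matrix(design, c("(Intercept)", terms))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient model; aliased terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, response)
  fitted <- as.numeric(X %*% beta)
  res <- response - fitted
  dfres <- n - ncol(X)
  rss <- sum(res^2)
  sigma2 <- rss / dfres
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(diag(XtXinv) * sigma2)
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), dfres, lower.tail = FALSE)
  tss <- sum((response - mean(response))^2)
  r2 <- 1 - rss / tss
  # overall F on the model terms
  dfm <- ncol(X) - 1
  fstat <- ((tss - rss) / dfm) / sigma2
  fp <- stats::pf(fstat, dfm, dfres, lower.tail = FALSE)
  # PRESS / predicted R-squared
  hat <- rowSums((X %*% XtXinv) * X)
  press <- sum((res / (1 - hat))^2)
  coefs <- cbind(Estimate = beta, `Std. Error` = se, `t value` = tval,
                 `Pr(>|t|)` = pval)
  structure(list(coefficients = coefs, terms = terms, form = form,
                 r_squared = r2, pred_r_squared = 1 - press / tss,
                 press = press, f_statistic = fstat, f_pvalue = fp,
                 sigma = sqrt(sigma2), df_residual = dfres,
                 fitted = fitted, residuals = res,
                 design = design, response = response),
            class = "response_surface")
}

#' @export
coef.response_surface <- function(object, ...) {
  stats::setNames(object$coefficients[, "Estimate"],
                  rownames(object$coefficients))
}

#' @export
residuals.response_surface <- function(object, ...) object$residuals

#' @export
fitted.response_surface <- function(object, ...) object$fitted

#' @export
predict.response_surface <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- .term_matrix(newdata, c("(Intercept)", object$terms))
  as.numeric(X %*% coef(object))
}

#' @export
print.response_surface <- function(x, digits = 4, ...) {
  cat(sprintf("Response surface (%s): %d runs, %d terms + intercept\n",
              x$form, length(x$response), length(x$terms)))
  stats::printCoefmat(x$coefficients, digits = digits)
  cat(sprintf("R-squared %.4f   predicted R-squared %.4f   ",
              x$r_squared, x$pred_r_squared))
  cat(sprintf("F = %.2f (p = %.3g)\n", x$f_statistic, x$f_pvalue))
  invisible(x)
}

#' @export
summary.response_surface <- function(object, ...) object

# hierarchy: parents of an interaction or square term
.term_parents <- function(term) {
  m <- regmatches(term, regexec("^(x[1-4]):(x[1-4])$", term))[[1]]
  if (length(m) == 3) return(m[2:3])
  m <- regmatches(term, regexec("^I\\((x[1-4])\\^2\\)$", term))[[1]]
  if (length(m) == 2) return(m[2])
  character(0)
}

#' Hierarchical backward elimination of a response surface
#'
#' Repeatedly removes the least significant removable term (largest
#' p-value above `alpha`) and refits, preserving model hierarchy: a main
#' effect is kept as long as any of its interactions or its square term
#' remains in the model.
#'
#' @param model a [fit_response_surface()] result.
#' @param alpha significance level for retention (default 0.05).
#' @return The reduced `"response_surface"`.
#' @examples
#' d <- study_data()
#' m <- fit_response_surface(d, d$wavelength_frames, form = "linear")
#' reduce_model(m)$terms   # only the sphericity factor survives
#' @export
reduce_model <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "response_surface"))
  repeat {
    terms <- model$terms
    p <- model$coefficients[-1, "Pr(>|t|)"]
    names(p) <- terms
    in_hierarchy <- vapply(terms, function(tm) {
      any(vapply(setdiff(terms, tm),
                 function(other) tm %in% .term_parents(other), logical(1)))
    }, logical(1))
    removable <- terms[!in_hierarchy & p > alpha]
    if (length(removable) == 0 || length(terms) == 1) break
    drop <- removable[which.max(p[removable])]
    model <- fit_response_surface(model$design, model$response,
                                  terms = setdiff(terms, drop))
  }
  model
}

# ---- correlation matrix --------------------------------------------------

#' Pearson correlation matrix with two-tailed significance
#'
#' Pairwise Pearson correlations of the given columns with two-tailed
#' t-test p-values (`t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom). Zero-variance columns give `NA` entries with a
#' warning rather than silent zeros.
#'
#' @param data data frame or matrix of numeric columns (>= 3 complete
#'   rows).
#' @return Object of class `"correlation_matrix"`: list with `r`
#'   (correlations), `p` (p-values), `n`. Printed with significance
#'   stars (`*` p < 0.05, `**` p < 0.01).
#' @examples
#' d <- study_data()
#' cm <- pearson_matrix(d[, c("b", "c", "saor_deg", "ft_s")])
#' cm$r["b", "c"]
#' @export
pearson_matrix <- function(data) {
  X <- as.matrix(as.data.frame(data))
  if (!is.numeric(X)) stop("all columns must be numeric", call. = FALSE)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  if (n < 3) stop("need at least 3 complete rows", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance column(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "),
            "; correlations undefined (NA)", call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(X))
  r[, sds == 0] <- NA
  r[sds == 0, ] <- NA
  diag(r)[sds > 0] <- 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  diag(p) <- NA
  structure(list(r = r, p = p, n = n), class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  stars <- ifelse(is.na(x$p), "", ifelse(x$p < 0.01, " **",
                  ifelse(x$p < 0.05, " *", "")))
  cells <- matrix(paste0(format(round(x$r, digits)), stars),
                  nrow(x$r), dimnames = dimnames(x$r))
  cat(sprintf("Pearson correlations (n = %d):\n", x$n))
  print(cells, quote = FALSE, right = TRUE)
  cat("*  p < 0.05, ** p < 0.01 (two-tailed)\n")
  invisible(x)
}
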