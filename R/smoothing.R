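#' Local (LOESS) regression fit
#'
#' Thin wrapper over [stats::loess()] with exact ("direct") surface
#' computation: local regression of degree `degree` with tricube weights
#' over the `ceiling(span * n)` nearest points. Predictions outside the
#' data range raise an error (no extrapolation).
#'
#' @param x,y numeric vectors.
#' @param span smoothing span in `(0, 1]`; `span * n` must be >= 3.
#' @param degree local polynomial degree, 1 (default) or 2.
#' @return object of class `mimetect_loess`: list with the `loess` fit,
#'   `span`, `degree`, and the data range.
#' @export
loess_fit <- function(x, y, span, degree = 1L) {
  if (length(x) != length(y)) stop2("'x' and 'y' lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  assert_fraction(span, "span", open0 = TRUE)
  if (ceiling(span * n) < 3) stop2("span * n must be >= 3")
  if (n < max(5, ceiling(span * n))) stop2("too few points for this span")
  if (diff(range(x)) <= 0) stop2("'x' is degenerate (all values equal)")
  fit <- loess(y ~ x, span = span, degree = degree, family = "gaussian",
               control = loess.control(surface = "direct"),
               data = data.frame(x = x, y = y))
  structure(list(fit = fit, span = span, degree = degree,
                 range = range(x), x = x, y = y),
            class = "mimetect_loess")
}

#' Evaluate a LOESS fit (optionally with pointwise standard errors)
#'
#' @param object a `mimetect_loess`.
#' @param newdata numeric vector of x values within the fitted range.
#' @param se return pointwise standard errors of the smoother.
#' @param ... unused.
#' @return numeric vector of fitted values, or a list `fit`/`se` when
#'   `se = TRUE`.
#' @export
predict.mimetect_loess <- function(object, newdata, se = FALSE, ...) {
  if (any(newdata < object$range[1] - 1e-9 | newdata > object$range[2] + 1e-9))
    stop2("extrapolation outside the fitted x range is not supported")
  pr <- predict(object$fit, newdata = data.frame(x = newdata), se = se)
  if (se) list(fit = as.numeric(pr$fit), se = as.numeric(pr$se.fit)) else
    as.numeric(pr)
}

#' Select the LOESS span by k-fold cross-validation
#'
#' Partitions the data into `folds` random (seeded) folds; for each span
#' on the grid, the CV mean squared error is the mean squared held-out
#' prediction error. The selected span minimizes CV MSE; ties go to the
#' smaller span (noted by a message). The default grid runs from 0.4 to
#' 0.9 in increments of 0.01.
#'
#' @param x,y numeric vectors.
#' @param span_grid candidate spans.
#' @param folds number of CV folds, default 10.
#' @param seed seed for the fold partition.
#' @param degree local polynomial degree.
#' @return object of class `loess_model`: list with `fit` (the
#'   `mimetect_loess` refit at the selected span on all data),
#'   `selected_span`, `cv` (data frame span, mse), `folds`, `seed`.
#' @export
select_span_cv <- function(x, y, span_grid = seq(0.4, 0.9, by = 0.01),
                           folds = 10L, seed = 1L, degree = 1L) {
  n <- length(x)
  assert_count(folds, "folds", min = 2L)
  if (n < folds) stop2("need at least as many points as folds")
  set.seed(derive_seed(seed, "cv_folds"))
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  if (min(table(fold_id)) < 2L)
    stop2("a fold has < 2 points; use fewer folds")
  mse <- vapply(span_grid, function(sp) {
    errs <- numeric(0)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- suppressWarnings(loess(
        y ~ x, span = sp, degree = degree, family = "gaussian",
        control = loess.control(surface = "direct"),
        data = data.frame(x = x[tr], y = y[tr])))
      pred <- predict(fit, newdata = data.frame(x = x[!tr]))
      errs <- c(errs, (y[!tr] - pred)^2)
    }
    mean(errs)
  }, numeric(1))
  best <- which(mse <= min(mse) + 1e-15)
  if (length(best) > 1L)
    message("CV MSE tie; smallest span chosen")
  sel <- span_grid[min(best)]
  structure(list(fit = loess_fit(x, y, span = sel, degree = degree),
                 selected_span = sel,
                 cv = data.frame(span = span_grid, mse = mse),
                 folds = folds, seed = seed),
            class = "loess_model")
}

#' Locate the minimum (nadir) of a smoothed time course
#'
#' Evaluates the fitted curve on a regular grid over the data range and
#' returns the grid argmin with the pointwise 95% band of the smoother at
#' that point. A minimum on the grid boundary (monotone trend) triggers a
#' warning.
#'
#' @param model a `loess_model` (from [select_span_cv()]) or
#'   `mimetect_loess`.
#' @param grid_step evaluation grid step in x units, default 0.25.
#' @param level confidence level of the band, default 0.95.
#' @return list with `x_min`, `fit_min`, `lower`, `upper`, `grid`
#'   (data frame x, fit, se).
#' @export
find_nadir <- function(model, grid_step = 0.25, level = 0.95) {
  fit <- if (inherits(model, "loess_model")) model$fit else model
  stopifnot(inherits(fit, "mimetect_loess"))
  grid <- seq(fit$range[1], fit$range[2], by = grid_step)
  pr <- predict(fit, grid, se = TRUE)
  i <- which.min(pr$fit)
  if (i == 1L || i == length(grid))
    warn2("minimum lies on the boundary of the observed age range")
  z <- qnorm(1 - (1 - level) / 2)
  list(x_min = grid[i], fit_min = pr$fit[i],
       lower = pr$fit[i] - z * pr$se[i], upper = pr$fit[i] + z * pr$se[i],
       grid = data.frame(x = grid, fit = pr$fit, se = pr$se))
}
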