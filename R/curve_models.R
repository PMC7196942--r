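# Polynomial least squares. Degree degrades gracefully when data are short:
# cubic needs >= 5 points and >= 4 distinct x; otherwise the highest order the
# points support (down to interpolating line / intercept). With
# allow_saturated = FALSE (segment fits) the order is additionally capped at
# (distinct levels - 2), so a segment never interpolates its score levels:
# a saturated segment has zero lack of fit by construction, which would let a
# breakpoint search hide a true regime change inside it.
.fit_poly <- function(x, y, max_degree = 3L, allow_saturated = TRUE) {
  n <- length(x)
  distinct <- length(unique(x))
  degree <- min(max_degree,
                if (n >= 5) 3L else max(1L, n - 2L),
                distinct - (if (allow_saturated) 1L else 2L))
  degree <- max(degree, 0L)
  X <- outer(x, 0:degree, `^`)
  fit <- stats::lm.fit(X, y)
  coefs <- c(fit$coefficients, rep(0, 3L - degree))
  names(coefs) <- paste0("b", 0:3)
  fitted <- drop(X %*% fit$coefficients)
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst <= 0) 0 else min(max(1 - sse / sst, 0), 1)
  df2 <- n - degree - 1L
  std_errors <- rep(NA_real_, 4L)
  if (df2 > 0) {
    xtx_inv <- tryCatch(solve(crossprod(X)), error = function(e) NULL)
    if (!is.null(xtx_inv)) {
      std_errors[seq_len(degree + 1L)] <- sqrt(diag(xtx_inv) * sse / df2)
    }
  }
  names(std_errors) <- paste0("b", 0:3)
  p <- if (degree == 0L || df2 <= 0 || sst <= 0 || sse <= 0) {
    NA_real_
  } else {
    f <- (r2 / degree) / ((1 - r2) / df2)
    stats::pf(f, degree, df2, lower.tail = FALSE)
  }
  structure(
    list(coefficients = coefs, std_errors = std_errors, degree = degree,
         r_squared = r2, p_value = p, n = n, sse = sse, sst = sst,
         x = x, y = y, fitted = fitted),
    class = c(if (max_degree >= 3L) "casus_cubic_fit" else "casus_linear_fit",
              "casus_fit")
  )
}

#' Cubic regression of flow on stenosis score
#'
#' Ordinary least-squares fit of `flow = b0 + b1 x + b2 x^2 + b3 x^3`, the
#' model used to trace how global blood flow falls as the total stenosis
#' score rises. R-squared is `1 - SSE/SST` on the fitted data; the p-value is
#' the overall F test. A constant outcome is fitted as its mean with the
#' convention R-squared = 0.
#'
#' @param data Data frame holding the score and flow columns.
#' @param score,flow Column names (tidy-eval); default `tss`, `gbf_ml_min`.
#' @return A `casus_cubic_fit`: coefficients `b0..b3`, `r_squared`,
#'   `p_value`, `n`. Supports [predict()], [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' d <- tibble::tibble(tss = 0:6, gbf_ml_min = 2 - (0:6) + 0.5 * (0:6)^2)
#' fit_cubic(d)
#' @export
fit_cubic <- function(data, score = tss, flow = gbf_ml_min) {
  x <- dplyr::pull(data, {{ score }})
  y <- dplyr::pull(data, {{ flow }})
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 5) abort_validation("Cubic fit needs at least 5 observations.")
  if (length(unique(x)) < 4) {
    abort_computation("Cubic fit needs at least 4 distinct score values (rank-deficient otherwise).")
  }
  .fit_poly(x, y, 3L)
}

#' Linear regression of flow on stenosis score
#'
#' The single-vessel analogue: flow falls roughly linearly in a vessel's own
#' 0-4 stenosis score.
#'
#' @inheritParams fit_cubic
#' @param score,flow Column names (tidy-eval); default `ss`,
#'   `blood_flow_ml_min`.
#' @return A `casus_linear_fit` with `b0` (intercept), `b1` (slope),
#'   `r_squared`, `p_value`, `n`.
#' @export
fit_linear <- function(data, score = ss, flow = blood_flow_ml_min) {
  x <- dplyr::pull(data, {{ score }})
  y <- dplyr::pull(data, {{ flow }})
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2 || length(unique(x)) < 2) {
    abort_computation("Linear fit needs at least 2 distinct score values.")
  }
  .fit_poly(x, y, 1L)
}

#' Evaluate a cubic polynomial at given scores
#'
#' Convenience for predicting from printed coefficients, e.g. a published
#' fitted equation, without refitting.
#'
#' @param coefficients Numeric `(b0, b1, b2, b3)`.
#' @param x Scores at which to evaluate.
#' @return `b0 + b1 x + b2 x^2 + b3 x^3`.
#' @examples
#' eval_cubic(c(1380.6, -13.3, 24.2, -1.2), 0) # 1380.6
#' @export
eval_cubic <- function(coefficients, x) {
  stopifnot(length(coefficients) == 4)
  drop(outer(x, 0:3, `^`) %*% coefficients)
}

#' Three-segment cubic regression with breakpoint search
#'
#' Fits an independent polynomial (cubic where the segment supports it) on
#' each of the three score ranges `x < t1`, `t1 <= x <= t2`, `x > t2` for
#' every candidate breakpoint pair, and selects the pair maximising the
#' pooled R-squared `1 - sum(segment SSE) / SST(all flows)`. This captures
#' the inverse-S flow-score relationship: initial decline, compensated
#' plateau, second decline. No continuity constraint is imposed at the
#' breakpoints. Ties are broken towards the smaller first threshold, then the
#' smaller second.
#'
#' Segment fits are never allowed to saturate their observed score levels
#' (polynomial order at most the number of distinct scores minus 2): an
#' interpolating segment has zero lack of fit whatever the data, so without
#' the cap the search degenerates into rewarding whichever partition isolates
#' the sparsest score ranges instead of the true regime boundaries. A
#' consequence is that a segmentation with very short segments can score
#' below the unsegmented cubic; the nesting guarantee (pooled R-squared at
#' least the global cubic's) holds whenever every segment supports a cubic.
#'
#' Because candidate pairs can consume different numbers of parameters (a
#' short segment is fitted with a lower order), the raw pooled R-squared is
#' biased towards partitions that spend the most parameters; the *selection*
#' therefore maximises the df-adjusted pooled R-squared
#' `1 - (SSE / (n - p)) / (SST / (n - 1))` with `p` the total parameters
#' across the three segments, while the plain pooled R-squared is reported
#' for the selected pair.
#'
#' @inheritParams fit_cubic
#' @param breakpoints Candidate pairs: a two-column matrix / data frame or a
#'   list of length-2 vectors. Default: every integer pair
#'   `3 <= t1 < t2 <= 12`.
#' @return A `casus_segmented_fit`: `breakpoints`, `segment_fits` (list of
#'   three fits), `pooled_r_squared`, and `candidates`, the per-pair search
#'   table.
#' @export
fit_segmented <- function(data, score = tss, flow = gbf_ml_min,
                          breakpoints = NULL) {
  x <- dplyr::pull(data, {{ score }})
  y <- dplyr::pull(data, {{ flow }})
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (is.null(breakpoints)) {
    grid <- expand.grid(t1 = 3:12, t2 = 3:12)
    breakpoints <- grid[grid$t1 < grid$t2, ]
  }
  if (is.data.frame(breakpoints) || is.matrix(breakpoints)) {
    breakpoints <- asplit(as.matrix(breakpoints), 1)
  }
  if (length(breakpoints) == 0) abort_validation("Empty breakpoint candidate list.")

  sst <- sum((y - mean(y))^2)
  fit_one_pair <- function(bp) {
    t1 <- bp[[1]]; t2 <- bp[[2]]
    if (!(t1 < t2)) abort_validation("Breakpoints must satisfy t1 < t2.")
    seg <- ifelse(x < t1, 1L, ifelse(x <= t2, 2L, 3L))
    if (any(tabulate(seg, 3L) < 2L)) {
      rlang::warn(sprintf(
        "Breakpoint pair (%g, %g) leaves a segment with < 2 points; skipped.",
        t1, t2))
      return(NULL)
    }
    fits <- lapply(1:3, function(s) {
      .fit_poly(x[seg == s], y[seg == s], 3L, allow_saturated = FALSE)
    })
    sse <- sum(vapply(fits, `[[`, numeric(1), "sse"))
    p <- sum(vapply(fits, `[[`, integer(1), "degree")) + 3L
    n <- length(x)
    adj <- if (sst <= 0 || n - p <= 0) {
      -Inf
    } else {
      1 - (sse / (n - p)) / (sst / (n - 1))
    }
    list(t1 = t1, t2 = t2, fits = fits, n_params = p, adj_r2 = adj,
         pooled_r2 = if (sst <= 0) 0 else min(max(1 - sse / sst, 0), 1))
  }

  results <- purrr::compact(purrr::map(breakpoints, fit_one_pair))
  if (length(results) == 0) {
    abort_computation("Every breakpoint candidate left an empty or degenerate segment.")
  }
  cand <- tibble::tibble(
    t1 = purrr::map_dbl(results, "t1"),
    t2 = purrr::map_dbl(results, "t2"),
    pooled_r_squared = purrr::map_dbl(results, "pooled_r2"),
    adj_r_squared = purrr::map_dbl(results, "adj_r2"),
    n_params = purrr::map_dbl(results, "n_params")
  )
  best_idx <- order(-cand$adj_r_squared, cand$t1, cand$t2)[1]
  best <- results[[best_idx]]
  structure(
    list(breakpoints = c(best$t1, best$t2),
         segment_fits = best$fits,
         pooled_r_squared = best$pooled_r2,
         candidates = dplyr::arrange(cand, .data$t1, .data$t2),
         n = length(x), sst = sst, x = x, y = y),
    class = "casus_segmented_fit"
  )
}

#' @export
predict.casus_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) {
    object$x
  } else if (is.data.frame(newdata)) {
    newdata[[1]]
  } else {
    newdata
  }
  eval_cubic(object$coefficients, x)
}

#' @export
predict.casus_segmented_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) {
    object$x
  } else if (is.data.frame(newdata)) {
    newdata[[1]]
  } else {
    newdata
  }
  t1 <- object$breakpoints[1]; t2 <- object$breakpoints[2]
  seg <- ifelse(x < t1, 1L, ifelse(x <= t2, 2L, 3L))
  out <- numeric(length(x))
  for (s in 1:3) {
    if (any(seg == s)) {
      out[seg == s] <- eval_cubic(object$segment_fits[[s]]$coefficients,
                                  x[seg == s])
    }
  }
  out
}

#' @export
print.casus_fit <- function(x, ...) {
  cat(sprintf("Polynomial fit (degree %d, n = %d)\n", x$degree, x$n))
  cat("  coefficients:",
      paste(sprintf("%s = %.4g", names(x$coefficients), x$coefficients),
            collapse = ", "), "\n")
  cat(sprintf("  R-squared = %.3f, p = %.3g\n", x$r_squared, x$p_value))
  invisible(x)
}

#' @export
print.casus_segmented_fit <- function(x, ...) {
  cat(sprintf(
    "Three-segment fit: breakpoints (%g, %g), pooled R-squared = %.3f, n = %d\n",
    x$breakpoints[1], x$breakpoints[2], x$pooled_r_squared, x$n))
  invisible(x)
}

#' @export
tidy.casus_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = unname(x$std_errors))
}

#' @export
tidy.casus_segmented_fit <- function(x, ...) {
  purrr::map2_dfr(x$segment_fits, seq_along(x$segment_fits), function(f, i) {
    dplyr::mutate(tidy(f), segment = i, .before = 1)
  })
}

#' @export
glance.casus_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, p.value = x$p_value,
                 df = x$degree, nobs = x$n)
}

#' @export
glance.casus_segmented_fit <- function(x, ...) {
  tibble::tibble(t1 = x$breakpoints[1], t2 = x$breakpoints[2],
                 pooled.r.squared = x$pooled_r_squared, nobs = x$n)
}

fit_plot_data <- function(object) {
  grid <- seq(min(object$x), max(object$x), length.out = 200)
  list(points = tibble::tibble(x = object$x, y = object$y),
       curve = tibble::tibble(x = grid,
                              y = stats::predict(object, newdata = grid)))
}

#' @export
autoplot.casus_fit <- function(object, ...) {
  d <- fit_plot_data(object)
  ggplot2::ggplot(d$points, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = d$curve, colour = "#2166ac", linewidth = 1) +
    ggplot2::labs(x = "stenosis score", y = "blood flow (mL/min)",
                  title = sprintf("Polynomial fit (R² = %.3f)",
                                  object$r_squared)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.casus_segmented_fit <- function(object, ...) {
  d <- fit_plot_data(object)
  ggplot2::ggplot(d$points, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = d$curve, colour = "#b2182b", linewidth = 1) +
    ggplot2::geom_vline(xintercept = object$breakpoints, linetype = "dashed") +
    ggplot2::labs(x = "total stenosis score", y = "global blood flow (mL/min)",
                  title = sprintf(
                    "Segmented fit, breakpoints (%g, %g), pooled R² = %.3f",
                    object$breakpoints[1], object$breakpoints[2],
                    object$pooled_r_squared)) +
    ggplot2::theme_minimal()
}
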