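## Polynomial trend fitting along the altitudinal gradient with
## significance-driven degree selection: cubic first, quadratic if the cubic
## term is not significant, linear as the floor (reported even when its
## slope is itself not significant).

#' Fit one polynomial of fixed degree
#'
#' Ordinary least squares on powers of centered altitude (centering controls
#' the collinearity of raw powers); coefficients are mapped back to the raw
#' altitude scale before being reported. The p-value of the highest-order
#' coefficient comes from its two-sided t-test. Exact fits (zero residual
#' variance) have no valid t-test and are flagged \code{perfect_fit}.
#'
#' @param x Predictor (interval midpoints in meters).
#' @param y Response (density or mean SSI).
#' @param degree Polynomial degree, >= 1.
#' @return List with \code{degree}, \code{coefficients} (raw scale,
#'   ascending order), \code{r_squared}, \code{p_highest},
#'   \code{perfect_fit}, \code{n_points} and the underlying \code{lm} fit
#'   (on centered x) plus the centering constant \code{x_center}.
#' @export
fit_polynomial <- function(x, y, degree) {
  stopifnot(degree >= 1)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < degree + 2) {
    stop("need at least degree + 2 = ", degree + 2,
         " points to fit and test a degree-", degree, " polynomial (got ",
         n, ")", call. = FALSE)
  }
  if (length(unique(x)) <= degree) {
    stop("predictor has too few distinct values for degree ", degree,
         call. = FALSE)
  }
  xc <- x - mean(x)
  X <- stats::poly(xc, degree = degree, raw = TRUE)
  fit <- stats::lm(y ~ X)
  beta_c <- stats::coef(fit)                  # centered-scale coefficients
  beta_c[is.na(beta_c)] <- 0

  tss <- sum((y - mean(y))^2)
  rss <- sum(stats::residuals(fit)^2)
  r_squared <- if (tss <= 0) 0 else max(0, min(1, 1 - rss / tss))
  perfect <- rss <= 1e-12 * max(tss, 1)

  p_highest <- if (perfect) NA_real_ else {
    ct <- stats::coef(summary(fit))
    rn <- paste0("X", degree)
    if (rn %in% rownames(ct)) ct[rn, "Pr(>|t|)"] else NA_real_
  }

  list(degree = degree,
       coefficients = uncenter_poly(beta_c, mean(x)),
       r_squared = r_squared,
       p_highest = p_highest,
       perfect_fit = perfect,
       top_coefficient = unname(beta_c[degree + 1]),
       n_points = n,
       x_center = mean(x),
       lm_fit = fit)
}

# Expand sum_k b_k (x - c)^k into raw-scale coefficients of x^k.
uncenter_poly <- function(beta_centered, center) {
  d <- length(beta_centered) - 1L
  raw <- numeric(d + 1L)
  for (k in 0:d) {
    # (x - c)^k = sum_j choose(k, j) x^j (-c)^(k - j)
    for (j in 0:k) {
      raw[j + 1L] <- raw[j + 1L] +
        beta_centered[k + 1L] * choose(k, j) * (-center)^(k - j)
    }
  }
  stats::setNames(raw, paste0("x^", 0:d))
}

significance_label <- function(p) {
  if (is.na(p)) return("ns")
  if (p < 0.001) "p<0.001" else if (p < 0.01) "p<0.01"
  else if (p < 0.05) "p<0.05" else "ns"
}

#' Select an altitudinal trend by backward degree selection
#'
#' Tries a cubic first (when enough points are available); if the cubic term
#' is not significant at \code{alpha}, falls back to a quadratic; if the
#' quadratic term is also not significant, reports the linear fit, which is
#' kept even when its slope is not significant (labelled \code{ns}). An
#' exactly interpolating fit with a nonzero top coefficient is retained as
#' if significant, since its t-test is undefined. Cubics need at least 5
#' points and quadratics at least 4 (degree + 2, so the top term is
#' testable); degrees that would saturate are skipped, not errors.
#'
#' @param x Interval midpoints (meters).
#' @param y Response; \code{NA}s are dropped pairwise.
#' @param alpha Significance level of the term-dropping rule.
#' @return Object of class \code{alti_trend}: the [fit_polynomial()] fields
#'   plus \code{degree_label} (\code{a}/\code{b}/\code{c} for degree
#'   1/2/3), \code{significance_label} and \code{alpha}.
#' @export
#' @examples
#' x <- seq(150, 1250, by = 100)
#' sel <- select_trend(x, 2 + 0.001 * x)
#' sel$degree # 1
select_trend <- function(x, y, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) {
    stop("need at least 3 points to fit a trend (got ", length(x), ")",
         call. = FALSE)
  }
  chosen <- NULL
  for (degree in c(3, 2)) {
    if (length(x) < degree + 2 || length(unique(x)) <= degree) next
    fit <- fit_polynomial(x, y, degree)
    retained <- if (fit$perfect_fit) {
      abs(fit$top_coefficient) > 1e-10
    } else {
      !is.na(fit$p_highest) && fit$p_highest < alpha
    }
    if (retained) { chosen <- fit; break }
  }
  if (is.null(chosen)) chosen <- fit_polynomial(x, y, 1)

  chosen$alpha <- alpha
  chosen$degree_label <- c("a", "b", "c")[chosen$degree]
  chosen$significance_label <-
    if (chosen$perfect_fit && abs(chosen$top_coefficient) > 1e-10) {
      "p<0.001"
    } else {
      significance_label(chosen$p_highest)
    }
  class(chosen) <- "alti_trend"
  chosen
}

#' @export
print.alti_trend <- function(x, digits = 3, ...) {
  cat(sprintf("Polynomial trend: degree %d (%s), R2 = %.2f, %s (n = %d)\n",
              x$degree, x$degree_label, x$r_squared,
              x$significance_label, x$n_points))
  cat("Coefficients (raw scale):\n")
  print(signif(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.alti_trend <- function(object, ...) object$coefficients

#' @export
predict.alti_trend <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    return(unname(stats::fitted(object$lm_fit)))
  }
  x <- if (is.data.frame(newdata)) newdata[[1]] else newdata
  drop(outer(x, 0:object$degree, "^") %*% object$coefficients)
}

#' Fit trends for a table of profiles
#'
#' Applies [select_trend()] to every (region, group) combination of a
#' profile table, for one response column.
#'
#' @param profiles Data frame with columns \code{region_id, group,
#'   midpoint_m} and the response.
#' @param response Name of the response column (\code{"density"} or
#'   \code{"mean_ssi"}).
#' @param alpha Term-dropping significance level.
#' @param min_points Combinations with fewer finite points are skipped.
#' @return Data frame with one row per fitted combination: \code{region_id,
#'   group, response, n_points, degree, degree_label, r_squared, p_highest,
#'   significance_label} and the fitted objects in the \code{"fits"}
#'   attribute.
#' @export
fit_trend_table <- function(profiles, response, alpha = 0.05,
                            min_points = 3) {
  stopifnot(response %in% names(profiles))
  combos <- unique(profiles[c("region_id", "group")])
  fits <- list()
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    sel <- profiles$region_id == combos$region_id[i] &
      profiles$group == combos$group[i]
    x <- profiles$midpoint_m[sel]
    y <- profiles[[response]][sel]
    if (sum(is.finite(x) & is.finite(y)) < max(3, min_points)) next
    fit <- select_trend(x, y, alpha = alpha)
    key <- paste(combos$region_id[i], combos$group[i], response, sep = "|")
    fits[[key]] <- fit
    rows[[key]] <- data.frame(
      region_id = combos$region_id[i],
      group = combos$group[i],
      response = response,
      n_points = fit$n_points,
      degree = fit$degree,
      degree_label = fit$degree_label,
      r_squared = fit$r_squared,
      p_highest = fit$p_highest,
      significance_label = fit$significance_label,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(region_id = character(0), group = character(0),
                      response = character(0), n_points = integer(0),
                      degree = integer(0), degree_label = character(0),
                      r_squared = numeric(0), p_highest = numeric(0),
                      significance_label = character(0))
  }
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
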