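# Statistical utilities used downstream of the metrics tables:
# normality-gated correlation choice, Benjamini-Yekutieli adjustment,
# Bonferroni-corrected t-tests, and maximum-likelihood power-transform
# selection. Mixed-model fitting is deliberately out of scope: the package
# exports tidy tables for those fits rather than re-implementing them.

shapiro_gate_p <- function(x) {
  # shapiro.test accepts 3..5000 points; longer vectors are gated on a
  # deterministic evenly spaced subsample
  n <- length(x)
  if (n > 5000L) x <- x[round(seq(1L, n, length.out = 5000L))]
  shapiro.test(x)$p.value
}

#' Normality-gated correlation
#'
#' Runs a Shapiro-Wilk test on each variable (after pairwise removal of
#' missing values); Pearson's r is used only when both pass at
#' `alpha_norm`, otherwise Spearman's rank correlation. Pearson p-values
#' come from the t approximation; Spearman from the large-sample t
#' approximation unless `exact = TRUE` (permutation-exact, sensible only
#' for n <= 10).
#'
#' @param x,y Numeric vectors of equal length (n >= 3 after pairwise
#'   missing removal).
#' @param alpha_norm Normality-gate significance level (default 0.05);
#'   Pearson requires both variables to pass.
#' @param exact Use the exact Spearman null distribution for tiny n.
#' @return A one-row data frame: `method`, `estimate`, `p_raw`, `n`,
#'   `shapiro_x`, `shapiro_y`.
#' @export
choose_and_correlate <- function(x, y, alpha_norm = 0.05, exact = FALSE) {
  if (length(x) != length(y)) {
    pl_stop("x and y must have equal length", "prelever_contract_error")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    pl_stop("need at least 3 complete pairs", "prelever_contract_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    pl_stop("constant vector: correlation undefined",
            "prelever_degenerate_input_error")
  }
  px <- shapiro_gate_p(x)
  py <- shapiro_gate_p(y)
  if (px >= alpha_norm && py >= alpha_norm) {
    ct <- cor.test(x, y, method = "pearson")
    method <- "Pearson"
  } else {
    ct <- suppressWarnings(
      cor.test(x, y, method = "spearman", exact = exact)
    )
    method <- "Spearman"
  }
  data.frame(method = method, estimate = unname(ct$estimate),
             p_raw = ct$p.value, n = n, shapiro_x = px, shapiro_y = py,
             stringsAsFactors = FALSE)
}

#' Benjamini-Yekutieli p-value adjustment
#'
#' FDR control valid under arbitrary dependence: the step-up procedure
#' with the harmonic penalty C(m) = sum_{k<=m} 1/k.
#'
#' @param p Vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
by_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    pl_stop("p-values must lie in [0, 1]", "prelever_domain_error")
  }
  p.adjust(p, method = "BY")
}

#' Pairwise t-tests with Bonferroni correction
#'
#' @param groups Named list of numeric vectors (each n >= 2).
#' @param comparisons List of length-2 character vectors naming the group
#'   pairs to compare; default all pairs.
#' @param paired Paired t-tests (groups must be length-matched).
#' @param var_equal Assume equal variances (classical Student test,
#'   default TRUE); FALSE gives Welch.
#' @return Data frame: `group1`, `group2`, `t`, `df`, `p_raw`, `p_adj`
#'   (Bonferroni over the comparisons run).
#' @export
bonferroni_ttests <- function(groups, comparisons = NULL, paired = FALSE,
                              var_equal = TRUE) {
  if (is.null(comparisons)) {
    comparisons <- utils::combn(names(groups), 2, simplify = FALSE)
  }
  rows <- lapply(comparisons, function(cmp) {
    a <- groups[[cmp[1]]]
    b <- groups[[cmp[2]]]
    if (length(a) < 2L || length(b) < 2L) {
      pl_stop("each group needs n >= 2", "prelever_contract_error")
    }
    if (paired && length(a) != length(b)) {
      pl_stop("paired comparison with mismatched lengths",
              "prelever_contract_error")
    }
    tt <- t.test(a, b, paired = paired, var.equal = var_equal)
    data.frame(group1 = cmp[1], group2 = cmp[2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p_raw * length(comparisons))
  out
}

#' Power-transform specification
#'
#' @param family `"BoxCox"` (strictly positive data) or `"YeoJohnson"`.
#' @param lambda Transform exponent.
#' @return A `transform_spec` list.
#' @export
transform_spec <- function(family = c("BoxCox", "YeoJohnson"), lambda) {
  family <- match.arg(family)
  stopifnot(is_scalar_number(lambda))
  structure(list(family = family, lambda = lambda),
            class = "transform_spec")
}

bc_loglik <- function(y, lambda) {
  z <- if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
  n <- length(y)
  v <- mean((z - mean(z))^2)
  -n / 2 * log(v) + (lambda - 1) * sum(log(y))
}

yj_transform <- function(y, lambda) {
  out <- numeric(length(y))
  pos <- y >= 0
  if (abs(lambda) < 1e-12) {
    out[pos] <- log1p(y[pos])
  } else {
    out[pos] <- ((y[pos] + 1)^lambda - 1) / lambda
  }
  l2 <- 2 - lambda
  if (abs(l2) < 1e-12) {
    out[!pos] <- -log1p(-y[!pos])
  } else {
    out[!pos] <- -((1 - y[!pos])^l2 - 1) / l2
  }
  out
}

yj_loglik <- function(y, lambda) {
  z <- yj_transform(y, lambda)
  n <- length(y)
  v <- mean((z - mean(z))^2)
  -n / 2 * log(v) + (lambda - 1) * sum(sign(y) * log1p(abs(y)))
}

golden_section <- function(f, lo, hi, tol = 1e-6) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo
  b <- hi
  c <- b - gr * (b - a)
  d <- a + gr * (b - a)
  fc <- f(c)
  fd <- f(d)
  while (b - a > tol) {
    if (fc > fd) {
      b <- d; d <- c; fd <- fc
      c <- b - gr * (b - a); fc <- f(c)
    } else {
      a <- c; c <- d; fc <- fd
      d <- a + gr * (b - a); fd <- f(d)
    }
  }
  (a + b) / 2
}

#' Select the maximum-likelihood power-transform lambda
#'
#' Maximizes the profile log-likelihood of the chosen family over a grid
#' on \[-2, 2\] with step 0.01, then refines around the best grid point by
#' golden-section search.
#'
#' @param y Numeric data vector (strictly positive for Box-Cox).
#' @param family `"BoxCox"` or `"YeoJohnson"`.
#' @return A [transform_spec()] with the fitted lambda.
#' @export
fit_power_transform <- function(y, family = c("BoxCox", "YeoJohnson")) {
  family <- match.arg(family)
  y <- y[is.finite(y)]
  if (length(y) < 3L) {
    pl_stop("need at least 3 finite values", "prelever_contract_error")
  }
  if (family == "BoxCox" && any(y <= 0)) {
    pl_stop("Box-Cox requires strictly positive data",
            "prelever_domain_error")
  }
  ll <- if (family == "BoxCox") function(l) bc_loglik(y, l)
        else function(l) yj_loglik(y, l)
  grid <- seq(-2, 2, by = 0.01)
  vals <- vapply(grid, ll, numeric(1))
  best <- grid[which.max(vals)]
  lo <- max(-2, best - 0.01)
  hi <- min(2, best + 0.01)
  transform_spec(family, golden_section(ll, lo, hi))
}

#' Apply a power transform
#'
#' Box-Cox: (y^lambda - 1)/lambda, log(y) at lambda = 0 (y > 0).
#' Yeo-Johnson: the standard four-branch definition valid on all reals.
#'
#' @param y Numeric vector.
#' @param spec A [transform_spec()].
#' @return Transformed vector.
#' @export
apply_power_transform <- function(y, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  l <- spec$lambda
  if (spec$family == "BoxCox") {
    if (any(y[is.finite(y)] <= 0)) {
      pl_stop("Box-Cox requires strictly positive data",
              "prelever_domain_error")
    }
    if (abs(l) < 1e-12) log(y) else (y^l - 1) / l
  } else {
    yj_transform(y, l)
  }
}

#' Invert a power transform
#'
#' @param z Transformed values.
#' @param spec The [transform_spec()] used forward.
#' @return Original-scale values.
#' @export
inverse_power_transform <- function(z, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  l <- spec$lambda
  if (spec$family == "BoxCox") {
    if (abs(l) < 1e-12) exp(z) else (l * z + 1)^(1 / l)
  } else {
    out <- numeric(length(z))
    pos <- z >= 0
    if (abs(l) < 1e-12) {
      out[pos] <- expm1(z[pos])
    } else {
      out[pos] <- (l * z[pos] + 1)^(1 / l) - 1
    }
    l2 <- 2 - l
    if (abs(l2) < 1e-12) {
      out[!pos] <- -expm1(-z[!pos])
    } else {
      out[!pos] <- 1 - (1 - l2 * z[!pos])^(1 / l2)
    }
    out
  }
}
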