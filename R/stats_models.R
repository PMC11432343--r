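#' Response transformations
#'
#' The modelling ladder optionally transforms the response to meet residual
#' normality/homoscedasticity: square root, cube root, or a general power
#' (a negative power such as -3 is also used in practice). Each
#' transformation carries its inverse for back-reporting.
#'
#' @param name one of \code{"identity"}, \code{"sqrt"}, \code{"cbrt"},
#'   \code{"power"}.
#' @param p exponent, required for \code{"power"}.
#' @return object of class \code{transformation} with \code{fun} and
#'   \code{inverse}.
#' @export
transformation <- function(name = c("identity", "sqrt", "cbrt", "power"),
                           p = NULL) {
  name <- match.arg(name)
  tr <- switch(name,
    identity = list(fun = identity, inverse = identity),
    sqrt = list(
      fun = function(y) {
        bad <- which(y < 0)
        if (length(bad) > 0)
          stop("sqrt transform of negative values at indices: ",
               paste(bad, collapse = ", "))
        sqrt(y)
      },
      inverse = function(z) z^2),
    cbrt = list(fun = function(y) sign(y) * abs(y)^(1 / 3),
                inverse = function(z) z^3),
    power = {
      if (is.null(p)) stop("power transformation requires an exponent p")
      if (p == 0) stop("power exponent must be non-zero")
      list(fun = function(y) {
        bad <- which(y == 0)
        if (p < 0 && length(bad) > 0)
          stop("negative power of zero at indices: ",
               paste(bad, collapse = ", "))
        y^p
      },
      inverse = function(z) z^(1 / p))
    })
  structure(c(tr, list(name = name, p = p)), class = "transformation")
}

#' Apply a response transformation
#'
#' @param y numeric response vector.
#' @param t a \code{transformation} object or its name.
#' @param p exponent when \code{t} is \code{"power"}.
#' @return transformed vector; errors list domain-violating indices.
#' @export
apply_transformation <- function(y, t = "identity", p = NULL) {
  if (!inherits(t, "transformation")) t <- transformation(t, p)
  t$fun(y)
}

#' Goldfeld-Quandt test for heteroscedasticity
#'
#' Orders the observations by an explanatory variable, splits them in half,
#' refits the model on each half and compares residual variances with an F
#' test (two-sided: either half may be the more variable one).
#'
#' @param formula model formula.
#' @param data data frame.
#' @param order_by name of the ordering variable (default: the model's
#'   fitted values).
#' @return list with \code{statistic} (F), \code{df}, \code{p_value}.
#' @export
goldfeld_quandt <- function(formula, data, order_by = NULL) {
  if (is.null(order_by)) {
    ord <- order(stats::fitted(stats::lm(formula, data = data)))
  } else {
    ord <- order(data[[order_by]])
  }
  data <- data[ord, , drop = FALSE]
  n <- nrow(data)
  half <- floor(n / 2)
  fit1 <- stats::lm(formula, data = data[seq_len(half), , drop = FALSE])
  fit2 <- stats::lm(formula, data = data[(n - half + 1):n, , drop = FALSE])
  df1 <- fit1$df.residual; df2 <- fit2$df.residual
  if (df1 < 1 || df2 < 1) stop("too few observations for the split fits")
  s1 <- sum(stats::residuals(fit1)^2) / df1
  s2 <- sum(stats::residuals(fit2)^2) / df2
  f <- s2 / s1
  # two-sided: double the smaller tail
  p <- 2 * min(stats::pf(f, df2, df1), 1 - stats::pf(f, df2, df1))
  list(statistic = f, df = c(df2, df1), p_value = min(p, 1))
}

#' Heteroscedasticity-consistent covariance for a linear model
#'
#' Sandwich estimator \eqn{(X'X)^{-1} X' \Omega X (X'X)^{-1}} with
#' \eqn{\Omega = diag(w_i e_i^2)}: HC0 (\eqn{w_i = 1}), HC1
#' (\eqn{w_i = n/(n-k)}), or HC3 (\eqn{w_i = 1/(1-h_i)^2}).
#'
#' @param fit an \code{lm} fit.
#' @param type \code{"HC3"} (default), \code{"HC1"} or \code{"HC0"}.
#' @return coefficient covariance matrix.
#' @export
hc_vcov <- function(fit, type = c("HC3", "HC1", "HC0")) {
  type <- match.arg(type)
  X <- stats::model.matrix(fit)
  e <- stats::residuals(fit)
  n <- nrow(X); k <- ncol(X)
  w <- switch(type,
              HC0 = rep(1, n),
              HC1 = rep(n / (n - k), n),
              HC3 = 1 / (1 - stats::hatvalues(fit))^2)
  bread <- solve(crossprod(X))
  meat <- t(X) %*% (X * (w * e^2)) # X' diag(w e^2) X
  bread %*% meat %*% bread
}

coef_table_lm <- function(fit, robust = FALSE, hc_type = "HC3") {
  est <- stats::coef(fit)
  if (robust) {
    V <- hc_vcov(fit, hc_type)
    se <- sqrt(diag(V))
  } else {
    se <- sqrt(diag(stats::vcov(fit)))
  }
  tval <- est / se
  p <- 2 * stats::pt(-abs(tval), df = fit$df.residual)
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             t_value = unname(tval), p_value = unname(p),
             stringsAsFactors = FALSE)
}

coef_table_lmer <- function(fit) {
  sm <- summary(fit)$coefficients
  tval <- sm[, "t value"]
  # normal approximation on the t ratio (no Satterthwaite df available)
  data.frame(term = rownames(sm), estimate = unname(sm[, "Estimate"]),
             se = unname(sm[, "Std. Error"]), t_value = unname(tval),
             p_value = unname(2 * stats::pnorm(-abs(tval))),
             stringsAsFactors = FALSE)
}

#' Fit the linear / mixed model selection ladder
#'
#' Fits a simple linear model and, when random-intercept terms are given, a
#' linear mixed model with the same fixed effects. The mixed model is kept
#' iff its AIC is lower than the simple model's \emph{and} the fit is not
#' singular; otherwise the simple model is used. Residuals of the selected
#' model are tested for normality (Shapiro-Wilk) and heteroscedasticity
#' (Goldfeld-Quandt); when heteroscedasticity is detected on a simple model
#' fit, heteroscedasticity-robust (HC3) standard errors are reported.
#'
#' Models are compared by maximum likelihood (the mixed model is fitted with
#' \code{REML = FALSE}) so the AICs are commensurable.
#'
#' @param data per-video metrics table (one row per video).
#' @param response name of the response column.
#' @param fixed right-hand-side formula of fixed effects, e.g.
#'   \code{~ species * flower_cover_pct}.
#' @param random character vector of grouping variables for random
#'   intercepts (e.g. \code{c("wind", "temperature")}), or \code{NULL} for
#'   no mixed alternative.
#' @param trans a \code{transformation} (or its name) applied to the
#'   response before fitting.
#' @param p exponent when \code{trans = "power"}.
#' @param alpha significance level for both residual diagnostics
#'   (default 0.05).
#' @return object of class \code{fit_report}: coefficient table,
#'   \code{aic_simple}, \code{aic_mixed}, \code{singular_fit},
#'   \code{selected} ("simple"/"mixed"), diagnostic p-values,
#'   \code{robust_se} flag, the selection log, and the fitted model.
#' @export
fit_ladder <- function(data, response, fixed, random = NULL,
                       trans = "identity", p = NULL, alpha = 0.05) {
  if (!inherits(trans, "transformation")) trans <- transformation(trans, p)
  if (!response %in% names(data)) stop("response column not found: ", response)
  fixed_terms <- attr(stats::terms(fixed), "term.labels")
  vars <- all.vars(fixed)
  for (v in vars) {
    x <- data[[v]]
    if (length(unique(x)) < 2)
      stop(sprintf("degenerate design: '%s' is constant", v))
  }
  d <- data
  d$.y <- trans$fun(d[[response]])
  d <- d[stats::complete.cases(d[c(".y", vars, random)]), , drop = FALSE]

  f_simple <- stats::as.formula(paste(".y ~", paste(fixed_terms, collapse = " + ")))
  fit_simple <- stats::lm(f_simple, data = d)
  aic_simple <- stats::AIC(fit_simple)

  log_lines <- sprintf("simple lm: AIC = %.3f", aic_simple)
  aic_mixed <- NA_real_
  singular <- NA
  selected <- "simple"
  fit_mixed <- NULL
  if (!is.null(random) && length(random) > 0) {
    rterms <- paste(sprintf("(1 | %s)", random), collapse = " + ")
    f_mixed <- stats::as.formula(
      paste(".y ~", paste(fixed_terms, collapse = " + "), "+", rterms))
    fit_mixed <- lme4::lmer(f_mixed, data = d, REML = FALSE,
                            control = lme4::lmerControl(
                              check.conv.singular = "ignore"))
    aic_mixed <- stats::AIC(fit_mixed)
    singular <- lme4::isSingular(fit_mixed)
    log_lines <- c(log_lines,
                   sprintf("mixed lmer: AIC = %.3f, singular = %s",
                           aic_mixed, singular))
    if (!singular && aic_mixed < aic_simple) selected <- "mixed"
    log_lines <- c(log_lines, sprintf(
      "selected %s model (mixed kept iff AIC lower and fit non-singular)",
      selected))
  } else {
    log_lines <- c(log_lines, "no random terms given; simple model used")
  }

  fit_sel <- if (selected == "mixed") fit_mixed else fit_simple
  resid_sel <- stats::residuals(fit_sel)
  norm_p <- tryCatch(stats::shapiro.test(resid_sel)$p.value,
                     error = function(e) NA_real_)
  gq <- tryCatch(goldfeld_quandt(f_simple, d), error = function(e) NULL)
  het_p <- if (is.null(gq)) NA_real_ else gq$p_value
  heteroscedastic <- !is.na(het_p) && het_p < alpha
  robust <- heteroscedastic && selected == "simple"
  log_lines <- c(log_lines,
                 sprintf("Shapiro-Wilk p = %.4g; Goldfeld-Quandt p = %.4g%s",
                         norm_p, het_p,
                         if (robust) "; HC3 robust SEs reported" else ""))

  coefs <- if (selected == "mixed") coef_table_lmer(fit_mixed)
           else coef_table_lm(fit_simple, robust = robust)
  structure(list(coefficients = coefs,
                 aic_simple = aic_simple, aic_mixed = aic_mixed,
                 singular_fit = singular, selected = selected,
                 normality_p = norm_p, heteroscedasticity_p = het_p,
                 robust_se = robust, transformation = trans$name,
                 selection_log = log_lines, model = fit_sel,
                 n = nrow(d)),
            class = "fit_report")
}

signif_code <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report> %s model selected (n = %d)\n", x$selected, x$n))
  cat(sprintf("  AIC simple %.2f%s; transformation: %s\n",
              x$aic_simple,
              if (!is.na(x$aic_mixed))
                sprintf(", mixed %.2f (singular: %s)", x$aic_mixed,
                        x$singular_fit) else "",
              x$transformation))
  cat(sprintf("  diagnostics: normality p = %.3g, heteroscedasticity p = %.3g%s\n",
              x$normality_p, x$heteroscedasticity_p,
              if (x$robust_se) " [robust SEs]" else ""))
  tab <- x$coefficients
  tab$sig <- signif_code(tab$p_value)
  print(format(tab, digits = 4), row.names = FALSE)
  cat("  Signif. codes: 0 '***' 0.001 '**' 0.01 '*' 0.05\n")
  invisible(x)
}

#' Export a fit report
#'
#' Writes the coefficient table as CSV and the full report (selection log
#' included) as JSON.
#'
#' @param report a \code{fit_report}.
#' @param csv_path,json_path output paths (either may be NULL to skip).
#' @return invisibly, the report.
#' @export
write_fit_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(report$coefficients, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    out <- report[c("coefficients", "aic_simple", "aic_mixed",
                    "singular_fit", "selected", "normality_p",
                    "heteroscedasticity_p", "robust_se", "transformation",
                    "selection_log", "n")]
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(report)
}
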