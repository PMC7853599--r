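#' Final-height prediction model with two-way interactions and type II ANOVA
#'
#' Least-squares model of final height on the temperature-response slope,
#' vigour, elongation duration and allele contrasts at Rht-B1, Rht-D1 and
#' Ppd-D1 (or any user-chosen predictors), including all two-way
#' interactions.  Aliased (singular) terms are dropped and reported by name;
#' each remaining term is tested with type II sums of squares (adjusted for
#' all other terms except interactions containing it).
#'
#' @param data Data frame of genotype-level values; rows with missing
#'   predictors are dropped (complete-case analysis).
#' @param response Name of the response column.
#' @param predictors Character vector of predictor columns.  Character or
#'   factor columns are treated as 0/1 contrasts via factor coding.
#' @param interactions Include all two-way interactions?
#' @return Object of class `height_model`: `fit` (the `lm`), `anova`
#'   (type II table), `r_squared`, `dropped_terms`, `n`.
#' @export
fit_height_model <- function(data, response = "fh",
                             predictors = c("slope", "vigour", "gdd_se",
                                            "rht_b1", "rht_d1", "ppd_d1"),
                             interactions = TRUE) {
  stopifnot(response %in% names(data), all(predictors %in% names(data)))
  df <- data[, c(response, predictors)]
  df <- df[stats::complete.cases(df), ]
  for (p in predictors)
    if (is.character(df[[p]])) df[[p]] <- factor(df[[p]])
  rhs <- if (interactions)
    sprintf("(%s)^2", paste(predictors, collapse = " + "))
  else paste(predictors, collapse = " + ")
  form <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::lm(form, data = df)
  if (nrow(df) <= length(stats::coef(fit)))
    stop("fewer observations than parameters")
  dropped <- character(0)
  while (anyNA(stats::coef(fit))) {
    co <- stats::coef(fit)
    bad <- names(co)[is.na(co)]
    # map aliased columns back to model terms and drop whole terms
    asn <- attr(stats::model.matrix(fit), "assign")
    labs <- attr(stats::terms(fit), "term.labels")
    bad_terms <- unique(labs[asn[match(bad, colnames(stats::model.matrix(fit)))]])
    dropped <- c(dropped, bad_terms)
    form <- stats::update(stats::formula(fit),
                          stats::as.formula(paste(
                            ". ~ . -", paste(bad_terms, collapse = " - "))))
    fit <- stats::lm(form, data = df)
  }
  an <- if (suppressWarnings(summary(fit)$sigma) > 1e-8 * stats::sd(df[[response]])) {
    car::Anova(fit, type = 2)
  } else {
    type2_exact(fit, df)  # saturated fit: build the table from nested RSS
  }
  structure(list(
    fit = fit,
    anova = an,
    r_squared = suppressWarnings(summary(fit)$r.squared),
    dropped_terms = dropped,
    n = nrow(df)
  ), class = "height_model")
}

# Type II sums of squares by explicit nested-model comparisons; each term is
# adjusted for all others except interactions that contain it.  Used when the
# residual variance is (numerically) zero and the F-based path is undefined.
type2_exact <- function(fit, df) {
  tl <- attr(stats::terms(fit), "term.labels")
  resp <- all.vars(stats::formula(fit))[1]
  fit_rss <- function(labels) {
    rhs <- if (length(labels)) paste(labels, collapse = " + ") else "1"
    m <- stats::lm(stats::reformulate(rhs, response = resp), data = df)
    list(rss = sum(stats::residuals(m)^2), rdf = stats::df.residual(m))
  }
  rows <- lapply(tl, function(tm) {
    vars <- strsplit(tm, ":", fixed = TRUE)[[1]]
    contains <- vapply(tl, function(o) {
      ov <- strsplit(o, ":", fixed = TRUE)[[1]]
      all(vars %in% ov)
    }, logical(1))
    base <- setdiff(tl, tl[contains])      # everything not containing tm
    m0 <- fit_rss(base)
    m1 <- fit_rss(c(base, tm))
    data.frame(`Sum Sq` = m0$rss - m1$rss, Df = m0$rdf - m1$rdf,
               `F value` = NA_real_, `Pr(>F)` = NA_real_,
               check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- tl
  out <- rbind(out, Residuals = data.frame(
    `Sum Sq` = sum(stats::residuals(fit)^2), Df = stats::df.residual(fit),
    `F value` = NA_real_, `Pr(>F)` = NA_real_, check.names = FALSE))
  out
}

#' @export
print.height_model <- function(x, ...) {
  cat(sprintf("Final-height model: n = %d, R2 = %.3f\n", x$n, x$r_squared))
  if (length(x$dropped_terms))
    cat("  dropped (singular):", paste(x$dropped_terms, collapse = ", "), "\n")
  print(x$anova)
  invisible(x)
}

#' @export
summary.height_model <- function(object, ...) summary(object$fit, ...)

#' @export
coef.height_model <- function(object, ...) stats::coef(object$fit)

#' @export
predict.height_model <- function(object, newdata = NULL, ...)
  stats::predict(object$fit, newdata = newdata, ...)
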