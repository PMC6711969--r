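# Quasi-Poisson GAM of daily occurrence, with GCV-guided backwards term
# selection, collapse of effectively-linear smooths, and a final-vs-full
# F-ratio test. Basis construction and smoothing-parameter optimization are
# delegated to mgcv (thin-plate regression splines, GCV); the selection
# loop, the GCV bookkeeping used to compare candidate models
# (n * deviance / (n - edf)^2), the smooth-to-linear collapse rule and the
# F-ratio test live here.

#' Model term constructors
#'
#' Build the term list of an occurrence-model specification: 1-d thin-plate
#' smooths, a 2-d isotropic interaction smooth, or plain linear terms.
#'
#' @param var,var1,var2 covariate names in the covariate table.
#' @param k basis dimension (default 10 for 1-d, 30 for 2-d smooths).
#' @return a term object (list with \code{kind}, \code{vars}, \code{k}).
#' @name gam_terms
NULL

#' @rdname gam_terms
#' @export
smooth_term <- function(var, k = 10) {
  structure(list(kind = "smooth", vars = var, k = k), class = "occ_term")
}

#' @rdname gam_terms
#' @export
smooth2_term <- function(var1, var2, k = 30) {
  structure(list(kind = "smooth2", vars = c(var1, var2), k = k),
            class = "occ_term")
}

#' @rdname gam_terms
#' @export
linear_term <- function(var) {
  structure(list(kind = "linear", vars = var, k = NA_integer_),
            class = "occ_term")
}

term_label <- function(tm) {
  switch(tm$kind,
         smooth = sprintf("s(%s)", tm$vars),
         smooth2 = sprintf("s(%s,%s)", tm$vars[1], tm$vars[2]),
         linear = tm$vars)
}

validate_terms <- function(terms, table) {
  if (!length(terms)) return(invisible(TRUE))
  allv <- unlist(lapply(terms, `[[`, "vars"))
  if (anyDuplicated(allv))
    stop("variable appears in two terms: ",
         paste(unique(allv[duplicated(allv)]), collapse = ", "))
  miss <- setdiff(allv, names(table))
  if (length(miss))
    stop("term variable(s) absent from table: ",
         paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Fit the quasi-Poisson occurrence GAM
#'
#' Fits daily unique counts with a log link and quasi-Poisson errors on
#' thin-plate regression splines; smoothing parameters are chosen by GCV.
#' Rows with any missing model variable are dropped listwise (count
#' reported in the fit). The two covariates of a 2-d interaction smooth are
#' standardized to unit variance before basis construction, because an
#' isotropic smooth on, say, degrees Celsius against hours of daylight is
#' otherwise scale-sensitive; the constants are stored in the fit and
#' reapplied at prediction time.
#'
#' The reported GCV score is n * deviance / (n - edf)^2 (edf = total
#' effective degrees of freedom); the dispersion phi is the Pearson
#' statistic over the residual degrees of freedom; deviance explained is
#' 100 * (1 - deviance / null deviance).
#'
#' @param table covariate table (see \code{\link{build_covariate_table}}).
#' @param terms list of \code{\link{gam_terms}} objects (possibly empty:
#'   intercept-only model).
#' @param response response column name; non-negative integer counts.
#' @return object of class \code{occ_gam}: the term list, per-term and
#'   total edf, coefficients, \code{phi}, \code{deviance},
#'   \code{null_deviance}, \code{dev_expl} (percent), \code{gcv}, \code{n},
#'   \code{n_dropped}, fitted values, the standardization constants, and
#'   the underlying \code{mgcv} fit in \code{$fit}.
#' @export
occurrence_gam <- function(table, terms, response = "UDC") {
  if (inherits(terms, "occ_term")) terms <- list(terms)
  validate_terms(terms, table)
  if (!(response %in% names(table))) stop("response column not found: ",
                                          response)
  vars <- unique(unlist(lapply(terms, `[[`, "vars")))
  dat <- table[, c(response, vars), drop = FALSE]
  keep <- complete.cases(dat)
  n_dropped <- sum(!keep)
  dat <- dat[keep, , drop = FALSE]
  y <- dat[[response]]
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8))
    stop("response must be non-negative integer counts")
  n <- nrow(dat)

  std <- list()
  rhs <- character()
  for (tm in terms) {
    if (tm$kind == "smooth") {
      kk <- min(tm$k, length(unique(dat[[tm$vars]])) - 1L)
      if (kk < 3) stop("too few unique values of ", tm$vars, " for a smooth")
      rhs <- c(rhs, sprintf("s(%s, k = %d)", tm$vars, kk))
    } else if (tm$kind == "smooth2") {
      cols <- character(2)
      for (i in 1:2) {
        v <- tm$vars[i]
        mu <- mean(dat[[v]]); sg <- sd(dat[[v]])
        if (!is.finite(sg) || sg == 0) sg <- 1
        col <- paste0(".std_", v)
        dat[[col]] <- (dat[[v]] - mu) / sg
        std[[v]] <- c(center = mu, scale = sg)
        cols[i] <- col
      }
      ncomb <- nrow(unique(dat[, cols]))
      kk <- min(tm$k, ncomb - 1L)
      rhs <- c(rhs, sprintf("s(%s, %s, k = %d)", cols[1], cols[2], kk))
    } else {
      rhs <- c(rhs, tm$vars)
    }
  }
  if (!length(rhs)) rhs <- "1"
  form <- stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
  environment(form) <- environment()
  fit <- mgcv::gam(form, family = stats::quasipoisson(link = "log"),
                   data = dat, method = "GCV.Cp")
  if (any(is.na(coef(fit))))
    stop("rank-deficient fit; collinear terms: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))

  total_edf <- sum(fit$edf)
  dev <- stats::deviance(fit)
  null_dev <- fit$null.deviance
  phi <- sum(residuals(fit, type = "pearson")^2) / (n - total_edf)
  gcv <- n * dev / (n - total_edf)^2

  # per-term edf: smooths by their coefficient blocks, parametric terms 1 each
  edf_by_term <- numeric(length(terms))
  names(edf_by_term) <- vapply(terms, term_label, character(1))
  sm_i <- 0L
  for (i in seq_along(terms)) {
    if (terms[[i]]$kind %in% c("smooth", "smooth2")) {
      sm_i <- sm_i + 1L
      sm <- fit$smooth[[sm_i]]
      edf_by_term[i] <- sum(fit$edf[sm$first.para:sm$last.para])
    } else {
      edf_by_term[i] <- 1
    }
  }

  structure(list(
    terms = terms, response = response,
    edf = edf_by_term, total_edf = total_edf,
    coefficients = coef(fit), phi = phi,
    deviance = dev, null_deviance = null_dev,
    dev_expl = 100 * (1 - dev / null_dev),
    gcv = gcv, n = n, n_dropped = n_dropped,
    fitted = fitted(fit), std = std, data = dat, fit = fit),
    class = "occ_gam")
}

#' @export
print.occ_gam <- function(x, ...) {
  rhs <- if (length(x$terms))
    paste(vapply(x$terms, term_label, character(1)), collapse = " + ")
  else "1"
  cat("Quasi-Poisson occurrence GAM (log link)\n")
  cat("  ", x$response, " ~ ", rhs, "\n", sep = "")
  cat(sprintf("  n = %d (%d incomplete row(s) dropped)\n", x$n, x$n_dropped))
  cat(sprintf("  total edf = %.2f, dispersion phi = %.3f\n",
              x$total_edf, x$phi))
  cat(sprintf("  deviance explained = %.1f%%, GCV = %.4f\n",
              x$dev_expl, x$gcv))
  invisible(x)
}

#' @export
summary.occ_gam <- function(object, ...) {
  structure(list(object = object, mgcv = summary(object$fit)),
            class = "summary.occ_gam")
}

#' @export
print.summary.occ_gam <- function(x, ...) {
  print(x$object)
  cat("\nPer-term effective degrees of freedom:\n")
  print(round(x$object$edf, 2))
  lin <- vapply(x$object$terms, function(t) t$kind == "linear", logical(1))
  if (any(lin)) {
    cat("\nLinear coefficients:\n")
    vars <- vapply(x$object$terms[lin], `[[`, character(1), "vars")
    print(x$object$coefficients[vars])
  }
  invisible(x)
}

#' @export
coef.occ_gam <- function(object, ...) object$coefficients

#' @export
fitted.occ_gam <- function(object, ...) object$fitted

#' @export
residuals.occ_gam <- function(object, type = "pearson", ...) {
  residuals(object$fit, type = type, ...)
}

#' Predict from an occurrence GAM
#'
#' @param object \code{occ_gam} fit.
#' @param newdata data.frame with the model covariates on their original
#'   scales (standardization of interaction covariates is reapplied
#'   internally); default: the fitting data.
#' @param type \code{"response"} (expected count) or \code{"link"} (log
#'   scale).
#' @param ... passed to \code{mgcv}'s predict method.
#' @return numeric vector of predictions.
#' @export
predict.occ_gam <- function(object, newdata = NULL,
                            type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  for (v in names(object$std)) {
    cs <- object$std[[v]]
    newdata[[paste0(".std_", v)]] <- (newdata[[v]] - cs["center"]) / cs["scale"]
  }
  as.numeric(predict(object$fit, newdata = newdata, type = type, ...))
}

#' @export
plot.occ_gam <- function(x, ...) {
  if (length(x$fit$smooth)) plot(x$fit, pages = 1, ...)
  else plot(x$data[[x$response]], fitted(x), xlab = "observed",
            ylab = "fitted", ...)
  invisible(x)
}

#' Backwards term selection by GCV
#'
#' Stepwise backwards elimination from the full model: at each step every
#' remaining term is tentatively removed and the candidate models' GCV
#' scores (n * deviance / (n - edf)^2) compared; the best removal is
#' accepted if it lowers the GCV, and the process repeats. Whenever no
#' removal improves the score, any 1-d smooth whose effective degrees of
#' freedom have fallen below \code{edf_linear_threshold} is refit as a plain
#' linear term (a smooth with edf near one is essentially a straight line),
#' after which elimination resumes. The trace records every candidate
#' examined.
#'
#' @param table covariate table.
#' @param full_terms term list of the full model.
#' @param response response column.
#' @param edf_linear_threshold collapse threshold on a 1-d smooth's edf
#'   (default 1.5).
#' @return list: \code{final} and \code{full} (\code{occ_gam} fits) and
#'   \code{trace} (data.frame: step, action, term, gcv, accepted).
#' @export
backwards_select <- function(table, full_terms, response = "UDC",
                             edf_linear_threshold = 1.5) {
  full <- occurrence_gam(table, full_terms, response)
  current <- full
  trace <- data.frame(step = 0L, action = "full", term = "",
                      gcv = full$gcv, accepted = TRUE,
                      stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    step <- step + 1L
    improved <- FALSE
    if (length(current$terms)) {
      cand <- vector("list", length(current$terms))
      for (i in seq_along(current$terms)) {
        cand[[i]] <- occurrence_gam(table, current$terms[-i], response)
        trace <- rbind(trace, data.frame(
          step = step, action = "drop",
          term = term_label(current$terms[[i]]),
          gcv = cand[[i]]$gcv, accepted = FALSE))
      }
      gcvs <- vapply(cand, `[[`, numeric(1), "gcv")
      best <- which.min(gcvs)
      if (gcvs[best] < current$gcv) {
        trace$accepted[nrow(trace) - length(cand) + best] <- TRUE
        current <- cand[[best]]
        improved <- TRUE
      }
    }
    if (!improved) {
      coll <- which(vapply(current$terms, function(t) t$kind == "smooth",
                           logical(1)) &
                      current$edf < edf_linear_threshold)
      if (length(coll)) {
        new_terms <- current$terms
        for (i in coll) new_terms[[i]] <- linear_term(new_terms[[i]]$vars)
        current <- occurrence_gam(table, new_terms, response)
        trace <- rbind(trace, data.frame(
          step = step, action = "collapse",
          term = paste(vapply(current$terms[coll], term_label, character(1)),
                       collapse = "+"),
          gcv = current$gcv, accepted = TRUE))
      } else break
    }
  }
  if (!length(current$terms))
    warning("all terms eliminated; returning intercept-only model")
  list(final = current, full = full, trace = trace)
}

#' F-ratio comparison of a selected model against the full model
#'
#' Tests whether the selected (final) model explains significantly less of
#' the residual deviance than the full model it was reduced from:
#' F = [(D_final - D_full) / (edf_full - edf_final)] / phi_full, referred
#' to an F distribution on (edf_full - edf_final, n - edf_full) degrees of
#' freedom (fractional dfs are used as-is). A significant result indicates
#' the selection under-pruned... i.e. the final model is under-parameterized
#' relative to the data.
#'
#' @param final,full \code{occ_gam} fits on the same rows; the final model's
#'   terms must be a (possibly linearized) subset of the full model's.
#' @return object of class \code{occ_ftest}: \code{F}, \code{df1},
#'   \code{df2}, \code{p_value}; for identical models a degenerate result
#'   with \code{note = "identical models"}.
#' @export
f_ratio_test <- function(final, full) {
  if (final$n != full$n)
    stop("models fit to different numbers of rows")
  fin_vars <- lapply(final$terms, `[[`, "vars")
  full_vars <- lapply(full$terms, `[[`, "vars")
  nested <- all(vapply(fin_vars, function(v)
    any(vapply(full_vars, function(w) all(v %in% w), logical(1))),
    logical(1)))
  if (!nested) stop("final model terms are not a subset of the full model's")
  df1 <- full$total_edf - final$total_edf
  if (abs(df1) < 1e-6)
    return(structure(list(F = NA_real_, df1 = 0, df2 = final$n -
                            full$total_edf, p_value = NA_real_,
                          note = "identical models"), class = "occ_ftest"))
  if (df1 < 0) stop("full model has fewer edf than final: not nested")
  df2 <- full$n - full$total_edf
  Fstat <- ((final$deviance - full$deviance) / df1) / full$phi
  Fstat <- max(Fstat, 0)
  structure(list(F = Fstat, df1 = df1, df2 = df2,
                 p_value = pf(Fstat, df1, df2, lower.tail = FALSE),
                 note = NULL), class = "occ_ftest")
}

#' @export
print.occ_ftest <- function(x, ...) {
  if (!is.null(x$note)) cat("F-ratio test:", x$note, "\n")
  else cat(sprintf("F-ratio test: F(%.2f, %.2f) = %.3f, p = %.4f\n",
                   x$df1, x$df2, x$F, x$p_value))
  invisible(x)
}

#' Predicted response surface over the 2-d interaction
#'
#' Evaluates the fitted model on a regular grid over the two covariates of
#' its 2-d interaction smooth, all other covariates held at their medians.
#' Grid nodes outside the convex hull of the observed covariate pairs are
#' flagged as extrapolated.
#'
#' @param fit \code{occ_gam} containing a 2-d smooth.
#' @param n grid nodes per axis (default 40).
#' @return data.frame with the two covariates, \code{link},
#'   \code{response}, and \code{extrapolated} (logical).
#' @export
interaction_surface <- function(fit, n = 40) {
  is2 <- vapply(fit$terms, function(t) t$kind == "smooth2", logical(1))
  if (!any(is2)) stop("fit contains no 2-d interaction smooth")
  vars <- fit$terms[[which(is2)[1]]]$vars
  dat <- fit$data
  g <- expand.grid(
    v1 = seq(min(dat[[vars[1]]]), max(dat[[vars[1]]]), length.out = n),
    v2 = seq(min(dat[[vars[2]]]), max(dat[[vars[2]]]), length.out = n))
  names(g) <- vars
  others <- setdiff(unique(unlist(lapply(fit$terms, `[[`, "vars"))), vars)
  for (v in others) g[[v]] <- median(dat[[v]])
  g$link <- predict(fit, g, type = "link")
  g$response <- predict(fit, g, type = "response")
  pts <- as.matrix(dat[, vars])
  hull <- pts[chull(pts), , drop = FALSE]
  g$extrapolated <- !mgcv::in.out(rbind(hull, hull[1, ]),
                                  as.matrix(g[, vars]))
  g
}
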