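#' Factor-smooth model specification
#'
#' Describes the penalized regression of edge strength on the bilingualism
#' score: one cubic B-spline smooth of the score per directed connection
#' (a factor-smooth interaction), a parametric factor term for connection
#' (required for factor interactions), parametric covariates, and
#' ridge-penalized random intercepts.  The basis dimension defaults to
#' `k = 15` (14 basis functions after the sum-to-zero identifiability
#' constraint) with a fixed smoothing penalty of 0.02 on second-order
#' coefficient differences; no data-driven smoothness selection is
#' performed.
#'
#' @param response response column name.
#' @param smooth_var continuous predictor of the smooths.
#' @param by factor whose levels each get their own smooth.
#' @param k basis dimension before the constraint.
#' @param penalty fixed smoothing parameter multiplying the
#'   second-difference penalty.
#' @param covariates parametric covariate columns; factors are
#'   treatment-coded, ordinal covariates enter as integer codes.
#' @param random columns giving ridge-penalized random-intercept groups.
#' @param ridge fixed ridge penalty for the random-intercept blocks.
#' @return list of class `fs_model_spec`.
#' @export
fs_model_spec <- function(response = "gc", smooth_var = "lsbq",
                          by = "connection", k = 15L, penalty = 0.02,
                          covariates = c("age", "l2_aoa", "education",
                                         "gender"),
                          random = c("participant_id", "task_order"),
                          ridge = 1) {
  if (k < 3) stop("k must be >= 3")
  if (penalty < 0) stop("penalty must be >= 0")
  structure(as.list(environment()), class = "fs_model_spec")
}

#' Build the penalized design for a factor-smooth model
#'
#' Constructs the model matrix and block-diagonal penalty: an intercept,
#' the treatment-coded `by` factor, parametric covariates, one
#' sum-to-zero-constrained B-spline block per `by` level (all sharing the
#' same basis and penalty), and indicator blocks for each random-intercept
#' group.
#'
#' @param edge_table long-form data (e.g. from [to_edge_list()]).
#' @param spec an [fs_model_spec()].
#' @return object of class `fs_design` with elements `X`, `S`, `y`,
#'   `blocks` (per-block column indices and types), the basis objects
#'   needed to evaluate smooths on new data, and the originating data.
#' @export
build_design <- function(edge_table, spec = fs_model_spec()) {
  need <- c(spec$response, spec$smooth_var, spec$by, spec$covariates,
            spec$random)
  miss <- setdiff(need, names(edge_table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  bad <- which(rowSums(is.na(edge_table[, need, drop = FALSE])) > 0)
  if (length(bad))
    stop("missing covariate values in rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  n <- nrow(edge_table)
  y <- edge_table[[spec$response]]
  x <- edge_table[[spec$smooth_var]]
  fby <- factor(edge_table[[spec$by]])

  # parametric part
  Xp <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  blocks <- list(list(name = "(Intercept)", type = "parametric",
                      cols = 1L))
  add_block <- function(X, M, name, type, penalty_diag = NULL,
                        penalty_mat = NULL) {
    cols <- ncol(X) + seq_len(ncol(M))
    blocks[[length(blocks) + 1L]] <<-
      list(name = name, type = type, cols = cols,
           penalty_diag = penalty_diag, penalty_mat = penalty_mat)
    cbind(X, M)
  }
  if (nlevels(fby) > 1) {
    Mby <- stats::model.matrix(~fby)[, -1, drop = FALSE]
    colnames(Mby) <- paste0(spec$by, levels(fby)[-1])
    Xp <- add_block(Xp, Mby, spec$by, "parametric")
  }
  for (cv in spec$covariates) {
    v <- edge_table[[cv]]
    M <- if (is.numeric(v)) matrix(v, ncol = 1, dimnames = list(NULL, cv))
    else {
      fm <- stats::model.matrix(~factor(v))[, -1, drop = FALSE]
      colnames(fm) <- paste0(cv, levels(factor(v))[-1])
      fm
    }
    Xp <- add_block(Xp, M, cv, "parametric")
  }

  # smooth blocks: shared constrained B-spline basis
  B0 <- splines::bs(x, df = spec$k, intercept = TRUE)
  C <- matrix(colSums(B0), nrow = 1)
  Z <- qr.Q(qr(t(C)), complete = TRUE)[, -1, drop = FALSE]  # k x (k-1)
  Bc <- B0 %*% Z
  D <- diff(diag(spec$k), differences = 2)
  S0 <- t(Z) %*% crossprod(D) %*% Z                          # (k-1)^2
  X <- Xp
  for (lv in levels(fby)) {
    M <- Bc * (fby == lv)
    colnames(M) <- paste0("s(", lv, ").", seq_len(ncol(M)))
    X <- add_block(X, M, lv, "smooth", penalty_mat = spec$penalty * S0)
  }

  # random-intercept blocks
  for (rv in spec$random) {
    fr <- factor(edge_table[[rv]])
    M <- stats::model.matrix(~ 0 + fr)
    colnames(M) <- paste0(rv, levels(fr))
    X <- add_block(X, M, rv, "random", penalty_diag = spec$ridge)
  }

  P <- ncol(X)
  S <- matrix(0, P, P)
  for (b in blocks) {
    if (!is.null(b$penalty_mat)) S[b$cols, b$cols] <- b$penalty_mat
    if (!is.null(b$penalty_diag))
      S[b$cols, b$cols] <- diag(b$penalty_diag, length(b$cols))
  }
  structure(list(X = X, S = S, y = y, blocks = blocks, basis = B0, Z = Z,
                 S0 = S0, spec = spec, by_levels = levels(fby), x = x,
                 n = n),
            class = "fs_design")
}

#' @export
print.fs_design <- function(x, ...) {
  cat("fs_design:", x$n, "rows,", ncol(x$X), "columns,",
      length(x$by_levels), "factor-smooth level(s) of",
      ncol(x$Z), "basis function(s) each\n")
  invisible(x)
}

#' Fit the penalized factor-smooth model
#'
#' Minimizes `||sqrt(w)(y - X b)||^2 + b' S b` for the fixed penalty `S`
#' of the design.  Effective degrees of freedom are the block-wise traces
#' of the influence matrix; the coefficient covariance used for smooth
#' tests is the exact sampling covariance of the penalized estimator.
#'
#' @param design an [build_design()] result.
#' @param y optional replacement response (defaults to the design's).
#' @param weights optional observation weights.
#' @return object of class `fs_fit`: coefficients, fitted values,
#'   residual variance `sigma2`, per-block `edf`, log-likelihood, `aic`,
#'   and the matrices needed by [test_smooths()] and [fs_refit()].
#' @export
fit_penalized <- function(design, y = design$y, weights = NULL) {
  X <- design$X; S <- design$S
  n <- nrow(X)
  if (is.null(weights)) {
    XtX <- crossprod(X)
    Xty <- crossprod(X, y)
  } else {
    stopifnot(length(weights) == n, all(weights > 0))
    XtX <- crossprod(X, X * weights)
    Xty <- crossprod(X, y * weights)
  }
  A <- XtX + S
  R <- tryCatch(chol(A), error = function(e)
    stop("singular penalized system: ", conditionMessage(e)))
  Ainv <- chol2inv(R)
  beta <- drop(Ainv %*% Xty)
  names(beta) <- colnames(X)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  rss <- if (is.null(weights)) sum(res^2) else sum(weights * res^2)
  H1 <- Ainv %*% XtX                     # (X'WX + S)^-1 X'WX
  H_diag <- diag(H1)
  edf <- vapply(design$blocks, function(b) sum(H_diag[b$cols]), 0)
  names(edf) <- vapply(design$blocks, `[[`, "", "name")
  edf_total <- sum(edf)
  neff <- if (is.null(weights)) n else sum(weights)
  # unbiased scale: E[RSS] = sigma^2 (n - 2 tr(H) + tr(HH'))
  resid_df <- max(1, neff - 2 * edf_total + sum(H1 * t(H1)))
  sigma2 <- rss / resid_df
  M <- H1 %*% Ainv                       # cov(beta) / sigma^2
  ll <- -neff / 2 * (log(2 * pi * rss / neff) + 1)
  aic <- -2 * ll + 2 * (edf_total + 1)
  structure(list(coefficients = beta, fitted = fitted, residuals = res,
                 rss = rss, sigma2 = sigma2, edf = edf,
                 edf_total = edf_total, resid_df = resid_df, loglik = ll,
                 aic = aic, cov_unscaled = M, Ainv = Ainv,
                 design = design, n = n, weights = weights),
            class = "fs_fit")
}

#' @export
print.fs_fit <- function(x, ...) {
  cat("fs_fit:", x$n, "obs,", length(x$coefficients), "coefficients,",
      "total edf", round(x$edf_total, 1), "\n")
  cat("  sigma^2 =", signif(x$sigma2, 4), ", AIC =", round(x$aic, 2), "\n")
  invisible(x)
}

#' Refit an existing design to a new response
#'
#' Reuses the factorized penalized system of a previous fit, so repeated
#' simulation replicates cost one matrix-vector product each.
#'
#' @param fit an [fit_penalized()] result (unweighted).
#' @param y new response vector.
#' @return an `fs_fit`.
#' @export
fs_refit <- function(fit, y) {
  design <- fit$design
  X <- design$X
  beta <- drop(fit$Ainv %*% crossprod(X, y))
  names(beta) <- colnames(X)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  sigma2 <- rss / fit$resid_df
  ll <- -fit$n / 2 * (log(2 * pi * rss / fit$n) + 1)
  out <- fit
  out$coefficients <- beta
  out$fitted <- fitted
  out$residuals <- res
  out$rss <- rss
  out$sigma2 <- sigma2
  out$loglik <- ll
  out$aic <- -2 * ll + 2 * (fit$edf_total + 1)
  out
}

#' Wald tests of every connection smooth
#'
#' For each smooth block the statistic is `b' V^+ b` with `V` the block of
#' the exact (penalized-estimator) coefficient covariance, referred to a
#' chi-square distribution with the block's rank as degrees of freedom;
#' a rank-deficient block covariance falls back to an eigen
#' pseudo-inverse.
#'
#' @param fit an `fs_fit`.
#' @return data frame: `connection`, `edf`, `statistic`, `df`, `p_value`.
#' @export
test_smooths <- function(fit) {
  design <- fit$design
  sm <- Filter(function(b) b$type == "smooth", design$blocks)
  out <- lapply(sm, function(b) {
    bcoef <- fit$coefficients[b$cols]
    V <- fit$cov_unscaled[b$cols, b$cols] * fit$sigma2
    ev <- eigen(V, symmetric = TRUE)
    tol <- max(ev$values) * 1e-10
    pos <- ev$values > tol
    rank <- sum(pos)
    if (rank == 0) return(data.frame(connection = b$name,
                                     edf = fit$edf[[b$name]],
                                     statistic = 0, df = 0, p_value = 1))
    u <- crossprod(ev$vectors[, pos, drop = FALSE], bcoef)
    stat <- sum(u^2 / ev$values[pos])
    data.frame(connection = b$name, edf = unname(fit$edf[b$name]),
               statistic = stat, df = rank,
               p_value = stats::pchisq(stat, rank, lower.tail = FALSE))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Evaluate a fitted connection smooth on new score values
#'
#' @param fit an `fs_fit`.
#' @param connection `by`-level name.
#' @param newx score values (default: fine grid over the observed range).
#' @return data frame with `x` and the centered smooth estimate `s`.
#' @export
evaluate_smooth <- function(fit, connection,
                            newx = seq(min(fit$design$x),
                                       max(fit$design$x),
                                       length.out = 200)) {
  design <- fit$design
  b <- Filter(function(b) b$type == "smooth" && b$name == connection,
              design$blocks)
  if (!length(b)) stop("unknown connection: ", connection)
  b <- b[[1]]
  Bnew <- stats::predict(design$basis, newx) %*% design$Z
  data.frame(x = newx, s = drop(Bnew %*% fit$coefficients[b$cols]))
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjusted p-values; a connection is flagged significant when its
#' adjusted value is at most `q`.
#'
#' @param pvals raw p-values.
#' @param q target false-discovery rate (default 0.05).
#' @return data frame `p_raw`, `p_fdr`, `significant`.
#' @export
fdr_correct <- function(pvals, q = 0.05) {
  if (!length(pvals))
    return(data.frame(p_raw = numeric(0), p_fdr = numeric(0),
                      significant = logical(0)))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvals, method = "BH")
  data.frame(p_raw = pvals, p_fdr = adj, significant = adj <= q)
}

#' Compare nested penalized fits
#'
#' Approximate likelihood-ratio test: the deviance difference scaled by
#' the full model's residual variance is referred to a chi-square with the
#' difference in effective degrees of freedom; an information-criterion
#' comparison (`-2 loglik + 2 edf`) is reported alongside.
#'
#' @param fit_reduced,fit_full `fs_fit` objects on identical responses;
#'   the reduced design's blocks must be a subset of the full design's.
#' @return list: `chisq`, `df`, `p_value`, `aic_reduced`, `aic_full`,
#'   `preferred` (by AIC).
#' @export
compare_models <- function(fit_reduced, fit_full) {
  if (fit_reduced$n != fit_full$n ||
      !isTRUE(all.equal(fit_reduced$design$y, fit_full$design$y)))
    stop("models were not fitted to identical data")
  bn <- function(f) vapply(f$design$blocks, `[[`, "", "name")
  if (!all(bn(fit_reduced) %in% bn(fit_full)))
    stop("models are not nested (reduced terms missing from full)")
  df <- fit_full$edf_total - fit_reduced$edf_total
  chisq <- max(0, (fit_reduced$rss - fit_full$rss) / fit_full$sigma2)
  p <- if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else 1
  list(chisq = chisq, df = df, p_value = p,
       aic_reduced = fit_reduced$aic, aic_full = fit_full$aic,
       preferred = if (fit_full$aic < fit_reduced$aic) "full" else
         "reduced")
}

#' Interquartile-range outlier screen
#'
#' Flags values below `Q1 - 1.5 IQR` or above `Q3 + 1.5 IQR`.
#'
#' @param values numeric vector (at least 4 values).
#' @param k multiplier (default 1.5).
#' @return logical vector of flags.
#' @export
iqr_outlier_screen <- function(values, k = 1.5) {
  if (length(values) < 4) stop("need at least 4 values")
  q <- stats::quantile(values, c(0.25, 0.75), na.rm = TRUE)
  iqr <- q[2] - q[1]
  values < q[1] - k * iqr | values > q[2] + k * iqr
}

#' Per-ambiguity-level behavioral models
#'
#' For each ambiguity level L fits a mixed model of reaction time on
#' block, the centered bilingualism score, their interaction, and the
#' point class at L (ambiguous vs. disambiguated; at level 0, ambiguous
#' vs. unambiguous), with a participant random intercept.  Only correct
#' experimental trials enter.  Levels with no classified trials are
#' skipped with a message.
#'
#' @param trial_table output of [simulate_behavior()].
#' @param max_level highest class level analysed (default 4).
#' @return named list of per-level coefficient matrices (from
#'   `lme4::lmer`).
#' @export
fit_behavior_models <- function(trial_table, max_level = 4L) {
  d <- trial_table[trial_table$block > 0 & trial_table$correct == 1, ]
  d$lsbq_c <- d$lsbq - mean(d$lsbq)
  out <- list()
  for (L in 0:max_level) {
    cl <- d[[paste0("class_at_level_", L)]]
    keep <- if (L == 0) cl %in% c("unambiguous", "ambiguous") else
      cl %in% c("disambiguated", "ambiguous")
    dl <- d[keep, ]
    if (nrow(dl) == 0) {
      message("no classified trials at level ", L, "; skipped")
      next
    }
    dl$point_class <- factor(dl[[paste0("class_at_level_", L)]])
    fit <- lme4::lmer(
      rt_ms ~ block * lsbq_c + point_class + (1 | participant_id),
      data = dl, REML = TRUE)
    out[[paste0("level_", L)]] <- summary(fit)$coefficients
  }
  out
}
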