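# GLS fitting of consistency / loop / design-by-treatment interaction
# models on contrast-level data, and the global Wald test for inconsistency.

#' Construct a contrast-level dataset
#'
#' Each study contributes its relative-effect estimates versus a baseline
#' treatment together with their within-study covariance; a k-arm study
#' contributes k - 1 contrasts. The covariance blocks must be symmetric
#' positive definite.
#'
#' @param studies list of study records; each a list with elements
#'   `study` (id), `design` (character vector or compact string),
#'   `baseline` (treatment label), `treatments` (non-baseline labels),
#'   `estimates` (numeric, same order as `treatments`), and `cov`
#'   (covariance matrix of the estimates).
#' @param treatments optional declared treatment superset.
#' @return object of class `nmi_contrast_data` with elements `studies`,
#'   `designs` (the observed `nmi_design_set`) and `layout`.
#' @export
contrast_data <- function(studies, treatments = NULL) {
  if (length(studies) == 0L) stop("no studies", call. = FALSE)
  studies <- lapply(studies, function(s) {
    s$design <- parse_design(s$design)
    s$key <- design_key(s$design)
    s$baseline <- as.character(s$baseline)
    s$treatments <- as.character(s$treatments)
    if (!s$baseline %in% s$design ||
        !all(s$treatments %in% s$design) ||
        s$baseline %in% s$treatments ||
        !setequal(c(s$baseline, s$treatments), s$design)) {
      stop("study ", s$study, ": arms do not match its design ", s$key,
           call. = FALSE)
    }
    k <- length(s$treatments)
    s$cov <- as.matrix(s$cov)
    if (!is.numeric(s$estimates) || length(s$estimates) != k ||
        nrow(s$cov) != k || ncol(s$cov) != k) {
      stop("study ", s$study, ": estimate/covariance dimensions mismatch",
           call. = FALSE)
    }
    if (max(abs(s$cov - t(s$cov))) > 1e-10 ||
        min(eigen(s$cov, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop("study ", s$study, ": covariance not symmetric positive definite",
           call. = FALSE)
    }
    s
  })
  keys <- unique(vapply(studies, `[[`, character(1), "key"))
  designs <- design_set(as.list(keys), treatments = treatments)
  layout <- do.call(rbind, lapply(studies, function(s) {
    contrast_layout(study = rep(s$study, length(s$treatments)),
                    design = s$key, baseline = s$baseline,
                    treatment = s$treatments)
  }))
  structure(list(studies = studies, designs = designs, layout = layout),
            class = "nmi_contrast_data")
}

#' @export
print.nmi_contrast_data <- function(x, ...) {
  cat("Contrast dataset:", length(x$studies), "studies,",
      nrow(x$layout), "contrasts,", length(x$designs$keys), "designs {",
      paste(x$designs$keys, collapse = ", "), "}\n")
  invisible(x)
}

# stacked estimate vector, aligned with data$layout
estimate_vector <- function(data) {
  unlist(lapply(data$studies, `[[`, "estimates"), use.names = FALSE)
}

# block-diagonal total covariance: within-study + tau2 * exchangeable
# heterogeneity (tau2 on the diagonal, tau2/2 off-diagonal within a study)
total_covariance <- function(data, tau2) {
  blocks <- lapply(data$studies, function(s) {
    k <- length(s$treatments)
    s$cov + tau2 * ((diag(k) + matrix(1, k, k)) / 2)
  })
  n <- sum(vapply(blocks, nrow, integer(1)))
  V <- matrix(0, n, n)
  at <- 0L
  for (b in blocks) {
    idx <- at + seq_len(nrow(b))
    V[idx, idx] <- b
    at <- at + nrow(b)
  }
  V
}

#' Fit an inconsistency model by generalized least squares
#'
#' Weighted least squares with total covariance V = within-study
#' covariance + tau2 times the exchangeable heterogeneity structure
#' (variance tau2 per contrast, covariance tau2/2 within multi-arm
#' studies). Estimates are (X'V^-1 X)^-1 X'V^-1 y with covariance
#' (X'V^-1 X)^-1.
#'
#' @param data an `nmi_contrast_data`.
#' @param model an `nmi_model` from [build_matrix()] whose layout matches
#'   the data's contrasts, or an `nmi_partition` (the model is then built
#'   on the data's layout).
#' @param tau2 nonnegative heterogeneity variance (known or previously
#'   estimated).
#' @return object of class `nmi_fit`: `estimates` (named), `cov`,
#'   `residual_df`, `tau2`, `fitted`, `residuals`, `model`.
#' @export
fit_gls <- function(data, model, tau2 = 0) {
  stopifnot(tau2 >= 0)
  if (inherits(model, "nmi_partition")) {
    model <- build_matrix(data$layout, model)
  }
  if (nrow(model$X) != nrow(data$layout)) {
    stop("model matrix rows do not align with the data's contrasts",
         call. = FALSE)
  }
  X <- model$X
  y <- estimate_vector(data)
  V <- total_covariance(data, tau2)
  Vi <- chol2inv(chol(V))
  XtVi <- crossprod(X, Vi)
  A <- XtVi %*% X
  if (mat_rank(A) < ncol(X)) {
    stop("singular normal equations; rank-deficient columns among: ",
         paste(colnames(X), collapse = ", "), call. = FALSE)
  }
  Ai <- chol2inv(chol((A + t(A)) / 2))
  beta <- drop(Ai %*% (XtVi %*% y))
  names(beta) <- colnames(X)
  fitted <- drop(X %*% beta)
  dimnames(Ai) <- list(colnames(X), colnames(X))
  structure(list(estimates = beta, cov = Ai,
                 residual_df = nrow(X) - ncol(X),
                 tau2 = tau2, fitted = fitted, residuals = y - fitted,
                 model = model),
            class = "nmi_fit")
}

#' @export
print.nmi_fit <- function(x, ...) {
  cat("GLS fit (tau2 =", format(x$tau2, digits = 4), "):\n")
  tab <- data.frame(estimate = x$estimates,
                    se = sqrt(diag(x$cov)))
  print(round(tab, 4))
  cat("residual df:", x$residual_df, "\n")
  invisible(x)
}

#' Method-of-moments estimate of the heterogeneity variance
#'
#' Generalized DerSimonian-Laird estimator: with W the inverse of the
#' within-study covariance and Q the generalized residual Q-statistic of
#' the tau2 = 0 GLS fit, solves E\[Q\] = (N - p) + tau2 * c for tau2 and
#' truncates at zero, where c = tr(W S) - tr((X'WX)^-1 X'W S W X) and S is
#' the exchangeable heterogeneity structure.
#'
#' @param data an `nmi_contrast_data`.
#' @param model an `nmi_model` or `nmi_partition`; the estimator measures
#'   heterogeneity residual to this model. Use the discrete partition to
#'   avoid conflating inconsistency with heterogeneity.
#' @return nonnegative tau2 estimate.
#' @export
estimate_tau2 <- function(data, model) {
  if (inherits(model, "nmi_partition")) {
    model <- build_matrix(data$layout, model)
  }
  X <- model$X
  N <- nrow(X); p <- ncol(X)
  if (N - p < 1L) {
    stop("saturated model: no residual degrees of freedom to estimate tau2; ",
         "supply tau2 explicitly", call. = FALSE)
  }
  V0 <- total_covariance(data, 0)
  W <- chol2inv(chol(V0))
  # heterogeneity structure matrix S (same block pattern, unit scale)
  S <- local({
    blocks <- lapply(data$studies, function(s) {
      k <- length(s$treatments)
      (diag(k) + matrix(1, k, k)) / 2
    })
    M <- matrix(0, N, N); at <- 0L
    for (b in blocks) {
      idx <- at + seq_len(nrow(b)); M[idx, idx] <- b; at <- at + nrow(b)
    }
    M
  })
  fit0 <- fit_gls(data, model, tau2 = 0)
  r <- fit0$residuals
  Q <- drop(crossprod(r, W %*% r))
  XtW <- crossprod(X, W)
  Ai <- chol2inv(chol((XtW %*% X + t(XtW %*% X)) / 2))
  WS <- W %*% S
  cc <- sum(diag(WS)) - sum(diag(Ai %*% (XtW %*% S %*% t(XtW))))
  max(0, (Q - (N - p)) / cc)
}

#' Global Wald test for inconsistency
#'
#' Fits the design-by-treatment interaction model (discrete partition on
#' the observed designs) and tests the joint null that all identifiable
#' inconsistency parameters are zero: Q = omega' cov(omega)^-1 omega is
#' referred to the chi-square distribution with df equal to the
#' inconsistency degrees of freedom. Because the design-by-treatment
#' interaction model contains every loop inconsistency model, this single
#' test simultaneously tests for inconsistency in all of them.
#'
#' @param data an `nmi_contrast_data`.
#' @param tau2 heterogeneity variance: a nonnegative number, or `"auto"` to
#'   estimate it residually under the design-by-treatment interaction model
#'   (falls back to 0 with a warning when that model is saturated).
#' @param omega_order optional permutation of candidate omega columns,
#'   forwarded to [build_matrix()] (the statistic is invariant to it).
#' @return object of class `nmi_incon_test`: `Q`, `df`, `p_value`, `tau2`,
#'   `degenerate` flag, and the underlying `fit` (NULL when degenerate).
#' @export
wald_inconsistency_test <- function(data, tau2 = "auto", omega_order = NULL) {
  dxt <- discrete_partition(data$designs)
  model <- build_matrix(data$layout, dxt, omega_order = omega_order)
  k <- length(model$spec$omega)
  if (k == 0L) {
    return(structure(list(Q = 0, df = 0L, p_value = NA_real_,
                          tau2 = if (identical(tau2, "auto")) 0 else tau2,
                          degenerate = TRUE, fit = NULL),
                     class = "nmi_incon_test"))
  }
  if (identical(tau2, "auto")) {
    tau2 <- if (nrow(model$X) - ncol(model$X) >= 1L) {
      estimate_tau2(data, model)
    } else {
      warning("design-by-treatment interaction model is saturated; ",
              "using tau2 = 0 for the test")
      0
    }
  }
  fit <- fit_gls(data, model, tau2 = tau2)
  idx <- match(model$spec$omega, names(fit$estimates))
  w <- fit$estimates[idx]
  Vw <- fit$cov[idx, idx, drop = FALSE]
  Q <- drop(crossprod(w, solve(Vw, w)))
  structure(list(Q = Q, df = k,
                 p_value = stats::pchisq(Q, df = k, lower.tail = FALSE),
                 tau2 = tau2, degenerate = FALSE, fit = fit),
            class = "nmi_incon_test")
}

#' @export
print.nmi_incon_test <- function(x, ...) {
  if (x$degenerate) {
    cat("Global inconsistency test: degenerate (0 inconsistency df;",
        "a single design cannot be inconsistent with itself)\n")
  } else {
    cat(sprintf(
      "Global Wald test for inconsistency: Q = %.4f, df = %d, p = %.4g (tau2 = %.4g)\n",
      x$Q, x$df, x$p_value, x$tau2))
  }
  invisible(x)
}
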