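# Generation of contrast-level network meta-analysis data with controlled
# consistency, between-study heterogeneity, and design-level inconsistency.

#' Simulation configuration
#'
#' Describes a generative network: per-study true basic effects versus the
#' reference are delta + beta + omega, where delta are the network-level
#' basic effects, beta is a study-specific heterogeneity draw with the
#' exchangeable structure (variance tau2 per contrast, covariance tau2/2),
#' and omega are fixed design-level inconsistency offsets. Observed
#' contrasts versus each study's baseline follow by within-trial
#' consistency, plus sampling noise from a shared-baseline-arm covariance
#' (per-arm variance `var_scale`, hence contrast variance 2 * var_scale and
#' within-study covariance var_scale), which is recorded as known.
#'
#' @param treatments character vector of treatment labels; the
#'   lexicographically first is the reference.
#' @param designs observed designs (character vector of compact strings or
#'   list of member vectors).
#' @param studies_per_design integer, scalar or named by design key.
#' @param delta named numeric vector of basic effects for non-reference
#'   treatments (effect units); missing entries default to 0.
#' @param tau2 nonnegative between-study heterogeneity variance.
#' @param omega named list: per design key, a named numeric vector of
#'   inconsistency offsets versus the reference for treatments in that
#'   design (entries for treatments not in the design are an error).
#' @param var_scale per-arm sampling variance (variance units).
#' @param seed integer master seed (mandatory: reproducibility contract).
#' @return object of class `nmi_sim_config`.
#' @export
sim_config <- function(treatments, designs, studies_per_design = 1L,
                       delta = numeric(0), tau2 = 0, omega = list(),
                       var_scale = 0.05, seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  ds <- design_set(designs, treatments = treatments)
  treatments <- ds$treatments
  reference <- treatments[1L]
  full_delta <- stats::setNames(numeric(length(treatments)), treatments)
  if (length(delta)) {
    bad <- setdiff(names(delta), treatments)
    if (length(bad) || is.null(names(delta))) {
      stop("delta must be named by treatments in the network", call. = FALSE)
    }
    if (reference %in% names(delta) && delta[[reference]] != 0) {
      stop("delta for the reference treatment must be 0", call. = FALSE)
    }
    full_delta[names(delta)] <- delta
  }
  if (length(omega)) {
    bad <- setdiff(names(omega), ds$keys)
    if (length(bad) || is.null(names(omega))) {
      stop("omega must be named by observed design keys; unknown: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    dmembers <- stats::setNames(ds$designs, ds$keys)
    for (d in names(omega)) {
      off <- setdiff(names(omega[[d]]), dmembers[[d]])
      if (length(off) || is.null(names(omega[[d]]))) {
        stop("omega for design ", d, " names treatments not in the design: ",
             paste(off, collapse = ", "), call. = FALSE)
      }
    }
  }
  if (length(studies_per_design) == 1L && is.null(names(studies_per_design))) {
    studies_per_design <- stats::setNames(
      rep(as.integer(studies_per_design), length(ds$keys)), ds$keys)
  } else {
    stopifnot(setequal(names(studies_per_design), ds$keys))
    studies_per_design <-
      stats::setNames(as.integer(studies_per_design[ds$keys]), ds$keys)
  }
  stopifnot(all(studies_per_design >= 1L), tau2 >= 0, var_scale > 0)
  structure(list(treatments = treatments, designs = ds,
                 reference = reference,
                 studies_per_design = studies_per_design,
                 delta = full_delta, tau2 = tau2, omega = omega,
                 var_scale = var_scale, seed = as.integer(seed)),
            class = "nmi_sim_config")
}

#' @export
print.nmi_sim_config <- function(x, ...) {
  cat("Simulation config:", length(x$designs$keys), "designs,",
      sum(x$studies_per_design), "studies, tau2 =", x$tau2,
      ", seed =", x$seed, "\n")
  invisible(x)
}

# deterministic per-study substream seed below 2^31
study_seed <- function(master, index) {
  (as.numeric(master) * 48271 + index * 9973) %% 2147483629
}

mvn_draw <- function(mean, Sigma) {
  k <- length(mean)
  if (k == 0L) return(numeric(0))
  L <- chol(Sigma)
  drop(mean + t(L) %*% stats::rnorm(k))
}

#' Simulate a contrast-level network meta-analysis dataset
#'
#' For each study of design d with baseline b, draws true contrasts
#' theta_J - theta_b where theta_J = delta_J + omega_d,J (omega defaulting
#' to 0), adds a heterogeneity draw with the exchangeable tau2 structure
#' and sampling noise with the shared-baseline-arm covariance, and records
#' that covariance as known. Per-study random substreams are derived
#' deterministically from the master seed, so partial reruns reproduce.
#'
#' @param config an `nmi_sim_config`.
#' @return an `nmi_contrast_data`.
#' @export
simulate_network <- function(config) {
  stopifnot(inherits(config, "nmi_sim_config"))
  dmembers <- stats::setNames(config$designs$designs, config$designs$keys)
  studies <- list()
  idx <- 0L
  for (d in config$designs$keys) {
    m <- dmembers[[d]]
    b <- m[1L]
    trts <- m[-1L]
    k <- length(trts)
    om <- stats::setNames(numeric(length(m)), m)
    if (!is.null(config$omega[[d]])) {
      om[names(config$omega[[d]])] <- config$omega[[d]]
    }
    theta <- (config$delta[trts] + om[trts]) - (config$delta[[b]] + om[[b]])
    R <- (diag(k) + matrix(1, k, k)) / 2          # exchangeable, unit scale
    Sigma <- config$var_scale * (diag(k) + matrix(1, k, k))  # shared baseline arm
    for (i in seq_len(config$studies_per_design[[d]])) {
      idx <- idx + 1L
      set.seed(study_seed(config$seed, idx))
      y <- mvn_draw(theta, config$tau2 * R + Sigma)
      studies[[idx]] <- list(study = sprintf("%s_%02d", d, i),
                             design = m, baseline = b, treatments = trts,
                             estimates = stats::setNames(y, trts),
                             cov = Sigma)
    }
  }
  contrast_data(studies, treatments = config$treatments)
}

#' Ready-made simulation scenarios
#'
#' * `"triangle"` -- the {AB, AC, BC} network, 2 studies per design by
#'   default, with a configurable inconsistency offset on the BC design
#'   (applied to treatment C).
#' * `"full_T_n4"` -- one study per each of the 11 possible designs of a
#'   4-treatment network, with a configurable offset on the BC design.
#' * `"star_plus_loop"` -- the star {AB, AC, AD} plus the loop-closing
#'   {BC} design (inconsistency df 1 under the discrete partition).
#'
#' @param name scenario identifier.
#' @param omega numeric inconsistency offset placed on the scenario's
#'   designated design (default 0: consistent network).
#' @param tau2 heterogeneity variance.
#' @param studies studies per design (scalar).
#' @param delta named basic effects; scenario defaults used when NULL.
#' @param var_scale per-arm sampling variance.
#' @param seed master seed.
#' @return an `nmi_sim_config`.
#' @export
scenario_suite <- function(name = c("triangle", "full_T_n4", "star_plus_loop"),
                           omega = 0, tau2 = 0, studies = NULL, delta = NULL,
                           var_scale = 0.05, seed) {
  name <- match.arg(name)
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  om <- function(key, trt) {
    if (omega == 0) list() else
      stats::setNames(list(stats::setNames(omega, trt)), key)
  }
  switch(name,
    triangle = sim_config(
      treatments = c("A", "B", "C"),
      designs = c("AB", "AC", "BC"),
      studies_per_design = if (is.null(studies)) 2L else studies,
      delta = if (is.null(delta)) c(B = 0.2, C = 0.5) else delta,
      tau2 = tau2, omega = om("BC", "C"),
      var_scale = var_scale, seed = seed),
    full_T_n4 = sim_config(
      treatments = c("A", "B", "C", "D"),
      designs = enumerate_designs(c("A", "B", "C", "D"))$keys,
      studies_per_design = if (is.null(studies)) 1L else studies,
      delta = if (is.null(delta)) c(B = 0.2, C = 0.5, D = 0.8) else delta,
      tau2 = tau2, omega = om("BC", "C"),
      var_scale = var_scale, seed = seed),
    star_plus_loop = sim_config(
      treatments = c("A", "B", "C", "D"),
      designs = c("AB", "AC", "AD", "BC"),
      studies_per_design = if (is.null(studies)) 2L else studies,
      delta = if (is.null(delta)) c(B = 0.2, C = 0.5, D = 0.8) else delta,
      tau2 = tau2, omega = om("BC", "C"),
      var_scale = var_scale, seed = seed)
  )
}
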