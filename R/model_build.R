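# Translate design sets and consistency partitions into identifiable
# fixed-effects parameterizations and contrast-level design matrices.
#
# Model for the true effect of treatment J vs the reference A in study i of
# design d:  mu_di^{AJ} = delta^{AJ} + beta_di^{AJ} + omega_d^{AJ},
# with within-trial consistency mu_di^{IJ} = mu_di^{AJ} - mu_di^{AI}.
# Under a consistency partition, designs in the same group share their
# omega parameters; the discrete partition gives the full
# design-by-treatment interaction model, the single-group partition the
# consistency model.

RANK_TOL <- 1e-8

mat_rank <- function(x) {
  if (is.null(dim(x)) || ncol(x) == 0L || nrow(x) == 0L) return(0L)
  qr(x, tol = RANK_TOL)$rank
}

#' Contrast layout of a dataset
#'
#' One row per observed contrast (study x non-baseline treatment). A study
#' of a k-arm design contributes k - 1 rows, all sharing the study's
#' baseline treatment.
#'
#' @param study vector of study identifiers.
#' @param design character vector of design keys (one per row).
#' @param baseline character vector of baseline treatments (one per row).
#' @param treatment character vector of non-baseline treatments.
#' @return a `data.frame` with those four columns.
#' @export
contrast_layout <- function(study, design, baseline, treatment) {
  out <- data.frame(study = as.character(study),
                    design = as.character(design),
                    baseline = as.character(baseline),
                    treatment = as.character(treatment),
                    stringsAsFactors = FALSE)
  bad <- out$baseline == out$treatment
  if (any(bad)) stop("contrast where treatment equals baseline", call. = FALSE)
  out
}

#' Canonical one-study-per-design layout
#'
#' One synthetic study per design, baseline = lexicographically first
#' member. Useful for rank computations and model comparisons that depend
#' only on the design set.
#'
#' @param designs an `nmi_design_set`.
#' @return a [contrast_layout()] data frame.
#' @export
layout_one_per_design <- function(designs) {
  rows <- lapply(seq_along(designs$keys), function(i) {
    m <- designs$designs[[i]]
    contrast_layout(study = rep(designs$keys[i], length(m) - 1L),
                    design = designs$keys[i],
                    baseline = m[1L], treatment = m[-1L])
  })
  do.call(rbind, rows)
}

omega_name <- function(group_label, ref, trt) {
  paste0("w_", group_label, "_", ref, trt)
}

# raw (unreduced) columns: basic effects + all candidate group-level omegas
raw_matrix <- function(layout, partition, reference) {
  designs <- partition$designs
  treatments <- designs$treatments
  if (!reference %in% treatments) {
    stop("reference treatment ", reference, " not in the network",
         call. = FALSE)
  }
  gi <- group_index(partition)
  miss <- setdiff(unique(layout$design), names(gi))
  if (length(miss)) {
    stop("designs absent from the partition: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  # validate baselines belong to their design
  dmembers <- stats::setNames(designs$designs, designs$keys)
  for (r in seq_len(nrow(layout))) {
    m <- dmembers[[layout$design[r]]]
    if (!(layout$baseline[r] %in% m) || !(layout$treatment[r] %in% m)) {
      stop("study ", layout$study[r], ": arm not in design ",
           layout$design[r], call. = FALSE)
    }
  }
  non_ref <- setdiff(treatments, reference)
  delta_cols <- paste0("d_", reference, non_ref)

  # candidate omegas: per group, per non-reference treatment occurring in it
  group_labels <- vapply(partition$groups, `[`, character(1), 1L)
  omega_cols <- character(0)
  omega_group <- integer(0)
  omega_trt <- character(0)
  for (g in seq_along(partition$groups)) {
    trts <- sort(unique(unlist(dmembers[partition$groups[[g]]])),
                 method = "radix")
    trts <- setdiff(trts, reference)
    if (length(trts)) {
      omega_cols <- c(omega_cols, omega_name(group_labels[g], reference, trts))
      omega_group <- c(omega_group, rep(g, length(trts)))
      omega_trt <- c(omega_trt, trts)
    }
  }

  n_row <- nrow(layout)
  X <- matrix(0, n_row, length(delta_cols) + length(omega_cols),
              dimnames = list(NULL, c(delta_cols, omega_cols)))
  dpos <- stats::setNames(seq_along(non_ref), non_ref)
  opos <- stats::setNames(seq_along(omega_cols) + length(delta_cols),
                          paste(omega_group, omega_trt))
  for (r in seq_len(n_row)) {
    b <- layout$baseline[r]; j <- layout$treatment[r]
    g <- gi[[layout$design[r]]]
    if (j != reference) {
      X[r, dpos[[j]]] <- X[r, dpos[[j]]] + 1
      X[r, opos[[paste(g, j)]]] <- X[r, opos[[paste(g, j)]]] + 1
    }
    if (b != reference) {
      X[r, dpos[[b]]] <- X[r, dpos[[b]]] - 1
      X[r, opos[[paste(g, b)]]] <- X[r, opos[[paste(g, b)]]] - 1
    }
  }
  list(X = X, n_delta = length(delta_cols))
}

#' Build the identifiable design matrix for an inconsistency model
#'
#' Constructs the contrast-level design matrix for the model defined by a
#' consistency partition. Each row expresses a contrast as a difference of
#' basic effects versus the reference treatment plus group-level
#' inconsistency offsets shared by every design in the contrast's group.
#' Because not all inconsistency parameters are identifiable, the omega
#' columns are reduced to an identifiable subset by rank-revealing greedy
#' elimination: basic-effect columns are always kept, then candidate omega
#' columns are added in a deterministic canonical order (groups in
#' canonical order, treatments lexicographic) whenever they increase the
#' rank. Any valid constraint scheme spans the same column space.
#'
#' @param layout a [contrast_layout()] data frame.
#' @param partition an `nmi_partition` covering every design in `layout`.
#' @param reference reference treatment; defaults to the lexicographically
#'   first treatment of the network.
#' @param omega_order optional permutation of the candidate omega column
#'   indices, used to verify that inference is invariant to the
#'   identifiable subset chosen.
#' @return list of class `nmi_model` with elements `X` (reduced matrix,
#'   rows aligned with `layout`), `layout`, `spec` (an `nmi_model_spec`
#'   with `reference`, `basic` parameter names, `omega` parameter names,
#'   and the `partition`), and `rank`.
#' @export
build_matrix <- function(layout, partition, reference = NULL,
                         omega_order = NULL) {
  designs <- partition$designs
  if (is.null(reference)) reference <- designs$treatments[1L]
  raw <- raw_matrix(layout, partition, reference)
  X <- raw$X
  delta_idx <- seq_len(raw$n_delta)
  omega_idx <- setdiff(seq_len(ncol(X)), delta_idx)
  if (!is.null(omega_order)) {
    stopifnot(setequal(omega_order, seq_along(omega_idx)))
    omega_idx <- omega_idx[omega_order]
  }
  kept <- delta_idx
  r <- mat_rank(X[, kept, drop = FALSE])
  for (j in omega_idx) {
    r_new <- mat_rank(X[, c(kept, j), drop = FALSE])
    if (r_new > r) {
      kept <- c(kept, j)
      r <- r_new
    }
  }
  Xr <- X[, kept, drop = FALSE]
  spec <- structure(
    list(reference = reference,
         basic = colnames(X)[delta_idx],
         omega = setdiff(colnames(Xr), colnames(X)[delta_idx]),
         partition = partition),
    class = "nmi_model_spec")
  structure(list(X = Xr, layout = layout, spec = spec, rank = r),
            class = "nmi_model")
}

#' @export
print.nmi_model <- function(x, ...) {
  cat("Contrast-level model:", nrow(x$X), "contrasts,",
      length(x$spec$basic), "basic effects,",
      length(x$spec$omega), "identifiable inconsistency parameters",
      "(rank ", x$rank, ")\n")
  invisible(x)
}

#' Inconsistency degrees of freedom of a partition
#'
#' The rank of the model matrix minus the rank of the consistency
#' (single-group) matrix, computed on a canonical one-study-per-design
#' layout. Zero for the single-group partition; maximal -- sum over designs
#' of (arms - 1) minus the consistency rank -- for the discrete partition.
#'
#' @param designs an `nmi_design_set`.
#' @param partition an `nmi_partition` on `designs`; defaults to the
#'   discrete partition (the design-by-treatment interaction model).
#' @return integer degrees of freedom.
#' @export
inconsistency_df <- function(designs, partition = discrete_partition(designs)) {
  layout <- layout_one_per_design(designs)
  full <- build_matrix(layout, partition)
  cons <- build_matrix(layout, single_group_partition(designs))
  full$rank - cons$rank
}

#' Does one model contain another? (column-space inclusion)
#'
#' Model containment means every set of studies assumed consistent by the
#' outer model is also assumed consistent by the inner one; at the linear
#' model level this is column-space inclusion of the inner design matrix in
#' the outer one.
#'
#' @param outer,inner `nmi_model` objects built on the same layout.
#' @return logical: `TRUE` iff rank(\[outer | inner\]) = rank(outer).
#' @export
model_contains <- function(outer, inner) {
  if (nrow(outer$X) != nrow(inner$X)) {
    stop("models built on different layouts (row mismatch)", call. = FALSE)
  }
  mat_rank(cbind(outer$X, inner$X)) == outer$rank
}

#' Export a model matrix to CSV
#'
#' @param model an `nmi_model`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_matrix_csv <- function(model, path) {
  df <- cbind(model$layout, as.data.frame(model$X))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
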