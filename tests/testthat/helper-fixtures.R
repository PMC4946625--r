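# shared fixtures and independent oracles

T3 <- enumerate_designs(c("A", "B", "C"))
T4 <- enumerate_designs(c("A", "B", "C", "D"))
TRIANGLE <- design_set(c("AB", "AC", "BC"))

# random partition of a design set: independent uniform group labels
random_partition <- function(designs, k = 3L) {
  labels <- sample.int(k, length(designs$keys), replace = TRUE)
  consistency_partition(split(designs$keys, labels), designs)
}

# brute-force separation oracle: does ANY distinct ordering separate p, q?
brute_force_separated <- function(key_p, key_q, designs, orderings) {
  for (o in orderings) {
    gi <- netincon:::group_index(loop_model(o, designs))
    if (gi[[key_p]] != gi[[key_q]]) return(TRUE)
  }
  FALSE
}

# does every group of p sit inside some group of q? (p refines q)
refines <- function(p, q) {
  all(vapply(p$groups, function(g) {
    any(vapply(q$groups, function(h) all(g %in% h), logical(1)))
  }, logical(1)))
}

# classical consistency design matrix built independently of the package:
# one study per design, baseline = first member, columns = non-reference
# treatments, row for contrast (b, j): +1 at j, -1 at b (0 for reference)
oracle_consistency_matrix <- function(designs) {
  trts <- designs$treatments
  non_ref <- trts[-1L]
  rows <- list()
  for (m in designs$designs) {
    b <- m[1L]
    for (j in m[-1L]) {
      r <- stats::setNames(numeric(length(non_ref)), non_ref)
      if (j %in% non_ref) r[j] <- 1
      if (b %in% non_ref) r[b] <- r[b] - 1
      rows[[length(rows) + 1L]] <- r
    }
  }
  do.call(rbind, rows)
}

# oracle inconsistency df for the discrete partition, one study per design:
# the saturated model has rank = number of contrasts
oracle_dxt_df <- function(designs) {
  n_contrasts <- sum(lengths(designs$designs) - 1L)
  n_contrasts - qr(oracle_consistency_matrix(designs))$rank
}

rank_of <- function(X) if (is.null(dim(X)) || ncol(X) == 0) 0L else qr(X)$rank

same_colspace <- function(A, B) {
  rank_of(cbind(A, B)) == rank_of(A) && rank_of(A) == rank_of(B)
}

# minimal hand-built contrast dataset from per-study two-arm summaries
two_arm_data <- function(rows) {
  # rows: data.frame(study, design, baseline, treatment, estimate, variance)
  contrast_data(lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    list(study = r$study, design = r$design, baseline = r$baseline,
         treatments = r$treatment,
         estimates = stats::setNames(r$estimate, r$treatment),
         cov = matrix(r$variance, dimnames = list(r$treatment, r$treatment)))
  }))
}

consistent_triangle <- function(vab = 0.1, vac = 0.1, vbc = 0.1,
                                dAB = 0.2, dAC = 0.5) {
  two_arm_data(data.frame(
    study = c("s1", "s2", "s3"),
    design = c("AB", "AC", "BC"),
    baseline = c("A", "A", "B"),
    treatment = c("B", "C", "C"),
    estimate = c(dAB, dAC, dAC - dAB),
    variance = c(vab, vac, vbc),
    stringsAsFactors = FALSE))
}
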