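# Combinatorics of designs, treatment orderings, loop inconsistency models
# and their unions (common refinements of consistency partitions).

#' Parse a design into its canonical member vector
#'
#' A design is the set of treatments compared within a single study. Designs
#' can be given as character vectors of treatment labels or as compact
#' strings: single-character labels concatenate directly (`"ABD"`), while
#' multi-character labels must be separated by `+`, `,` or `;`
#' (`"drugA+placebo"`).
#'
#' @param x a character vector of treatment labels, or a single string.
#' @return sorted character vector of unique treatment labels (length >= 2).
#' @keywords internal
parse_design <- function(x) {
  x <- as.character(x)
  if (length(x) == 1L) {
    members <- if (grepl("[+,;]", x)) strsplit(x, "[+,;]")[[1]] else
      strsplit(x, "")[[1]]
  } else {
    members <- x
  }
  members <- sort(unique(trimws(members)), method = "radix")
  members <- members[nzchar(members)]
  if (length(members) < 2L) {
    stop("a design must contain at least two distinct treatments, got: ",
         paste(members, collapse = ","), call. = FALSE)
  }
  members
}

#' Canonical string key of a design
#'
#' Sorted labels, concatenated directly when all labels are single
#' characters (the usual A, B, C convention), otherwise joined with `+`.
#'
#' @param members character vector of treatment labels.
#' @return a single string.
#' @export
design_key <- function(members) {
  members <- sort(unique(as.character(members)), method = "radix")
  sep <- if (all(nchar(members) == 1L)) "" else "+"
  paste(members, collapse = sep)
}

#' Construct a design set
#'
#' A design set couples a collection of designs (each a set of >= 2
#' treatments) with the network's treatment set. The treatment set defaults
#' to the union of all design members but may be a declared superset.
#'
#' @param designs list of character vectors, or a character vector of
#'   compact design strings (see [parse_design()]).
#' @param treatments optional character vector of treatment labels; must
#'   contain every design member.
#' @return an object of class `nmi_design_set` with elements `designs`
#'   (list of member vectors, canonically ordered), `keys` (canonical
#'   strings) and `treatments`.
#' @examples
#' design_set(c("AB", "AC", "BC"))
#' @export
design_set <- function(designs, treatments = NULL) {
  if (length(designs) == 0L) stop("design set must be nonempty", call. = FALSE)
  if (!is.list(designs)) designs <- as.list(as.character(designs))
  members <- lapply(designs, parse_design)
  keys <- vapply(members, design_key, character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate designs: ", paste(unique(keys[duplicated(keys)]),
         collapse = ", "), call. = FALSE)
  }
  ord <- order(keys, method = "radix")
  members <- members[ord]
  keys <- keys[ord]
  all_members <- sort(unique(unlist(members)), method = "radix")
  if (is.null(treatments)) {
    treatments <- all_members
  } else {
    treatments <- sort(unique(as.character(treatments)), method = "radix")
    missing <- setdiff(all_members, treatments)
    if (length(missing)) {
      stop("designs use treatments not in the declared treatment set: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(designs = members, keys = keys, treatments = treatments),
            class = "nmi_design_set")
}

#' @export
print.nmi_design_set <- function(x, ...) {
  cat("Design set:", length(x$keys), "designs over treatments {",
      paste(x$treatments, collapse = ", "), "}\n")
  cat(" ", paste(x$keys, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.nmi_design_set <- function(x) length(x$keys)

#' Enumerate all possible designs over a treatment set
#'
#' Returns the set T of all subsets of the treatments containing more than
#' one label; its size is 2^n - n - 1 for n treatments.
#'
#' @param treatments character vector of >= 2 treatment labels.
#' @return an `nmi_design_set` holding every subset of size >= 2.
#' @examples
#' enumerate_designs(c("A", "B", "C", "D"))  # the 11 designs for n = 4
#' @export
enumerate_designs <- function(treatments) {
  treatments <- sort(unique(as.character(treatments)), method = "radix")
  n <- length(treatments)
  if (n < 2L) stop("a network needs at least 2 treatments", call. = FALSE)
  if (n > 20L) stop("refusing to enumerate 2^", n, " subsets", call. = FALSE)
  subsets <- list()
  for (k in 2:n) {
    subsets <- c(subsets,
                 utils::combn(treatments, k, simplify = FALSE))
  }
  design_set(subsets, treatments = treatments)
}

# ---- consistency partitions -------------------------------------------------

new_partition <- function(groups, designs, source = NULL) {
  # canonical form: designs within a group sorted; groups sorted by their
  # lexicographically smallest design
  groups <- lapply(groups, function(g) sort(as.character(g), method = "radix"))
  first <- vapply(groups, `[`, character(1), 1L)
  groups <- groups[order(first, method = "radix")]
  names(groups) <- NULL
  structure(list(groups = groups, designs = designs, source = source),
            class = "nmi_partition")
}

validate_partition <- function(p) {
  stopifnot(inherits(p, "nmi_partition"))
  all_keys <- unlist(p$groups)
  if (any(lengths(p$groups) == 0L)) stop("empty group in partition")
  if (anyDuplicated(all_keys)) stop("groups are not disjoint")
  if (!setequal(all_keys, p$designs$keys)) {
    stop("groups do not cover the design set exactly")
  }
  invisible(p)
}

#' Construct a consistency partition directly
#'
#' A consistency partition splits a design set into groups of designs that
#' are assumed to estimate the same treatment effects (to be mutually
#' consistent). Every inconsistency model considered here -- consistency,
#' loop, union, and the design-by-treatment interaction model -- is
#' represented by such a partition.
#'
#' @param groups list of character vectors of design keys (or of designs
#'   coercible via [design_key()]).
#' @param designs the `nmi_design_set` being partitioned.
#' @param source optional provenance tag (e.g. `"ordering:C,B,D,A"`).
#' @return an `nmi_partition`, in canonical form.
#' @export
consistency_partition <- function(groups, designs, source = NULL) {
  groups <- lapply(groups, function(g) {
    vapply(as.list(g), function(d) design_key(parse_design(d)), character(1))
  })
  p <- new_partition(groups, designs, source)
  validate_partition(p)
  p
}

#' The discrete partition: every design its own group
#'
#' Represents the design-by-treatment interaction model, in which every
#' design estimates a different set of treatment effects.
#'
#' @param designs an `nmi_design_set`.
#' @return an `nmi_partition` of singletons.
#' @export
discrete_partition <- function(designs) {
  new_partition(as.list(designs$keys), designs, source = "discrete")
}

#' The single-group (consistency) partition
#'
#' @param designs an `nmi_design_set`.
#' @return an `nmi_partition` with one group holding every design.
#' @export
single_group_partition <- function(designs) {
  new_partition(list(designs$keys), designs, source = "consistency")
}

#' @export
print.nmi_partition <- function(x, ...) {
  src <- if (is.null(x$source)) "" else paste0(" [", x$source, "]")
  cat("Consistency partition", src, ": ", length(x$groups),
      " group(s)\n", sep = "")
  for (g in x$groups) cat("  {", paste(g, collapse = ", "), "}\n")
  invisible(x)
}

#' Test two partitions for equality (canonical form)
#'
#' @param p,q `nmi_partition` objects over the same design set.
#' @return logical.
#' @export
partitions_equal <- function(p, q) {
  identical(p$groups, q$groups) && setequal(p$designs$keys, q$designs$keys)
}

#' Is a partition discrete (all singleton groups)?
#'
#' @param p an `nmi_partition`.
#' @return logical.
#' @export
is_discrete <- function(p) all(lengths(p$groups) == 1L)

# group index of each design key, aligned with designs$keys
group_index <- function(p) {
  idx <- integer(length(p$designs$keys))
  names(idx) <- p$designs$keys
  for (i in seq_along(p$groups)) idx[p$groups[[i]]] <- i
  idx
}

# ---- loop inconsistency models ---------------------------------------------

check_ordering <- function(ordering, treatments) {
  ordering <- as.character(ordering)
  if (anyDuplicated(ordering) ||
      !setequal(ordering, treatments) ||
      length(ordering) != length(treatments)) {
    stop("ordering must be a permutation of the treatment set {",
         paste(treatments, collapse = ", "), "}", call. = FALSE)
  }
  ordering
}

#' Loop inconsistency model induced by a treatment ordering
#'
#' Given an ordering of the treatments, designs are grouped by the
#' earliest-ordered treatment they contain: all designs containing the
#' first treatment form one group, designs containing the second but not
#' the first form the next, and so on. Designs within a group are assumed
#' to estimate the same treatment effects. Empty groups are dropped.
#'
#' @param ordering character vector, a permutation of `designs$treatments`.
#' @param designs an `nmi_design_set`.
#' @return an `nmi_partition` whose `source` records the ordering.
#' @examples
#' loop_model(c("C", "B", "D", "A"), enumerate_designs(c("A","B","C","D")))
#' @export
loop_model <- function(ordering, designs) {
  ordering <- check_ordering(ordering, designs$treatments)
  pos <- stats::setNames(seq_along(ordering), ordering)
  earliest <- vapply(designs$designs, function(m) min(pos[m]), numeric(1))
  groups <- split(designs$keys, earliest)
  new_partition(groups, designs,
                source = paste0("ordering:", paste(ordering, collapse = ",")))
}

#' Union (common refinement) of two consistency partitions
#'
#' The union of two inconsistency models is the smallest inconsistency
#' model containing both: its groups are all nonempty pairwise
#' intersections of the arguments' groups. The operation is idempotent,
#' commutative and associative up to canonical form.
#'
#' @param p,q `nmi_partition` objects over the same design set.
#' @return an `nmi_partition` with `source = "union"`.
#' @export
partition_union <- function(p, q) {
  if (!setequal(p$designs$keys, q$designs$keys)) {
    stop("partitions are defined on different design sets", call. = FALSE)
  }
  gp <- group_index(p)
  gq <- group_index(q)[names(gp)]
  groups <- split(names(gp), paste(gp, gq))
  new_partition(groups, p$designs, source = "union")
}

#' Union of the loop models of several orderings
#'
#' Left-fold of [partition_union()] over [loop_model()] results. The
#' canonical result does not depend on the fold order.
#'
#' @param designs an `nmi_design_set`.
#' @param orderings nonempty list of treatment orderings.
#' @return an `nmi_partition`.
#' @export
union_over_orderings <- function(designs, orderings) {
  if (length(orderings) == 0L) {
    stop("at least one ordering is required", call. = FALSE)
  }
  acc <- loop_model(orderings[[1L]], designs)
  for (o in orderings[-1L]) acc <- partition_union(acc, loop_model(o, designs))
  acc
}

# all permutations of a character vector, deterministic order
all_permutations <- function(v) {
  n <- length(v)
  if (n == 1L) return(list(v))
  out <- vector("list", factorial(n))
  k <- 1L
  for (i in seq_len(n)) {
    for (p in all_permutations(v[-i])) {
      out[[k]] <- c(v[i], p)
      k <- k + 1L
    }
  }
  out
}

#' Distinct treatment orderings up to the order of the last two treatments
#'
#' Swapping the final two treatments of an ordering leaves the induced
#' loop inconsistency model unchanged, so only n!/2 orderings produce
#' distinct models. One representative per equivalence class is returned:
#' the one whose final two treatments appear in lexicographic order.
#'
#' @param treatments character vector of >= 2 treatment labels.
#' @param force logical; exhaustive enumeration refuses n > 8 (8!/2 =
#'   20160 orderings) unless `force = TRUE`.
#' @return list of orderings (character vectors) of length n!/2.
#' @export
distinct_orderings <- function(treatments, force = FALSE) {
  treatments <- sort(unique(as.character(treatments)), method = "radix")
  n <- length(treatments)
  if (n < 2L) stop("a network needs at least 2 treatments", call. = FALSE)
  if (n > 8L && !force) {
    stop("refusing to enumerate ", n, "!/2 orderings; use force = TRUE, ",
         "or rely on separation_witness() which scales to any n",
         call. = FALSE)
  }
  perms <- all_permutations(treatments)
  keep <- vapply(perms, function(p) p[n - 1L] < p[n], logical(1))
  perms[keep]
}

#' Constructive witness ordering separating two designs
#'
#' For distinct designs P and Q there is a treatment Z in exactly one of
#' them; the ordering that puts Z first followed by the remaining
#' treatments in lexicographic order induces a loop model placing P and Q
#' in different groups. When both set differences are nonempty, Z is taken
#' from P \ Q; when P is a subset of Q, from Q \ P. The lexicographically
#' smallest eligible Z is used.
#'
#' @param p,q designs (character vectors or compact strings).
#' @param treatments the network treatment set.
#' @return an ordering (character vector).
#' @export
separation_witness <- function(p, q, treatments) {
  treatments <- sort(unique(as.character(treatments)), method = "radix")
  p <- parse_design(p)
  q <- parse_design(q)
  if (length(setdiff(union(p, q), treatments))) {
    stop("designs use treatments outside the network", call. = FALSE)
  }
  if (identical(p, q)) {
    stop("designs are identical and cannot be separated ",
         "(a design is always consistent with itself)", call. = FALSE)
  }
  diff <- setdiff(p, q)
  if (length(diff) == 0L) diff <- setdiff(q, p)
  z <- sort(diff, method = "radix")[1L]
  c(z, sort(setdiff(treatments, z), method = "radix"))
}

#' Verify the separation lemma on a design set
#'
#' For every unordered pair of distinct designs, computes the constructive
#' witness ordering and confirms, by recomputing its loop model, that the
#' pair lands in different groups. Any failure indicates an implementation
#' bug and raises an error.
#'
#' @param designs an `nmi_design_set` with >= 2 designs.
#' @return data frame with columns `design1`, `design2`, `ordering`
#'   (comma-joined witness), one row per pair.
#' @export
verify_lemma <- function(designs) {
  keys <- designs$keys
  if (length(keys) < 2L) stop("need at least 2 designs", call. = FALSE)
  pairs <- utils::combn(seq_along(keys), 2L)
  witness <- character(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    w <- separation_witness(designs$designs[[i1]], designs$designs[[i2]],
                            designs$treatments)
    gi <- group_index(loop_model(w, designs))
    if (gi[keys[i1]] == gi[keys[i2]]) {
      stop("lemma verification failed for pair ", keys[i1], ", ", keys[i2],
           " -- this is an implementation bug")
    }
    witness[j] <- paste(w, collapse = ",")
  }
  data.frame(design1 = keys[pairs[1L, ]], design2 = keys[pairs[2L, ]],
             ordering = witness, stringsAsFactors = FALSE)
}

#' Verify that the union of all loop models is the discrete partition
#'
#' Computes the union of the loop inconsistency models of all distinct
#' orderings and checks that it equals the discrete partition, i.e. the
#' design-by-treatment interaction model in which every design estimates
#' its own treatment effects.
#'
#' @param designs an `nmi_design_set`.
#' @param force passed to [distinct_orderings()].
#' @return logical.
#' @export
verify_theorem <- function(designs, force = FALSE) {
  if (length(designs$keys) == 1L) return(TRUE)
  u <- union_over_orderings(designs,
                            distinct_orderings(designs$treatments, force))
  is_discrete(u)
}
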