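# combinatorics of designs, orderings, loop models and partition unions

test_that("enumerate_designs returns every subset of size >= 2", {
  expect_setequal(
    T4$keys,
    c("AB", "AC", "AD", "BC", "BD", "CD",
      "ABC", "ABD", "ACD", "BCD", "ABCD"))
  expect_equal(design_set(c("AB"))$keys,
               enumerate_designs(c("A", "B"))$keys)
  for (n in 2:6) {
    expect_length(enumerate_designs(LETTERS[1:n])$keys, 2^n - n - 1)
  }
  expect_error(enumerate_designs("A"), "at least 2")
})

test_that("loop_model groups designs by earliest-ordered member", {
  L1 <- loop_model(c("C", "B", "D", "A"), T4)
  expect_setequal(
    vapply(L1$groups, paste, character(1), collapse = " "),
    c("ABC ABCD AC ACD BC BCD CD", "AB ABD BD", "AD"))
  L2 <- loop_model(c("A", "B", "C", "D"), T4)
  expect_setequal(
    vapply(L2$groups, paste, character(1), collapse = " "),
    c("AB ABC ABCD ABD AC ACD AD", "BC BCD BD", "CD"))
  # single design
  ab <- design_set("AB")
  expect_equal(loop_model(c("A", "B"), ab)$groups, list("AB"))
  # invalid orderings
  expect_error(loop_model(c("A", "B", "C"), T4), "permutation")
  expect_error(loop_model(c("A", "A", "B", "C"), T4), "permutation")
})

test_that("partition_union reproduces the worked refinement and its laws", {
  L1 <- loop_model(c("C", "B", "D", "A"), T4)
  L2 <- loop_model(c("A", "B", "C", "D"), T4)
  U <- partition_union(L1, L2)
  expect_setequal(
    vapply(U$groups, paste, character(1), collapse = " "),
    c("ABC ABCD AC ACD", "BC BCD", "CD", "AB ABD", "BD", "AD"))
  expect_true(partitions_equal(partition_union(L1, L1), L1))
  expect_true(partitions_equal(
    partition_union(L1, single_group_partition(T4)), L1))
  expect_error(partition_union(L1, discrete_partition(TRIANGLE)),
               "different design sets")
})

test_that("partition_union is commutative/associative and refines its args", {
  set.seed(41)
  for (rep in 1:20) {
    p <- random_partition(T4, k = 3L)
    q <- random_partition(T4, k = 4L)
    r <- random_partition(T4, k = 2L)
    pq <- partition_union(p, q)
    expect_true(partitions_equal(pq, partition_union(q, p)))
    expect_true(partitions_equal(
      partition_union(pq, r),
      partition_union(p, partition_union(q, r))))
    expect_true(refines(pq, p))
    expect_true(refines(pq, q))
    # partition laws hold by construction (validate would raise)
    expect_silent(netincon:::validate_partition(pq))
  }
})

test_that("distinct_orderings returns n!/2 class representatives", {
  expect_length(distinct_orderings(c("A", "B")), 1L)
  expect_length(distinct_orderings(c("A", "B", "C")), 3L)
  expect_length(distinct_orderings(c("A", "B", "C", "D")), 12L)
  expect_error(distinct_orderings(LETTERS[1:9]), "refusing")
  # the 3 representatives for n = 3 give 3 distinct partitions on full T
  parts <- lapply(distinct_orderings(c("A", "B", "C")), loop_model, designs = T3)
  sigs <- vapply(parts, function(p) paste(vapply(p$groups, paste,
    character(1), collapse = ","), collapse = "|"), character(1))
  expect_length(unique(sigs), 3L)
})

test_that("loop models are invariant to swapping the final two treatments", {
  for (n in 3:5) {
    designs <- enumerate_designs(LETTERS[1:n])
    perms <- netincon:::all_permutations(LETTERS[1:n])
    for (p in perms) {
      swapped <- p
      swapped[c(n - 1L, n)] <- p[c(n, n - 1L)]
      expect_true(partitions_equal(loop_model(p, designs),
                                   loop_model(swapped, designs)))
    }
  }
})

test_that("union over all orderings yields the discrete partition", {
  u4 <- union_over_orderings(T4, distinct_orderings(T4$treatments))
  expect_true(is_discrete(u4))
  expect_length(u4$groups, 11L)
  u3 <- union_over_orderings(T3, distinct_orderings(T3$treatments))
  expect_length(u3$groups, 4L)  # {AB, AC, BC, ABC} all singletons
  # fold order does not matter
  set.seed(7)
  ords <- distinct_orderings(T4$treatments)
  expect_true(partitions_equal(
    union_over_orderings(T4, ords),
    union_over_orderings(T4, sample(ords))))
  expect_error(union_over_orderings(T4, list()), "at least one")
})

test_that("separation_witness builds the constructive ordering", {
  w <- separation_witness("ABD", "BC", c("A", "B", "C", "D"))
  expect_equal(w, c("A", "B", "C", "D"))
  gi <- netincon:::group_index(loop_model(w, T4))
  expect_true(gi[["ABD"]] != gi[["BC"]])
  # subset case: Z drawn from q \ p
  expect_equal(separation_witness("CD", "BCD", c("A", "B", "C", "D")),
               c("B", "A", "C", "D"))
  expect_error(separation_witness("AB", "AB", c("A", "B", "C")),
               "identical")
})

test_that("every design pair is separated: constructive vs brute force", {
  for (n in 3:5) {
    designs <- enumerate_designs(LETTERS[1:n])
    wit <- verify_lemma(designs)  # raises on any failure
    expect_equal(nrow(wit), choose(length(designs$keys), 2L))
    # brute-force oracle over all distinct orderings agrees
    ords <- distinct_orderings(designs$treatments)
    set.seed(n)
    take <- sample(nrow(wit), min(15L, nrow(wit)))
    for (i in take) {
      expect_true(brute_force_separated(wit$design1[i], wit$design2[i],
                                        designs, ords))
    }
  }
  # two disjoint designs
  expect_equal(nrow(verify_lemma(design_set(c("AB", "CD")))), 1L)
})

test_that("union of all loop models is discrete on observed subsets too", {
  expect_true(verify_theorem(T3))
  expect_true(verify_theorem(T4))
  expect_true(verify_theorem(design_set("ABC")))  # single design
  set.seed(99)
  T5 <- enumerate_designs(LETTERS[1:5])
  for (rep in 1:5) {
    sub <- design_set(sample(T5$keys, sample(2:10, 1)))
    expect_true(verify_theorem(sub))
  }
})

test_that("loop model group count is at most n - 1 on full T", {
  for (n in 3:5) {
    designs <- enumerate_designs(LETTERS[1:n])
    for (o in distinct_orderings(designs$treatments)) {
      expect_lte(length(loop_model(o, designs)$groups), n - 1L)
    }
  }
})
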