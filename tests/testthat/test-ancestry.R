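sc <- scoring_scheme()

test_that("triplet distances vanish for identical sequences and are symmetric", {
  d <- triplet_distances("ACDEFG", "ACDEFG", "ACDEFG", sc)
  expect_equal(as.numeric(d), c(0, 0, 0))
  # distance of a pair does not depend on the order within the pair
  a <- "ACDEFGHIKL"; b <- "ACDEFGHIKV"; p <- "MCDEFGHIKL"
  expect_equal(alignment_distance(a, b, sc), alignment_distance(b, a, sc))
  d1 <- triplet_distances(a, b, p, sc)
  expect_equal(d1[["d_NA"]], alignment_distance(a, b, sc))
})

test_that("the smallest distance names the pattern; near-ties are unresolved", {
  expect_equal(classify_triplet(c(0.1, 0.3, 0.3)), "PATTERN_I")
  expect_equal(classify_triplet(c(0.3, 0.1, 0.3)), "PATTERN_II")
  expect_equal(classify_triplet(c(0.4, 0.35, 0.1)), "PATTERN_III")
  expect_equal(classify_triplet(c(0.2, 0.2, 0.5)), "UNRESOLVED")
  expect_equal(classify_triplet(c(0.2, 0.2 + 1e-13, 0.5), tolerance = 1e-12),
               "UNRESOLVED")
  expect_equal(classify_triplet(c(0.2, 0.2 + 1e-3, 0.5), tolerance = 1e-4),
               "PATTERN_I")
  # saturation sentinels: resolvable when the minimum is finite
  expect_equal(classify_triplet(c(0.2, Inf, Inf)), "PATTERN_I")
  expect_equal(classify_triplet(c(0.2, 0.4, Inf)), "PATTERN_I")
  expect_equal(classify_triplet(c(Inf, Inf, Inf)), "UNRESOLVED")
})

test_that("swapping the two references permutes patterns I and II", {
  set.seed(9)
  for (k in 1:50) {
    d <- sort(stats::runif(3), decreasing = TRUE)[sample(1:3)]
    lab <- classify_triplet(d)
    swapped <- classify_triplet(d[c(2, 1, 3)])
    expected <- c(PATTERN_I = "PATTERN_II", PATTERN_II = "PATTERN_I",
                  PATTERN_III = "PATTERN_III", UNRESOLVED = "UNRESOLVED")
    expect_equal(swapped, unname(expected[lab]))
  }
})

test_that("host-sister simulations put the focal/host pair nearest", {
  d <- simulate_dataset(sim_config(n_families = 200,
                                   topology_proportions = c(1, 0, 0),
                                   sequence_length = 120, master_seed = 12L))
  fams <- unique(d$truth$family_id)
  dm <- t(vapply(fams, function(f)
    triplet_distances(d$proteomes$N$sequences[[paste0(f, "_N")]],
                      d$proteomes$A$sequences[[paste0(f, "_A")]],
                      d$proteomes$P$sequences[[paste0(f, "_P")]], sc),
    numeric(3)))
  expect_lt(mean(dm[, 1]), mean(dm[, 2]))
  expect_lt(mean(dm[, 1]), mean(dm[, 3]))
})

test_that("dataset classification routes buckets and sums its counts", {
  # empty orthogroup set -> all-zero summary
  og0 <- data.frame(group_id = character(), species = character(),
                    member_id = character(), single_copy = logical(),
                    multi_copy = logical())
  p0 <- list(N = proteome("N", character(), character()),
             A = proteome("A", character(), character()),
             P = proteome("P", character(), character()))
  s0 <- classify_dataset(og0, p0, sc)
  expect_true(all(s0$counts == 0))
  # multi-copy-only dataset -> everything in MULTI_COPY
  d <- simulate_dataset(sim_config(n_families = 0, n_multicopy = 3,
                                   sequence_length = 150, master_seed = 3L))
  fit <- triplet_origin(d$proteomes$N, d$proteomes$A, d$proteomes$P, sc)
  expect_equal(unname(fit$summary$counts["MULTI_COPY"]), 3L)
  expect_equal(sum(fit$summary$counts[c("PATTERN_I", "PATTERN_II",
                                        "PATTERN_III")]), 0L)
  # counts always sum to the number of counted orthogroups
  expect_equal(sum(fit$summary$counts), fit$summary$n_groups)
})

test_that("pattern proportions are recovered within 3 binomial s.e.", {
  props <- c(0.26, 0.26, 0.48)
  n <- 300L
  d <- simulate_dataset(sim_config(n_families = n,
                                   topology_proportions = props,
                                   sequence_length = 300, master_seed = 31L))
  # orthogroups straight from the generator's family structure: this test
  # isolates the classifier from the search stage
  og <- truth_orthogroups(d$truth)
  s <- classify_dataset(og, d$proteomes, sc)
  got <- s$counts[c("PATTERN_I", "PATTERN_II", "PATTERN_III")] / n
  se <- sqrt(props * (1 - props) / n)
  expect_true(all(abs(got - props) < 3 * se),
              info = paste(round(got, 3), collapse = " "))
})

test_that("venn partition is exhaustive and matches its hit tables", {
  p <- proteome("N", sprintf("g%d", 1:6), rep("ACDEFGHIKL", 6))
  hits_A <- data.frame(query = c("g1", "g2", "g3"))
  hits_P <- data.frame(query = c("g3", "g4"))
  v <- venn_partition(p, hits_A, hits_P)
  expect_equal(unclass(v)[1:4],
               c(n_unique = 2L, n_only_A = 2L, n_only_P = 1L, n_both = 1L))
  expect_equal(sum(v), length(p))
  # no hits at all -> everything unique
  v0 <- venn_partition(p, data.frame(query = character()),
                       data.frame(query = character()))
  expect_equal(v0[["n_unique"]], 6L)
  # partition property on random hit tables
  set.seed(66)
  for (k in 1:20) {
    hA <- data.frame(query = sample(p$ids, sample(0:6, 1)))
    hP <- data.frame(query = sample(p$ids, sample(0:6, 1)))
    expect_equal(sum(venn_partition(p, hA, hP)), 6L)
  }
})

test_that("evidence tally separates host from symbiont patterns", {
  t1 <- symbiont_evidence_tally(c(PATTERN_I = 645, PATTERN_II = 635,
                                  PATTERN_III = 722, MULTI_COPY = 476))
  expect_equal(t1$host_count, 645L)
  expect_equal(t1$symbiont_count, 1357L)
  expect_equal(t1$verdict, "symbiont-dominant")
  t2 <- symbiont_evidence_tally(c(PATTERN_I = 10, PATTERN_II = 5,
                                  PATTERN_III = 5))
  expect_equal(t2$verdict, "indeterminate")
  t3 <- symbiont_evidence_tally(c(PATTERN_I = 0, PATTERN_II = 0,
                                  PATTERN_III = 0))
  expect_equal(t3$verdict, "indeterminate")
  t4 <- symbiont_evidence_tally(c(PATTERN_I = 9, PATTERN_II = 4,
                                  PATTERN_III = 4))
  expect_equal(t4$verdict, "host-dominant")
})
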