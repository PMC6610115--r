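test_that("root sequences are reproducible and uniform over the alphabet", {
  expect_equal(sample_root_sequence(0, seed = 1), "")
  expect_error(sample_root_sequence(-1), "non-negative")
  expect_identical(sample_root_sequence(50, seed = 7),
                   sample_root_sequence(50, seed = 7))
  # per-letter frequency over 1e5 residues compatible with uniform 1/20
  s <- sample_root_sequence(1e5, seed = 3)
  counts <- table(factor(strsplit(s, "")[[1]],
                         levels = strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]))
  p <- stats::chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.001)
})

test_that("sequence evolution preserves length and the zero-branch identity", {
  s <- sample_root_sequence(200, seed = 5)
  expect_identical(evolve_sequence(s, 0), s)
  expect_error(evolve_sequence(s, -0.1), "non-negative")
  for (t in c(0.05, 0.3, 2)) {
    e <- evolve_sequence(s, t)
    expect_equal(nchar(e), nchar(s))
  }
  # X residues are inert
  expect_identical(evolve_sequence("XXXX", 5, seed = 1), "XXXX")
})

test_that("observed p-distance matches the closed form within 3 s.e.", {
  set.seed(101)
  t_total <- 0.2
  L <- 100L
  n_rep <- 500L
  obs <- vapply(seq_len(n_rep), function(i) {
    a <- sample_root_sequence(L)
    b <- evolve_sequence(a, t_total)
    mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, numeric(1))
  expected <- expected_p_distance(t_total)
  se <- stats::sd(obs) / sqrt(n_rep)
  expect_lt(abs(mean(obs) - expected), 3 * se)
})

test_that("expected_p_distance evaluates its closed form", {
  expect_equal(expected_p_distance(0), 0)
  expect_equal(expected_p_distance(1e9), 19 / 20)
  expect_equal(expected_p_distance(0.1),
               (19 / 20) * (1 - exp(-20 * 0.1 / 19)))
  expect_equal(round(expected_p_distance(0.1), 4), 0.0949)
  expect_error(expected_p_distance(-1), "non-negative")
})

test_that("topology counts are allocated exactly by largest remainder", {
  d <- simulate_dataset(sim_config(n_families = 100,
                                   topology_proportions = c(0.3, 0.5, 0.2),
                                   sequence_length = 20))
  fams <- family_truth(d$truth)
  expect_equal(as.vector(table(factor(fams$label,
                                      levels = c("NA", "NP", "AP")))),
               c(30L, 50L, 20L))
})

test_that("unique and multi-copy units are emitted as planned", {
  d <- simulate_dataset(sim_config(n_families = 4, n_unique = c(7, 2, 0),
                                   n_multicopy = 3, sequence_length = 20))
  tr <- d$truth
  expect_equal(sum(tr$label == "UNIQUE" & tr$species == "N"), 7L)
  expect_equal(sum(tr$label == "UNIQUE" & tr$species == "A"), 2L)
  expect_equal(sum(tr$label == "UNIQUE" & tr$species == "P"), 0L)
  # each multi-copy family has two focal members
  multi <- tr[tr$label == "MULTI", ]
  expect_equal(length(unique(multi$family_id)), 3L)
  expect_true(all(table(multi$family_id, multi$species)[, "N"] == 2L))
})

test_that("every record id appears in exactly one truth entry", {
  d <- simulate_dataset(sim_config(n_families = 15, n_unique = 3,
                                   n_multicopy = 2, sequence_length = 30))
  all_ids <- unlist(lapply(d$proteomes, function(p) p$ids))
  expect_setequal(d$truth$member_id, all_ids)
  expect_equal(anyDuplicated(d$truth$member_id), 0L)
})

test_that("a fixed master seed reproduces byte-identical FASTA output", {
  cfg <- sim_config(n_families = 10, n_unique = 2, n_multicopy = 1,
                    sequence_length = 40, master_seed = 99L)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(d1$proteomes$N, f1)
  write_fasta(d2$proteomes$N, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(d1$truth, d2$truth)
})

test_that("changing only the master seed changes sequences, not labels", {
  cfg1 <- sim_config(n_families = 12, n_unique = 1, n_multicopy = 1,
                     sequence_length = 40, master_seed = 1L)
  cfg2 <- sim_config(n_families = 12, n_unique = 1, n_multicopy = 1,
                     sequence_length = 40, master_seed = 2L)
  d1 <- simulate_dataset(cfg1); d2 <- simulate_dataset(cfg2)
  expect_equal(table(family_truth(d1$truth)$label),
               table(family_truth(d2$truth)$label))
  expect_false(identical(d1$proteomes$N$sequences,
                         d2$proteomes$N$sequences))
})

test_that("triplet branch lengths order the expected pairwise divergences", {
  # on NA-topology families the focal/host pair is the nearest pair
  set.seed(2)
  cfg <- sim_config(n_families = 60,
                    topology_proportions = c(1, 0, 0),
                    sequence_length = 150)
  d <- simulate_dataset(cfg)
  p_dist <- function(x, y)
    mean(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  fams <- unique(d$truth$family_id)
  d_NA <- d_NP <- d_AP <- numeric(length(fams))
  for (k in seq_along(fams)) {
    sN <- d$proteomes$N$sequences[[paste0(fams[k], "_N")]]
    sA <- d$proteomes$A$sequences[[paste0(fams[k], "_A")]]
    sP <- d$proteomes$P$sequences[[paste0(fams[k], "_P")]]
    d_NA[k] <- p_dist(sN, sA); d_NP[k] <- p_dist(sN, sP)
    d_AP[k] <- p_dist(sA, sP)
  }
  expect_lt(mean(d_NA), mean(d_NP))
  expect_lt(mean(d_NA), mean(d_AP))
  # sister pair divergence tracks 2*terminal, cross pairs 2*(terminal+internal)
  expect_lt(abs(mean(d_NA) - expected_p_distance(0.6)), 0.03)
  expect_lt(abs(mean(d_NP) - expected_p_distance(1.2)), 0.03)
})

test_that("sim_config validates proportions and counts", {
  expect_error(sim_config(topology_proportions = c(0.5, 0.5, 0.1)),
               "summing to 1")
  expect_error(sim_config(n_families = -1), "non-negative")
  expect_error(sim_config(sequence_length = 0), "positive")
})
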