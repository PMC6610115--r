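sc <- scoring_scheme()

test_that("toolkit definitions enforce their invariants", {
  refs <- proteome("ref", "GeneA_ref", sample_root_sequence(60, seed = 1))
  genes <- data.frame(gene = "GeneA", category = "c1")
  tk <- toolkit_definition("tk", genes, refs,
                           c(GeneA_ref = "GeneA"))
  expect_s3_class(tk, "toolkit_definition")
  expect_error(
    toolkit_definition("tk", data.frame(gene = c("A", "A"),
                                        category = "c"),
                       refs, c(GeneA_ref = "A")),
    "unique")
  expect_error(
    toolkit_definition("tk", genes, refs, c(GeneA_ref = "GeneA"),
                       decoys = refs,
                       decoy_gene = c(GeneA_ref = "GeneA")),
    "disjoint")
  expect_error(
    toolkit_definition("tk", data.frame(gene = c("GeneA", "GeneB"),
                                        category = "c"),
                       refs, c(GeneA_ref = "GeneA")),
    "GeneB")
})

test_that("an exact reference copy is called present", {
  sim <- simulate_toolkit(data.frame(gene = "GeneA", present = TRUE,
                                     decoy_distance = NA_real_),
                          sequence_length = 150, carrier_distance = 0,
                          master_seed = 5L)
  call <- screen_gene(sim$toolkit, "GeneA", sim$proteome, sc)
  expect_true(call$present)
  expect_equal(call$candidate_id, "cand_GeneA")
  expect_equal(call$nearest_label, "reference")
})

test_that("a candidate nearer the decoy paralog is rejected and named", {
  sim <- simulate_toolkit(rec8_plan(decoy_distance = 1.0),
                          sequence_length = 250, master_seed = 6L)
  call <- screen_gene(sim$toolkit, "Rec8", sim$proteome, sc)
  expect_false(call$present)
  expect_false(is.na(call$candidate_id))  # a homolog was found...
  expect_equal(call$nearest_label, "decoy")  # ...but it is the cohesin decoy
  expect_equal(call$nearest_id, "Rec8_decoy")
})

test_that("absent genes with no homolog give no candidate; empty proteome warns", {
  sim <- simulate_toolkit(data.frame(gene = "GeneB", present = FALSE,
                                     decoy_distance = NA_real_),
                          sequence_length = 150, master_seed = 7L)
  # proteome is empty: the only planned gene was absent without decoy
  expect_warning(call <- screen_gene(sim$toolkit, "GeneB", sim$proteome, sc),
                 "empty")
  expect_false(call$present)
  expect_true(is.na(call$candidate_id))
  # unrelated proteome: candidate fails the E-value filter
  set.seed(77)
  unrelated <- random_proteome("u", 3, len = 150)
  call2 <- screen_gene(sim$toolkit, "GeneB", unrelated, sc)
  expect_false(call2$present)
  expect_true(is.na(call2$candidate_id))
})

test_that("screening a toolkit returns one ordered call per gene", {
  plan <- rbind(meiosis_plan(), rec8_plan())
  sim <- simulate_toolkit(plan, sequence_length = 200, master_seed = 8L)
  calls <- screen_toolkit(sim$toolkit, sim$proteome, sc)
  expect_equal(nrow(calls), nrow(plan))
  expect_equal(calls$gene, plan$gene)
  expect_equal(calls$present, plan$present)
  # the X/- matrix follows the calls
  m <- presence_matrix(list(focal = calls))
  expect_equal(unname(m["focal", ]), ifelse(plan$present, "X", "-"))
})

test_that("the meiosis screen of the five-present fixture counts 3 absences", {
  tk <- read_toolkit(
    system.file("extdata", "meiosis_toolkit_synthetic.fasta",
                package = "tripletOrigin"),
    system.file("extdata", "meiosis_toolkit_synthetic.tsv",
                package = "tripletOrigin"))
  target <- read_fasta(
    system.file("extdata", "focal_meiosis_synthetic.fasta",
                package = "tripletOrigin"), "N")
  calls <- screen_toolkit(tk, target, sc)
  meiosis8 <- calls[calls$gene != "Rec8", ]
  expect_equal(sum(!meiosis8$present), 3L)
  expect_setequal(meiosis8$gene[!meiosis8$present],
                  c("Hop1", "Dmc1", "Mnd1"))
  # the Rec8 slot is occupied by a Rad21-like cohesin: absent via decoy
  rec8 <- calls[calls$gene == "Rec8", ]
  expect_false(rec8$present)
  expect_equal(rec8$nearest_label, "decoy")
  # 5 of 8 meiosis-specific genes present -> asexual under the >= 6 rule
  expect_equal(decide_sexual_reproduction(meiosis8), "asexual")
})

test_that("a decoy never yields a present call, at any threshold", {
  sim <- simulate_toolkit(rec8_plan(decoy_distance = 0.8),
                          sequence_length = 200, master_seed = 9L)
  for (thr in c(1e-2, 1e-5, 1e-10)) {
    sci <- scoring_scheme(evalue_threshold = thr)
    call <- screen_gene(sim$toolkit, "Rec8", sim$proteome, sci)
    expect_false(call$present)
  }
})

test_that("present counts never grow when the E-value threshold tightens", {
  plan <- rbind(meiosis_plan(), rec8_plan())
  sim <- simulate_toolkit(plan, sequence_length = 200,
                          carrier_distance = 0.6, master_seed = 10L)
  thresholds <- c(1e-2, 1e-5, 1e-20, 1e-60)
  presents <- vapply(thresholds, function(thr) {
    calls <- screen_toolkit(sim$toolkit, sim$proteome,
                            scoring_scheme(evalue_threshold = thr))
    sum(calls$present)
  }, integer(1))
  expect_true(all(diff(presents) <= 0))
})

test_that("the >= 6 rule separates sexual from asexual configurations", {
  expect_equal(decide_sexual_reproduction(rep(TRUE, 8)), "sexual")
  expect_equal(decide_sexual_reproduction(c(rep(TRUE, 5), rep(FALSE, 3))),
               "asexual")
  expect_equal(decide_sexual_reproduction(c(rep(TRUE, 6), rep(FALSE, 2))),
               "sexual")  # boundary inclusive
  expect_equal(decide_sexual_reproduction(logical(0)), "asexual")
  expect_error(decide_sexual_reproduction(rep(TRUE, 8), threshold = -1))
})

test_that("category totals sum the species column of the count table", {
  tab <- utils::read.delim(
    system.file("extdata", "flagellum_categories_synthetic.tsv",
                package = "tripletOrigin"))
  expect_equal(nrow(tab), 8L)
  expect_equal(category_totals(tab, "focal_nonmotile"), 29L)
  expect_equal(category_totals(tab, "relative_nonmotile"), 17L)
  expect_equal(category_totals(data.frame(category = character()), "x"), 0L)
  expect_error(category_totals(tab, "no_such_species"), "unknown")
})

test_that("motility ratio is a guarded quotient", {
  expect_equal(round(motility_ratio(104, 55), 2), 1.89)
  expect_equal(motility_ratio(7, 7), 1)
  expect_equal(motility_ratio(0, 55), 0)
  expect_error(motility_ratio(1, 0), "positive")
})
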