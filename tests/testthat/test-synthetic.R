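test_that("invalid panel configurations name the offending field", {
  expect_error(synthetic_panel_config(n_related = 0, n_irrelevant = 0,
                                      n_adversarial = 0),
               "n_related")
  expect_error(synthetic_panel_config(bit_density = 0), "bit_density")
  expect_error(synthetic_panel_config(label_noise = 0.6), "label_noise")
  expect_error(synthetic_panel_config(concept_jitter = -1), "concept_jitter")
})

test_that("panel generation is a pure function of the seed", {
  cfg <- synthetic_panel_config(d = 64, n_per_task = 100, label_noise = 0,
                                seed = 7)
  p1 <- make_panel(cfg)
  p2 <- make_panel(cfg)
  expect_identical(p1$source, p2$source)
  expect_identical(p1$target, p2$target)
  expect_identical(lapply(p1$concepts, `[[`, "beta"),
                   lapply(p2$concepts, `[[`, "beta"))
  # and generation does not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(make_panel(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("classes are balanced within one instance at zero label noise", {
  for (s in c(1, 2, 3)) {
    p <- make_panel(synthetic_panel_config(n_per_task = 99, label_noise = 0,
                                           n_irrelevant = 1L, seed = s))
    all_sets <- c(split(p$source$y, p$source$task_id),
                  list(target = p$target$y))
    for (y in all_sets) expect_lte(abs(sum(y) - sum(1 - y)), 1)
  }
})

test_that("concept geometry honours the relation invariants", {
  p <- make_panel(synthetic_panel_config(n_related = 2, n_irrelevant = 2,
                                         n_adversarial = 2, seed = 42))
  rep <- relatedness_report(p$concepts)
  expect_true(all(rep$cosine >= -1 & rep$cosine <= 1))
  expect_true(all(rep$cosine[rep$relation == "related"] >= 0.8))
  expect_true(all(rep$cosine[rep$relation == "adversarial"] <= -0.8))
  expect_true(all(abs(rep$cosine[rep$relation == "irrelevant"]) <= 0.2))
  # all concepts unit norm
  for (cc in p$concepts) expect_equal(sum(cc$beta^2), 1, tolerance = 1e-12)
})

test_that("relatedness_report handles identity, negation and errors", {
  beta <- c(1, 0, 0)
  concepts <- list(
    target = list(task_id = "target", beta = beta, relation = "target"),
    same = list(task_id = "same", beta = beta, relation = "related"),
    neg = list(task_id = "neg", beta = -beta, relation = "adversarial"))
  rep <- relatedness_report(concepts)
  expect_equal(rep$cosine[rep$task_id == "same"], 1)
  expect_equal(rep$cosine[rep$task_id == "neg"], -1)
  expect_equal(nrow(relatedness_report(concepts["target"])), 0)
  expect_error(relatedness_report(concepts[c("same", "neg")]), "target")
})

test_that("related task sequences share at least 70% of positions", {
  p <- make_panel(synthetic_panel_config(n_related = 3, seed = 9,
                                         seq_len = 60))
  tgt <- strsplit(p$concepts$target$sequence, "")[[1]]
  for (cc in p$concepts) {
    if (cc$relation != "related") next
    other <- strsplit(cc$sequence, "")[[1]]
    expect_gte(mean(tgt == other), 0.7)
  }
})

test_that("a noise-free target task is perfectly ranked by its latent score", {
  p <- make_panel(synthetic_panel_config(label_noise = 0, seed = 7))
  scores <- as.numeric(p$target$X %*% p$concepts$target$beta)
  expect_equal(auc_bruteforce(scores, p$target$y), 1.0)
  expect_equal(roc_auc(scores, p$target$y), 1.0)
})

test_that("panels round-trip through the on-disk format", {
  p <- make_panel(synthetic_panel_config(d = 16, n_per_task = 10,
                                         seq_len = 5, seed = 3))
  dir <- withr::local_tempdir()
  write_panel(p, dir)
  expect_true(all(file.exists(file.path(dir, c("instances.tsv",
                                               "sequences.fasta",
                                               "concepts.json")))))
  q <- read_panel(dir)
  expect_equal(q$source$X, p$source$X, ignore_attr = TRUE)
  expect_equal(q$source$y, p$source$y)
  expect_equal(q$target$compound_key, p$target$compound_key)
  expect_equal(q$concepts$target$beta, p$concepts$target$beta,
               tolerance = 1e-12)
  expect_equal(q$concepts$related_1$sequence, p$concepts$related_1$sequence)
})
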