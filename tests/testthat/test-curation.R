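test_that("Ki aggregation applies the geometric mean and the ratio rule", {
  expect_equal(aggregate_ki(c(100, 400)), 200)
  expect_equal(aggregate_ki(500), 500)
  expect_true(is.na(aggregate_ki(c(50, 600))))   # ratio 12 > 10: discarded
  expect_error(aggregate_ki(numeric(0)))
  expect_error(aggregate_ki(c(10, -1)), "positive")
})

test_that("Ki aggregation is permutation-invariant and scale-equivariant", {
  set.seed(1)
  for (i in 1:20) {
    v <- exp(runif(sample(1:5, 1), log(10), log(90)))  # ratio always <= 9
    expect_equal(aggregate_ki(v), aggregate_ki(rev(v)))
    expect_equal(aggregate_ki(3.7 * v), 3.7 * aggregate_ki(v),
                 tolerance = 1e-12)
  }
})

test_that("activity binarization is strict at the potency threshold", {
  expect_identical(binarize(500), 1L)
  expect_identical(binarize(1000), 0L)   # boundary labelled inactive
  expect_identical(binarize(10000), 0L)
  expect_identical(binarize(c(999.99, 1000.01)), c(1L, 0L))
  expect_error(binarize(-5), "positive")
})

test_that("sequence encoding is one-hot, padded and validated", {
  v <- encode_sequence("A", max_len = 2)
  expect_length(v, 42)
  expect_equal(sum(v[1:21]), 1)
  expect_equal(sum(v[22:42]), 0)
  expect_equal(encode_sequence("", max_len = 4), numeric(84))
  expect_error(encode_sequence("ACZ", max_len = 4), "position 3")
  # distinct equal-length sequences differ in at least 2 positions
  e1 <- encode_sequence("ACDE", max_len = 4)
  e2 <- encode_sequence("ACDF", max_len = 4)
  expect_gte(sum(e1 != e2), 2)
  # truncation keeps the output length fixed
  expect_length(encode_sequence(strrep("A", 99), max_len = 8), 8 * 21)
})

test_that("source assembly excludes the target and optionally shared compounds", {
  rec <- toy_records()
  s1 <- assemble_source(rec, "A", remove_overlap = FALSE)
  expect_setequal(unique(s1$task_id), "B")
  expect_setequal(s1$compound_key, c("c1", "c2", "c3"))
  # c2 is measured on the target task A, so overlap removal drops it
  s2 <- assemble_source(rec, "A", remove_overlap = TRUE)
  expect_setequal(s2$compound_key, c("c1", "c3"))
  expect_length(intersect(s2$compound_key,
                          rec$compound_key[rec$task_id == "A"]), 0)
  # no shared compounds => removal is a no-op
  rec2 <- rec[!(rec$compound_key == "c2" & rec$task_id == "B")]
  expect_identical(assemble_source(rec2, "A", TRUE),
                   assemble_source(rec2, "A", FALSE))
  expect_error(assemble_source(rec, "Z"), "unknown target")
})

test_that("stratified splits use largest-remainder counts and partition exactly", {
  set.seed(2)
  X <- matrix(rbinom(100 * 8, 1, 0.3), 100, 8)
  y <- c(rep(1, 30), rep(0, 70))
  S <- matrix(0, 100, 21)
  task <- instance_set(X, y, rep("t", 100), sprintf("c%03d", 1:100), S)
  sp <- stratified_split(task, 50, seed = 5)
  expect_equal(length(sp$train), 50)
  expect_equal(sum(sp$train$y), 15)           # 50 * 30/100
  expect_equal(sum(sp$train$y == 0), 35)
  # exact partition: no loss, no duplication
  expect_setequal(c(sp$train$compound_key, sp$test$compound_key),
                  task$compound_key)
  expect_length(intersect(sp$train$compound_key, sp$test$compound_key), 0)
  # determinism
  sp2 <- stratified_split(task, 50, seed = 5)
  expect_identical(sp$train$compound_key, sp2$train$compound_key)
  expect_error(stratified_split(task, 100, seed = 1), "smaller")
  one_class <- task[task$y == 1]
  expect_error(stratified_split(one_class, 5, seed = 1), "classes")
})

test_that("the curation pipeline aggregates, filters and labels a raw table", {
  raw <- data.frame(
    compound_key = c("c1", "c1", "c2", "c2", "c3", "c4"),
    target_id = c("A", "A", "A", "A", "A", "A"),
    ki_nM = c(100, 400, 50, 600, 800, 2000),
    mass_da = c(300, 300, 400, 400, 1200, 500))
  cur <- curate_activities(raw)
  # c1: geometric mean 200 -> active; c2: ratio 12 discarded; c3: mass filter
  expect_setequal(cur$compound_key, c("c1", "c4"))
  expect_equal(cur$ki_nM[cur$compound_key == "c1"], 200)
  expect_equal(cur$y[cur$compound_key == "c1"], 1L)
  expect_equal(cur$y[cur$compound_key == "c4"], 0L)
  rep <- active_fraction_report(cur)
  expect_equal(rep$active_fraction, 0.5)
})

test_that("build_instances joins featurizer and sequence encodings", {
  cur <- data.frame(compound_key = c("c1", "c2"), target_id = c("A", "B"),
                    ki_nM = c(10, 5000), y = c(1L, 0L))
  inst <- build_instances(cur, c(A = "ACD", B = "WYK"),
                          featurizer = hashed_featurizer(d = 32, n_bits = 4),
                          max_len = 5)
  expect_equal(dim(inst$X), c(2L, 32L))
  expect_equal(ncol(inst$S), 5 * 21)
  expect_true(all(inst$X %in% c(0, 1)))
  # same key always hashes to the same fingerprint
  inst2 <- build_instances(cur, c(A = "ACD", B = "WYK"),
                           featurizer = hashed_featurizer(d = 32, n_bits = 4),
                           max_len = 5)
  expect_identical(inst$X, inst2$X)
  expect_error(build_instances(cur, c(A = "ACD")), "sequence")
})
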