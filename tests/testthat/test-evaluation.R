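# stub models exercised through the predict() generic
make_stub <- function(class_levels, prob_fn) {
  structure(list(class_levels = class_levels, prob_fn = prob_fn),
            class = "stub_classifier")
}
predict.stub_classifier <- function(object, clips, ...) {
  t(vapply(clips, object$prob_fn, numeric(length(object$class_levels))))
}
registerS3method("predict", "stub_classifier", predict.stub_classifier,
                 envir = asNamespace("stats"))

stub_records <- function(labels, t_len = 12, n = 6, seed = 1) {
  set.seed(seed)
  lapply(seq_along(labels), function(i)
    roi_ts(matrix(rnorm(t_len * n), t_len, n), paste0("sub", i), "ses1",
           labels[i]))
}

test_that("a perfect stub model scores accuracy 1 and per-class accuracies", {
  labels <- c("a", "a", "b", "b", "b")
  recs <- stub_records(labels)
  # the stub encodes the truth through record order via a closure counter
  counter <- new.env()
  counter$i <- 0L
  stub <- make_stub(c("a", "b"), function(clip) {
    counter$i <- counter$i + 1L
    if (labels[counter$i] == "a") c(1, 0) else c(0, 1)
  })
  rep <- evaluate(stub, recs, 10)
  expect_equal(rep$accuracy, 1.0)
  expect_equal(unname(rep$per_class_accuracy), c(1, 1))
  expect_equal(rep$n_records, 5L)
  expect_equal(rep$n_frames_used, 10L)
})

test_that("a uniform stub predicts the first class everywhere", {
  labels <- c("a", "a", "a", "b")
  recs <- stub_records(labels)
  stub <- make_stub(c("a", "b"), function(clip) c(0.5, 0.5))
  rep <- evaluate(stub, recs, 5)
  expect_equal(rep$accuracy, 0.75)  # prevalence of the tie-broken class "a"
  expect_true(all(rep$predicted == "a"))
})

test_that("single-frame evaluation is legal and record length is checked", {
  model <- tiny_model()
  recs <- stub_records(c("class1", "class2"), t_len = 8, n = 20)
  rep <- evaluate(model, recs, 1)
  expect_equal(rep$n_frames_used, 1L)
  expect_error(evaluate(model, recs, 9), "sub1")
})

test_that("evaluation is deterministic for a fixed model", {
  model <- tiny_model()
  recs <- stub_records(c("class1", "class2", "class1"), t_len = 10, n = 20)
  expect_identical(evaluate(model, recs, 6), evaluate(model, recs, 6))
})

test_that("leave-one-site-out trains one fold per site on the other sites", {
  cohort <- tiny_cohort(seed = 5, n_sites = 2, site_effect = 0.3,
                        group_effect = 0.5)
  cv <- leave_one_site_out(cohort$records,
                           cgcn_model_factory(tiny_config()),
                           tiny_train_config(max_epochs = 2), k = 3,
                           n_frames_eval = 20)
  expect_s3_class(cv, "cv_report")
  expect_equal(cv$scheme, "leave_one_site_out")
  expect_named(cv$per_fold, c("site1", "site2"))
  accs <- vapply(cv$per_fold, function(r) r$accuracy, numeric(1))
  expect_equal(cv$mean_accuracy, mean(accs))
  expect_equal(cv$min_accuracy, min(accs))
  expect_equal(cv$max_accuracy, max(accs))
  expect_error(leave_one_site_out(cohort$records[1:4],
                                  cgcn_model_factory(tiny_config()),
                                  tiny_train_config(), 3, 20),
               "at least 2 sites")
})

test_that("held-out records cannot influence a fold's graph or weights", {
  cohort <- tiny_cohort(seed = 6, n_sites = 2, site_effect = 0.3,
                        group_effect = 0.5)
  sites <- vapply(cohort$records, function(r) r$site_label, character(1))
  train_rec <- cohort$records[sites == "site1"]
  test_rec <- cohort$records[sites == "site2"]
  mutated <- lapply(test_rec, function(r) { r$signals <- r$signals * 10 + 7; r })
  cfg <- tiny_train_config(max_epochs = 2)
  f1 <- cgcn:::.run_fold(train_rec, test_rec,
                         cgcn_model_factory(tiny_config()), cfg, 3, 20, seed = 1)
  f2 <- cgcn:::.run_fold(train_rec, mutated,
                         cgcn_model_factory(tiny_config()), cfg, 3, 20, seed = 1)
  expect_identical(f1$graph$neighbors, f2$graph$neighbors)
  expect_identical(f1$result$best_model$params, f2$result$best_model$params)
})

test_that("stratified folds preserve strata and keep subjects whole", {
  recs <- list()
  for (s in 1:100)
    recs[[s]] <- roi_ts(matrix(rnorm(20), 10, 2), sprintf("sub%03d", s),
                        "ses1", "c1", "site1")
  folds <- stratified_subject_folds(recs, 10, seed = 1)
  expect_equal(as.vector(table(folds)), rep(10L, 10))

  cohort <- tiny_cohort(seed = 7, n_classes = 2, n_sites = 2, n_subjects = 12)
  for (seed in 1:20) {
    f <- stratified_subject_folds(cohort$records, 2, seed = seed)
    subj <- vapply(cohort$records, function(r) r$subject_id, character(1))
    # every record of a subject maps to one fold; folds partition subjects
    expect_length(f, 12)
    expect_setequal(names(f), unique(subj))
    # strata balanced within one subject of each other
    info <- unique(data.frame(
      s = subj,
      site = vapply(cohort$records, function(r) r$site_label, character(1)),
      cls = vapply(cohort$records, function(r) r$class_label, character(1))))
    for (st in split(info$s, paste(info$site, info$cls))) {
      counts <- table(factor(f[st], levels = 1:2))
      expect_lte(max(counts) - min(counts), 1)
    }
  }
  expect_identical(stratified_subject_folds(cohort$records, 2, seed = 3),
                   stratified_subject_folds(cohort$records, 2, seed = 3))
  expect_error(stratified_subject_folds(cohort$records, 5, seed = 1),
               "smallest")
})

test_that("stratified k-fold trains and reports per fold", {
  cohort <- tiny_cohort(seed = 8, n_classes = 2, group_effect = 0.5)
  cv <- stratified_kfold(cohort$records, 2,
                         cgcn_model_factory(tiny_config()),
                         tiny_train_config(max_epochs = 2), k = 3,
                         n_frames_eval = 20, seed = 4)
  expect_equal(cv$scheme, "stratified_kfold")
  expect_length(cv$per_fold, 2)
  expect_equal(sum(vapply(cv$per_fold, function(r) r$n_records, integer(1))),
               length(cohort$records))
})

test_that("compare_graphs emits one row per combination, deterministically", {
  cohort <- tiny_cohort(seed = 9, group_effect = 0.5)
  ses <- vapply(cohort$records, function(r) r$session_id, character(1))
  tr <- cohort$records[ses == "ses01"]
  te <- cohort$records[ses == "ses02"]
  cfg <- tiny_train_config(max_epochs = 2)
  tab <- compare_graphs(tr, te, k_values = c(2, 3),
                        model_factory = cgcn_model_factory(tiny_config()),
                        train_cfg = cfg, seeds = c(1, 2), n_frames_eval = 20)
  expect_equal(nrow(tab), 2 * 2 * 2)
  expect_setequal(unique(tab$graph_kind), c("connectivity", "random"))
  tab2 <- compare_graphs(tr, te, k_values = 2,
                         graph_kinds = "connectivity",
                         model_factory = cgcn_model_factory(tiny_config()),
                         train_cfg = cfg, seeds = 1, n_frames_eval = 20)
  expect_equal(tab2$accuracy,
               tab$accuracy[tab$graph_kind == "connectivity" & tab$k == 2 &
                              tab$seed == 1])
})
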