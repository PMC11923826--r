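# A small planted simulation fitted once and reused across blocks.
quick <- local({
  params <- synth_params(n_proteins = 60)
  proteome <- generate_proteome(params, seed = 101)
  planted <- plant_labels(proteome, params, seed = 102)
  ds <- planted$features
  ds$label <- planted$truth$label
  hp <- palm_hyperparams(interaction_depth = 6, n_trees = 150,
                         shrinkage = 0.1, cv_folds = 5, seed = 3)
  model <- train_palm_model(ds, hp, cv = FALSE)
  list(params = params, proteome = proteome, ds = ds, hp = hp,
       model = model)
})

test_that("evaluate() agrees with direct confusion-matrix enumeration", {
  set.seed(17)
  thresholds <- seq(0, 1, by = 0.01)
  for (rep in 1:100) {
    n <- sample(20:60, 1)
    scores <- runif(n)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    for (t in sample(thresholds, 7)) {
      got <- confusion_at(scores, labels, t)
      want <- oracle_confusion(scores, labels, t)
      expect_equal(got$precision, unname(want["precision"]),
                   tolerance = 1e-9)
      expect_equal(got$recall, unname(want["recall"]), tolerance = 1e-9)
      expect_equal(got$f1, unname(want["f1"]), tolerance = 1e-9)
      expect_equal(got$mcc, unname(want["mcc"]), tolerance = 1e-9)
      expect_equal(c(got$tp, got$fp, got$fn, got$tn),
                   unname(want[c("tp", "fp", "fn", "tn")]))
    }
  }
})

test_that("MCC reproduces the closed-form example and stays within [-1, 1]", {
  # TP=8 FP=2 FN=1 TN=10 -> 78 / sqrt(11880)
  scores <- c(rep(0.9, 8), rep(0.9, 2), rep(0.1, 1), rep(0.1, 10))
  labels <- c(rep(1, 8), rep(0, 2), rep(1, 1), rep(0, 10))
  got <- confusion_at(scores, labels, 0.5)
  expect_equal(got$mcc, 78 / sqrt(11880), tolerance = 1e-9)
  expect_equal(got$mcc, 0.7156, tolerance = 1e-4)
  set.seed(18)
  for (i in 1:20) {
    s <- runif(30); y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    m <- confusion_at(s, y, 0.5)$mcc
    expect_true(m >= -1 && m <= 1)
  }
})

test_that("ROC AUC (rank statistic) matches pROC and the PR AUC of a no-skill classifier equals prevalence", {
  skip_if_not_installed("pROC")
  set.seed(19)
  for (i in 1:20) {
    n <- sample(30:80, 1)
    s <- runif(n); y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    ref <- suppressMessages(as.numeric(pROC::auc(y, s, direction = "<")))
    expect_equal(roc_auc(s, y), ref, tolerance = 1e-9)
  }
  # uniform-random scores, prevalence pi -> PR AUC ~ pi
  set.seed(20)
  n <- 4000; prev <- 0.2
  y <- rbinom(n, 1, prev)
  s <- runif(n)
  expect_equal(pr_curve(s, y)$auc, prev, tolerance = 0.05)
  # perfect separation
  yp <- c(rep(1, 10), rep(0, 30))
  sp <- c(runif(10, 0.8, 1), runif(30, 0, 0.2))
  expect_equal(pr_curve(sp, yp)$auc, 1.0, tolerance = 1e-9)
  expect_equal(confusion_at(sp, yp, 0.5)$mcc, 1.0)
  expect_equal(roc_auc(sp, yp), 1.0)
})

test_that("training is deterministic, refuses one-class input, and scores are order-equivariant", {
  m2 <- train_palm_model(quick$ds, quick$hp, cv = FALSE)
  p1 <- predict_palm(quick$model, quick$ds)
  p2 <- predict_palm(m2, quick$ds)
  expect_identical(p1$score, p2$score)
  expect_true(all(p1$score >= 0 & p1$score <= 1))

  one <- quick$ds[quick$ds$label == "negative", ]
  expect_error(train_palm_model(one, quick$hp), "both classes")

  # permuting rows permutes scores identically
  set.seed(23)
  perm <- sample(nrow(quick$ds))
  pp <- predict_palm(quick$model, quick$ds[perm, ])
  expect_equal(pp$score, p1$score[perm])

  # identical rows get identical scores
  same <- quick$ds[rep(1L, 5), ]
  expect_length(unique(predict_palm(quick$model, same)$score), 1L)
})

test_that("grid tuning returns the single grid point and enforces stratification", {
  sub <- quick$ds[quick$ds$accession %in%
                    unique(quick$ds$accession)[1:30], ]
  tuned <- tune_palm_grid(sub,
                          data.frame(interaction_depth = 4,
                                     n_trees = 60, shrinkage = 0.2),
                          cv_folds = 3, seed = 9)
  expect_equal(tuned$best$interaction_depth, 4L)
  expect_equal(tuned$best$n_trees, 60L)
  expect_equal(tuned$table$cv_auc_mean,
               sort(tuned$table$cv_auc_mean, decreasing = TRUE))
  tiny <- quick$ds[c(which(quick$ds$label == "positive")[1:2],
                     which(quick$ds$label == "negative")[1:2]), ]
  expect_error(tune_palm_grid(tiny, data.frame(n_trees = 10),
                              cv_folds = 5, seed = 1),
               "too few observations")
})

test_that("ranks are a permutation with monotone threshold counts and novelty arithmetic", {
  scores <- predict_palm(quick$model, quick$ds)
  rt <- rank_and_threshold(scores)
  expect_setequal(rt$ranked$rank, seq_len(nrow(scores)))
  expect_true(all(diff(rt$counts$n_above) <= 0))
  # known-site list subtracts from the novel tally
  top <- rt$ranked[rt$ranked$score > 0.75, c("accession", "position")]
  if (nrow(top) >= 2) {
    known <- top[1:2, ]
    rt2 <- rank_and_threshold(scores, known = known)
    expect_equal(rt2$novel, nrow(top) - 2L)
    expect_equal(rt2$n_known_above_top, 2L)
  }
  rt3 <- rank_and_threshold(scores, known = NULL)
  expect_equal(rt3$novel, sum(scores$score > 0.75))
  # printed-count identity: 1884 above high with 293 known leaves 1591
  fake <- tibble::tibble(accession = sprintf("A%04d", 1:2000),
                         position = 1L,
                         score = c(rep(0.9, 1884), rep(0.1, 116)))
  kn <- fake[1:293, c("accession", "position")]
  expect_equal(rank_and_threshold(fake, known = kn)$novel, 1591L)
})

test_that("external score ingestion is apples-to-apples", {
  scores <- predict_palm(quick$model, quick$ds)
  own <- evaluate_scores(scores$score, quick$ds$label)
  ing <- ingest_external_scores(scores, quick$ds)
  expect_equal(ing$report$roc_auc, own$roc_auc)
  expect_equal(ing$report$pr_auc, own$pr_auc)
  expect_equal(ing$n_matched, nrow(quick$ds))
  # half-coverage external table evaluates on the intersection
  half <- scores[seq_len(nrow(scores) %/% 2), ]
  ing2 <- ingest_external_scores(half, quick$ds)
  expect_equal(ing2$n_matched, nrow(half))
  expect_equal(nrow(ing2$unmatched), nrow(quick$ds) - nrow(half))
  # constant scores give MCC 0 at every threshold
  const <- scores; const$score <- 0.5
  ing3 <- ingest_external_scores(const, quick$ds)
  expect_true(all(ing3$report$by_threshold$mcc == 0))
})

test_that("model archives round-trip and refuse nothing on matching registries", {
  dir <- withr::local_tempdir()
  save_palm_model(quick$model, dir)
  expect_true(file.exists(file.path(dir, "model.json")))
  back <- load_palm_model(dir)
  p0 <- predict_palm(quick$model, quick$ds)
  p1 <- predict_palm(back, quick$ds)
  expect_equal(p1$score, p0$score, tolerance = 1e-12)
  expect_equal(back$hyperparams$n_trees, quick$hp$n_trees)
})

test_that("cys_scan reproduces native-Cys scores and skips ineligible positions", {
  p <- quick$proteome[[1]]
  scan <- cys_scan(quick$model, p)
  expect_lte(nrow(scan), nchar(p$sequence))
  expect_true(all(scan$score >= 0 & scan$score <= 1))
  # landscape at a native Cys equals predict on the unmutated protein
  fz <- featurize_protein(p)$features
  if (nrow(fz) > 0) {
    native <- predict_palm(quick$model, fz)
    for (i in seq_len(nrow(native))) {
      expect_equal(scan$score[scan$position == native$position[i]],
                   native$score[i])
    }
  }
  # signal/intramembrane positions are absent
  segs <- p$segments
  ineligible <- unlist(lapply(which(segs$kind %in%
                                      c("Signal", "Intramembrane")),
                              function(i) segs$start[i]:segs$end[i]))
  expect_length(intersect(scan$position, ineligible), 0L)
})
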