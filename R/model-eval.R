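# Gradient-boosted-tree training, evaluation and application:
# stratified cross-validated tuning, probability scoring with
# rank/threshold summaries, precision-recall / F1 / Matthews metrics,
# and the in-silico cysteine-scanning design procedure.

# 32-bit FNV-1a over a string; used to fingerprint the feature
# registry so a model refuses mismatched feature tables.
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x1f"))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    # xor only touches the low byte since b < 256; avoids 32-bit
    # integer overflow in bitwXor()
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # modular multiply in doubles via 16-bit split (keeps all
    # intermediates below 2^53)
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (h0 * prime + ((h1 * prime) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Gradient-boosted-tree hyperparameters
#'
#' Defaults mirror the tuned configuration this model family ships
#' with: interaction depth 18, 2000 trees, shrinkage 0.08, minimum 5
#' observations per terminal node, 10-fold cross-validation.
#'
#' @param interaction_depth Maximum tree depth.
#' @param n_trees Number of boosting rounds.
#' @param shrinkage Learning rate.
#' @param min_obs_per_node Minimum observations in a terminal node.
#' @param cv_folds Folds for cross-validation (>= 2).
#' @param seed RNG seed for fold assignment and the booster.
#' @return Object of class `palm_hyperparams`.
#' @export
palm_hyperparams <- function(interaction_depth = 18L, n_trees = 2000L,
                             shrinkage = 0.08, min_obs_per_node = 5L,
                             cv_folds = 10L, seed = 1L) {
  stopifnot(interaction_depth >= 1, n_trees >= 1, shrinkage > 0,
            min_obs_per_node >= 1, cv_folds >= 2)
  structure(list(interaction_depth = as.integer(interaction_depth),
                 n_trees = as.integer(n_trees),
                 shrinkage = shrinkage,
                 min_obs_per_node = as.integer(min_obs_per_node),
                 cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "palm_hyperparams")
}

#' Encode a feature table as a numeric model matrix
#'
#' Columns follow [feature_registry()] order; categoricals are mapped
#' through [TOPOLOGY_KIND_LEVELS] and [TM_ORIENTATION_LEVELS].
#'
#' @param features Feature tibble from [featurize_proteome()].
#' @return Numeric matrix with one column per registry feature.
#' @export
build_model_matrix <- function(features) {
  reg <- feature_registry()
  missing_cols <- setdiff(reg$name, names(features))
  if (length(missing_cols) > 0L) {
    stop("feature table missing registry column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  m <- matrix(NA_real_, nrow = nrow(features), ncol = nrow(reg),
              dimnames = list(NULL, reg$name))
  for (nm in reg$name) {
    v <- features[[nm]]
    if (nm == "topology_kind") {
      v <- unname(TOPOLOGY_KIND_LEVELS[v])
    } else if (nm == "tm_orientation") {
      v <- unname(TM_ORIENTATION_LEVELS[v])
    }
    m[, nm] <- as.numeric(v)
  }
  m
}

.registry_hash <- function() fnv1a(feature_registry()$name)

.xgb_params <- function(hp) {
  list(
    objective = "binary:logistic",
    max_depth = hp$interaction_depth,
    eta = hp$shrinkage,
    min_child_weight = hp$min_obs_per_node,
    nthread = 1L,
    seed = hp$seed,
    tree_method = "exact"
  )
}

# Stratified fold assignment; errors if any fold would be one-class.
stratified_folds <- function(labels, k, seed) {
  stopifnot(k >= 2)
  y <- labels == "positive"
  if (sum(y) < k || sum(!y) < k) {
    stop("too few observations per class for ", k,
         "-fold stratified cross-validation")
  }
  fold <- integer(length(y))
  set.seed(seed)
  for (cls in c(TRUE, FALSE)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.fit_booster <- function(x, y01, hp, n_trees = hp$n_trees) {
  dm <- xgboost::xgb.DMatrix(x, label = y01)
  xgboost::xgb.train(params = .xgb_params(hp), data = dm,
                     nrounds = n_trees, verbose = 0)
}

#' Train the palmitoylation classifier
#'
#' Fits a gradient-boosted tree on the labeled feature table and
#' records a cross-validated ROC AUC summary. Training is
#' deterministic given the hyperparameter seed (single-threaded exact
#' tree construction).
#'
#' @param dataset Labeled dataset from [infer_negatives()] (feature
#'   columns + `label`).
#' @param hp A [palm_hyperparams()].
#' @param cv Compute the cross-validated AUC summary (default TRUE;
#'   disable for speed when tuning externally).
#' @return Object of class `palm_model`: booster, registry hash,
#'   hyperparameters, CV summary.
#' @export
train_palm_model <- function(dataset, hp = palm_hyperparams(),
                             cv = TRUE) {
  stopifnot("label" %in% names(dataset))
  y <- dataset$label
  if (length(unique(y)) < 2L) {
    stop("training requires both classes present")
  }
  x <- build_model_matrix(dataset)
  y01 <- as.integer(y == "positive")
  cv_summary <- NULL
  if (cv) {
    fold <- stratified_folds(y, hp$cv_folds, hp$seed)
    aucs <- vapply(seq_len(hp$cv_folds), function(f) {
      tr <- fold != f
      b <- .fit_booster(x[tr, , drop = FALSE], y01[tr], hp)
      p <- predict(b, xgboost::xgb.DMatrix(x[!tr, , drop = FALSE]))
      roc_auc(p, y01[!tr])
    }, numeric(1))
    cv_summary <- list(auc_mean = mean(aucs), auc_sd = stats::sd(aucs),
                       fold_auc = aucs)
  }
  booster <- .fit_booster(x, y01, hp)
  structure(list(
    booster = booster,
    registry = feature_registry()$name,
    registry_hash = .registry_hash(),
    hyperparams = hp,
    cv = cv_summary,
    version = as.character(utils::packageVersion("topopalm"))
  ), class = "palm_model")
}

#' @export
print.palm_model <- function(x, ...) {
  cat(sprintf("<palm_model> %d features (registry %s), depth %d, %d trees, shrinkage %g\n",
              length(x$registry), x$registry_hash,
              x$hyperparams$interaction_depth, x$hyperparams$n_trees,
              x$hyperparams$shrinkage))
  if (!is.null(x$cv)) {
    cat(sprintf("  %d-fold CV ROC AUC %.3f (sd %.3f)\n",
                x$hyperparams$cv_folds, x$cv$auc_mean, x$cv$auc_sd))
  }
  invisible(x)
}

#' Grid-search hyperparameter tuning
#'
#' Ranks every grid point by mean ROC AUC over stratified
#' cross-validation folds; deterministic given the seed (folds are
#' shared across grid points).
#'
#' @param dataset Labeled dataset.
#' @param grid Data frame with any of the columns `interaction_depth`,
#'   `n_trees`, `shrinkage`, `min_obs_per_node`; absent columns take
#'   the defaults of [palm_hyperparams()].
#' @param cv_folds Number of folds (default 10).
#' @param seed RNG seed.
#' @return List with `best` (a [palm_hyperparams()]) and `table` (grid
#'   + `cv_auc_mean`, `cv_auc_sd`, sorted best first).
#' @export
tune_palm_grid <- function(dataset, grid, cv_folds = 10L, seed = 1L) {
  stopifnot(nrow(grid) >= 1L)
  y <- dataset$label
  x <- build_model_matrix(dataset)
  y01 <- as.integer(y == "positive")
  fold <- stratified_folds(y, cv_folds, seed)
  defaults <- palm_hyperparams(cv_folds = cv_folds, seed = seed)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    hp <- defaults
    for (nm in intersect(names(grid),
                         c("interaction_depth", "n_trees", "shrinkage",
                           "min_obs_per_node"))) {
      hp[[nm]] <- grid[[nm]][g]
    }
    aucs <- vapply(seq_len(cv_folds), function(f) {
      tr <- fold != f
      b <- .fit_booster(x[tr, , drop = FALSE], y01[tr], hp)
      p <- predict(b, xgboost::xgb.DMatrix(x[!tr, , drop = FALSE]))
      roc_auc(p, y01[!tr])
    }, numeric(1))
    c(cv_auc_mean = mean(aucs), cv_auc_sd = stats::sd(aucs))
  })
  tab <- dplyr::bind_cols(tibble::as_tibble(grid),
                          tibble::as_tibble(do.call(rbind, res)))
  ord <- order(-tab$cv_auc_mean)
  tab <- tab[ord, , drop = FALSE]
  best <- defaults
  for (nm in intersect(names(grid),
                       c("interaction_depth", "n_trees", "shrinkage",
                         "min_obs_per_node"))) {
    best[[nm]] <- tab[[nm]][1]
  }
  list(best = palm_hyperparams(best$interaction_depth, best$n_trees,
                               best$shrinkage, best$min_obs_per_node,
                               cv_folds, seed),
       table = tab)
}

#' Score sites with a trained model
#'
#' @param model A `palm_model`.
#' @param features Feature tibble whose registry matches the model's
#'   (otherwise an error).
#' @return Tibble `accession`, `position`, `score` (probability of the
#'   positive class, in `[0, 1]`), one row per input row in input
#'   order.
#' @export
predict_palm <- function(model, features) {
  stopifnot(inherits(model, "palm_model"))
  if (!identical(fnv1a(feature_registry()$name), model$registry_hash) ||
      !identical(model$registry, feature_registry()$name)) {
    stop("feature registry mismatch: model was trained with registry ",
         model$registry_hash)
  }
  x <- build_model_matrix(features)
  tibble::tibble(
    accession = features$accession,
    position = features$position,
    score = as.numeric(predict(model$booster, xgboost::xgb.DMatrix(x)))
  )
}

#' Feature importance of a trained model
#'
#' @param model A `palm_model`.
#' @return Tibble `feature`, `gain`, sorted by decreasing gain;
#'   features the booster never used are absent.
#' @export
palm_feature_importance <- function(model) {
  imp <- xgboost::xgb.importance(model = model$booster)
  tibble::tibble(feature = imp$Feature, gain = imp$Gain)
}

#' ROC AUC by the rank statistic
#'
#' Mann-Whitney formulation with average ranks for ties; exact, no
#' curve interpolation.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1, logical, or
#'   `"positive"`/`"negative"`).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- .as_binary(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("ROC AUC requires both classes")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.as_binary <- function(labels) {
  if (is.character(labels)) {
    as.integer(labels == "positive")
  } else {
    as.integer(as.logical(labels))
  }
}

#' Precision-recall curve and trapezoidal PR AUC
#'
#' Threshold sweep over the distinct scores (ties grouped), yielding
#' one (recall, precision) point per distinct score plus a recall-0
#' anchor at the first precision; AUC by the trapezoidal rule over
#' recall.
#'
#' @inheritParams roc_auc
#' @return List with `curve` (tibble `threshold`, `recall`,
#'   `precision`) and `auc`.
#' @export
pr_curve <- function(scores, labels) {
  y <- .as_binary(labels)
  P <- sum(y == 1L)
  if (P == 0L) stop("PR curve requires at least one positive")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- y[ord]
  grp <- !duplicated(s)
  tp <- cumsum(y); fp <- cumsum(1L - y)
  last_of_group <- c(which(grp[-1L]) , length(s))
  tp <- tp[last_of_group]; fp <- fp[last_of_group]
  thr <- s[grp]
  recall <- tp / P
  precision <- tp / (tp + fp)
  r <- c(0, recall); p <- c(precision[1], precision)
  auc <- sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
  list(curve = tibble::tibble(threshold = thr, recall = recall,
                              precision = precision),
       auc = auc)
}

#' Confusion-matrix metrics at one threshold
#'
#' Predicted positive iff `score >= threshold`. Precision, recall and
#' F1 are 0 when their denominator is 0; MCC is 0 when any marginal is
#' 0 (degenerate predictor convention).
#'
#' @inheritParams roc_auc
#' @param threshold Score cutoff.
#' @return One-row tibble `threshold`, `tp`, `fp`, `fn`, `tn`,
#'   `precision`, `recall`, `f1`, `mcc`.
#' @export
confusion_at <- function(scores, labels, threshold) {
  y <- .as_binary(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  tn <- sum(pred == 0L & y == 0L)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  denom <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / denom
  tibble::tibble(threshold = threshold, tp = tp, fp = fp, fn = fn,
                 tn = tn, precision = precision, recall = recall,
                 f1 = f1, mcc = mcc)
}

#' Full metric report for a score vector
#'
#' ROC AUC, PR AUC, the F1-versus-threshold curve, and confusion
#' metrics (precision, recall, F1, MCC) at the named cutoffs.
#'
#' @inheritParams roc_auc
#' @param thresholds Score cutoffs for the threshold-indexed metrics
#'   (default 0.25 / 0.50 / 0.75).
#' @return Object of class `metric_report`: list with `roc_auc`,
#'   `pr_auc`, `pr_points`, `f1_curve`, `by_threshold`, `n`,
#'   `n_positive`.
#' @export
evaluate_scores <- function(scores, labels,
                            thresholds = c(0.25, 0.50, 0.75)) {
  y <- .as_binary(labels)
  if (length(unique(y)) < 2L) {
    stop("evaluation requires both classes present")
  }
  pr <- pr_curve(scores, y)
  sweep <- sort(unique(c(pr$curve$threshold, thresholds)))
  f1_curve <- dplyr::bind_rows(lapply(sweep, function(t) {
    confusion_at(scores, y, t)[, c("threshold", "f1")]
  }))
  structure(list(
    roc_auc = roc_auc(scores, y),
    pr_auc = pr$auc,
    pr_points = pr$curve,
    f1_curve = f1_curve,
    by_threshold = dplyr::bind_rows(
      lapply(thresholds, function(t) confusion_at(scores, y, t))),
    n = length(y),
    n_positive = sum(y == 1L)
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> n = %d (%d positive)\n", x$n, x$n_positive))
  cat(sprintf("  ROC AUC %.4f, PR AUC %.4f\n", x$roc_auc, x$pr_auc))
  bt <- x$by_threshold
  for (i in seq_len(nrow(bt))) {
    cat(sprintf("  t=%.2f: precision %.3f recall %.3f F1 %.3f MCC %.3f\n",
                bt$threshold[i], bt$precision[i], bt$recall[i],
                bt$f1[i], bt$mcc[i]))
  }
  invisible(x)
}

#' Rank scores and count sites above thresholds
#'
#' Ranks are 1 = highest score, ties broken by accession then position
#' (so the rank vector is always a permutation of 1..N). "Above" a
#' threshold means strictly greater. Novel sites are those above the
#' highest threshold not present in the known-site list.
#'
#' @param scores Tibble `accession`, `position`, `score`.
#' @param thresholds Ascending score cutoffs.
#' @param known Optional tibble `accession`, `position` of
#'   database-reported sites.
#' @return List with `ranked` (scores + `rank` + `band`, sorted by
#'   rank), `counts` (tibble `threshold`, `n_above`), `novel`
#'   (count above the top threshold not in `known`; `NA` without a
#'   `known` list is never returned -- an empty list gives
#'   `novel = n_above_top`), and `n_known_above_top`.
#' @export
rank_and_threshold <- function(scores,
                               thresholds = c(0.25, 0.50, 0.75),
                               known = NULL) {
  thresholds <- sort(thresholds)
  ord <- order(-scores$score, scores$accession, scores$position)
  ranked <- scores[ord, , drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))
  band <- vapply(ranked$score, function(s) sum(s > thresholds),
                 integer(1))
  ranked$band <- c("below_low", "low", "medium", "high")[band + 1L]
  counts <- tibble::tibble(
    threshold = thresholds,
    n_above = vapply(thresholds, function(t) sum(scores$score > t),
                     integer(1))
  )
  top <- thresholds[length(thresholds)]
  above_top <- scores[scores$score > top, , drop = FALSE]
  n_known <- if (is.null(known) || nrow(known) == 0L) {
    0L
  } else {
    sum(paste(above_top$accession, above_top$position) %in%
          paste(known$accession, known$position))
  }
  list(ranked = ranked, counts = counts,
       novel = nrow(above_top) - n_known,
       n_known_above_top = n_known)
}

#' Evaluate an external tool's per-site scores on the same labels
#'
#' Joins external scores onto the labeled dataset by (accession,
#' position) and computes the identical [evaluate_scores()] report so
#' comparisons are like for like; unmatched labeled sites are logged
#' and excluded.
#'
#' @param external Tibble `accession`, `position`, `score`.
#' @param dataset Labeled dataset (`accession`, `position`, `label`).
#' @inheritParams evaluate_scores
#' @return List with `report` (a `metric_report`), `n_matched`,
#'   `unmatched` (labeled sites without an external score).
#' @export
ingest_external_scores <- function(external, dataset,
                                   thresholds = c(0.25, 0.50, 0.75)) {
  key <- function(a, p) paste(a, p, sep = "@")
  i <- match(key(dataset$accession, dataset$position),
             key(external$accession, external$position))
  matched <- !is.na(i)
  list(
    report = evaluate_scores(external$score[i[matched]],
                             dataset$label[matched], thresholds),
    n_matched = sum(matched),
    unmatched = tibble::tibble(accession = dataset$accession[!matched],
                               position = dataset$position[!matched])
  )
}

#' In-silico cysteine-scanning mutagenesis
#'
#' For every eligible position of the protein, substitute a cysteine,
#' re-featurize that site in the mutated sequence and score it with
#' the trained model; native cysteines are scored as-is. Positions in
#' signal peptides, intramembrane segments or unannotated gaps are
#' reported as missing (absent from the landscape).
#'
#' @param model A `palm_model`.
#' @param protein A [protein_record()] with >= 1 TM segment.
#' @param k Window width per side.
#' @return Tibble `position`, `native_residue`, `score`,
#'   `topology_kind`, `interface_distance`, ascending by position.
#' @export
cys_scan <- function(model, protein, k = 5L) {
  L <- nchar(protein$sequence)
  rows <- list()
  for (pos in seq_len(L)) {
    native <- substr(protein$sequence, pos, pos)
    mut <- protein
    if (native != "C") {
      s <- protein$sequence
      substr(s, pos, pos) <- "C"
      mut$sequence <- s
    }
    r <- featurize_site(mut, pos, k)
    if (is.character(r)) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      position = pos, native_residue = native,
      features = list(r))
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(position = integer(),
                          native_residue = character(),
                          score = double(), topology_kind = character(),
                          interface_distance = integer()))
  }
  meta <- dplyr::bind_rows(lapply(rows, function(r) r[, 1:2]))
  feats <- dplyr::bind_rows(lapply(rows, function(r) r$features[[1]]))
  tibble::tibble(
    position = meta$position,
    native_residue = meta$native_residue,
    score = predict_palm(model, feats)$score,
    topology_kind = feats$topology_kind,
    interface_distance = feats$interface_distance
  )
}

#' Save / load a trained model as a versioned archive
#'
#' The archive is a directory holding the raw booster dump plus a JSON
#' metadata file (feature registry, hyperparameters, package version).
#' Loading verifies the registry against the installed package and
#' refuses a mismatch.
#'
#' @param model A `palm_model`.
#' @param dir Directory to create/populate.
#' @return `dir`, invisibly (for `save_palm_model`); a `palm_model`
#'   (for `load_palm_model`).
#' @export
save_palm_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  raw <- xgboost::xgb.save.raw(model$booster)
  writeBin(raw, file.path(dir, "booster.bin"))
  meta <- list(
    registry = model$registry,
    registry_hash = model$registry_hash,
    hyperparams = unclass(model$hyperparams),
    cv = model$cv,
    version = model$version
  )
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_palm_model
#' @export
load_palm_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$registry_hash, .registry_hash())) {
    stop("model registry ", meta$registry_hash,
         " does not match installed feature registry ",
         .registry_hash())
  }
  fsize <- file.info(file.path(dir, "booster.bin"))$size
  raw <- readBin(file.path(dir, "booster.bin"), "raw", n = fsize)
  hp <- meta$hyperparams
  structure(list(
    booster = xgboost::xgb.load.raw(raw),
    registry = meta$registry,
    registry_hash = meta$registry_hash,
    hyperparams = palm_hyperparams(hp$interaction_depth, hp$n_trees,
                                   hp$shrinkage, hp$min_obs_per_node,
                                   hp$cv_folds, hp$seed),
    cv = meta$cv,
    version = meta$version
  ), class = "palm_model")
}
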