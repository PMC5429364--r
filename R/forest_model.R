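# Random-forest training, per-residue scoring, cross-validation, the
# exhaustive feature-group combination search, and feature importances.

#' Forest configuration
#'
#' Hyperparameters of the per-residue random forest. Defaults follow the
#' tuned operating point: maximum tree depth 13, 500 trees for the final
#' model (50 suffice for the feature-selection stage at a ~5% cost in
#' performance), and a probability cutoff of 0.5 so that a residue is
#' called protean when at least half the trees vote positive. Split
#' criterion, features-per-split and bootstrap settings are the forest
#' library's defaults and are recorded in the trained model's metadata.
#'
#' @param n_trees number of trees (default 500).
#' @param max_depth maximum tree depth, 1-25 (default 13).
#' @param p_cut probability cutoff in `[0, 1]` (default 0.5, ties
#'   positive).
#' @param seed RNG seed for tree growing.
#' @param feature_groups subset of `1:7` selecting feature-group columns
#'   (default all).
#' @return Object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 500, max_depth = 13, p_cut = 0.5,
                          seed = 1, feature_groups = 1:7) {
  stopifnot(n_trees >= 1, max_depth >= 1, max_depth <= 25,
            p_cut >= 0, p_cut <= 1,
            length(feature_groups) >= 1, all(feature_groups %in% 1:7))
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 p_cut = p_cut, seed = as.integer(seed),
                 feature_groups = sort(unique(as.integer(feature_groups)))),
            class = "forest_config")
}

.group_columns <- function(group_index, groups) {
  sort(unlist(group_index[paste0("group", groups)], use.names = FALSE))
}

#' Train the random forest on residue feature vectors
#'
#' Grows a classification forest (majority vote over trees) on the
#' selected feature-group columns. Deterministic given the seed in
#' `config`.
#'
#' @param features numeric feature matrix (rows = residues), with a
#'   `group_index` attribute or an explicit `group_index` argument.
#' @param labels binary 0/1 vector, one per row.
#' @param config a [forest_config()].
#' @param group_index feature-group column map (see
#'   [feature_group_index()]).
#' @return Object of class `trained_model` holding the fitted forest,
#'   the column subset, the configuration and training metadata. Models
#'   trained through [train_corpus()] additionally carry the PSSM scaler
#'   and feature-extraction options, making prediction self-contained.
#' @export
train_forest <- function(features, labels, config = forest_config(),
                         group_index = attr(features, "group_index")) {
  stopifnot(nrow(features) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("training labels contain a single class")
  if (is.null(group_index)) stop("no feature group index available")
  cols <- .group_columns(group_index, config$feature_groups)
  x <- features[, cols, drop = FALSE]
  if (is.null(colnames(x))) colnames(x) <- paste0("f", cols)
  fit <- ranger::ranger(
    x = x, y = factor(labels, levels = c(0L, 1L)),
    num.trees = config$n_trees, max.depth = config$max_depth,
    seed = config$seed, num.threads = 1, importance = "impurity"
  )
  structure(list(
    forest = fit,
    config = config,
    columns = colnames(x),
    column_idx = cols,
    group_index = group_index,
    scaler = NULL,
    feature_opts = NULL,
    metadata = list(
      n_train = nrow(x),
      positive_fraction = mean(labels == 1L),
      ranger_defaults = list(splitrule = "gini",
                             mtry = floor(sqrt(ncol(x))),
                             replace = TRUE, sample_fraction = 1),
      trained = format(Sys.time(), "%Y-%m-%d %H:%M:%S")
    )
  ), class = "trained_model")
}

#' Train a self-contained model from a corpus
#'
#' Fits the PSSM scaler on the corpus, extracts features and trains the
#' forest, storing the scaler and extraction options with the model so
#' that [predict_corpus()] needs nothing else.
#'
#' @param corpus corpus list.
#' @param config a [forest_config()].
#' @param ... feature-extraction options passed to
#'   [extract_corpus_features()] (window size, disorder threshold, ...).
#' @return A `trained_model` carrying `scaler` and `feature_opts`.
#' @export
train_corpus <- function(corpus, config = forest_config(), ...) {
  scaler <- fit_pssm_scaler(lapply(corpus, `[[`, "pssm"))
  ext <- extract_corpus_features(corpus, scaler, ...)
  model <- train_forest(ext$features, ext$labels, config, ext$group_index)
  model$scaler <- scaler
  model$feature_opts <- list(...)
  model
}

#' Per-residue protean scores
#'
#' The score of a residue is the fraction of trees voting positive.
#'
#' @param model a `trained_model`.
#' @param features feature matrix whose columns cover the model's
#'   training columns.
#' @return Numeric scores in `[0, 1]`, one per row.
#' @export
predict_scores <- function(model, features) {
  if (!all(model$columns %in% colnames(features))) {
    if (ncol(features) == length(model$column_idx)) {
      x <- features
      colnames(x) <- model$columns
    } else if (max(model$column_idx) <= ncol(features)) {
      x <- features[, model$column_idx, drop = FALSE]
      colnames(x) <- model$columns
    } else {
      stop("feature columns do not match the trained model")
    }
  } else {
    x <- features[, model$columns, drop = FALSE]
  }
  pred <- predict(model$forest, data = x, predict.all = TRUE,
                  num.threads = 1)$predictions
  pos_idx <- which(model$forest$forest$levels == "1")
  rowMeans(pred == pos_idx)
}

#' Binary calls from scores
#'
#' A residue is called protean when its score reaches the cutoff: ties
#' at `p_cut` are positive (at the default 0.5 this is "50% or more of
#' the trees").
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param p_cut probability cutoff.
#' @return Integer 0/1 calls.
#' @export
classify <- function(scores, p_cut = 0.5) {
  stopifnot(all(scores >= 0 & scores <= 1))
  as.integer(scores >= p_cut)
}

#' Predict per-residue scores for whole proteins
#'
#' @param model a self-contained `trained_model` (from
#'   [train_corpus()]).
#' @param corpus corpus list of proteins with tracks.
#' @return data.frame `(protein_id, position, residue, protean_score,
#'   call)`.
#' @export
predict_corpus <- function(model, corpus) {
  if (is.null(model$scaler))
    stop("model carries no PSSM scaler; train it with train_corpus()")
  ext <- do.call(extract_corpus_features,
                 c(list(corpus, model$scaler), model$feature_opts))
  scores <- predict_scores(model, ext$features)
  data.frame(
    protein_id = ext$protein_id,
    position = ext$position,
    residue = unlist(lapply(corpus, function(p)
      strsplit(p$sequence, "")[[1]]), use.names = FALSE),
    protean_score = scores,
    call = classify(scores, model$config$p_cut),
    stringsAsFactors = FALSE
  )
}

#' Cluster-grouped cross-validation
#'
#' For each fold rotation, refits the PSSM scaler on the training split
#' only, trains on the other folds and scores the held-out fold, so that
#' every residue receives exactly one out-of-fold score.
#'
#' @param corpus corpus list.
#' @param folds a [build_folds()] assignment covering the corpus.
#' @param config a [forest_config()] (per-fold forests use seeds
#'   `config$seed + fold`).
#' @param ... feature-extraction options passed to
#'   [extract_corpus_features()].
#' @return data.frame `(protein_id, position, score, label, fold)` with
#'   one row per residue of the corpus.
#' @export
cross_validate <- function(corpus, folds, config = forest_config(), ...) {
  k <- attr(folds, "k")
  out <- vector("list", k)
  for (fold in seq_len(k)) {
    sp <- split_corpus(corpus, folds, fold)
    if (length(sp$test) == 0) next
    scaler <- fit_pssm_scaler(lapply(sp$train, `[[`, "pssm"))
    tr <- extract_corpus_features(sp$train, scaler, ...)
    te <- extract_corpus_features(sp$test, scaler, ...)
    cfg <- config
    cfg$seed <- config$seed + fold
    model <- train_forest(tr$features, tr$labels, cfg, tr$group_index)
    scores <- predict_scores(model, te$features)
    out[[fold]] <- data.frame(
      protein_id = te$protein_id, position = te$position,
      score = scores, label = te$labels, fold = fold,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' All non-empty feature-group subsets
#'
#' @return List of 127 integer vectors, every non-empty subset of
#'   `1:7`.
#' @export
all_group_subsets <- function() {
  out <- list()
  for (m in 1:127) {
    out[[m]] <- which(bitwAnd(m, bitwShiftL(1L, 0:6)) > 0)
  }
  out
}

#' Exhaustive feature-group combination search
#'
#' Evaluates all 127 non-empty subsets of the seven feature groups by
#' cross-validated MCC and F1 at the configured cutoff. Features are
#' extracted once per fold; each subset then trains on its column
#' selection only.
#'
#' @param corpus corpus list.
#' @param folds a [build_folds()] assignment.
#' @param config a [forest_config()]; the search conventionally uses a
#'   reduced tree count (e.g. 50, or 10 on small fixture corpora).
#' @param ... feature-extraction options.
#' @return data.frame with one row per subset: `groups` (e.g.
#'   `"1+3+7"`), `n_groups`, `mcc`, `f1`, `rank_mcc`, `rank_f1`.
#' @export
group_subset_search <- function(corpus, folds, config = forest_config(n_trees = 50),
                                ...) {
  k <- attr(folds, "k")
  prep <- lapply(seq_len(k), function(fold) {
    sp <- split_corpus(corpus, folds, fold)
    scaler <- fit_pssm_scaler(lapply(sp$train, `[[`, "pssm"))
    list(train = extract_corpus_features(sp$train, scaler, ...),
         test = extract_corpus_features(sp$test, scaler, ...))
  })
  subsets <- all_group_subsets()
  rows <- lapply(seq_along(subsets), function(si) {
    groups <- subsets[[si]]
    cfg <- config
    cfg$feature_groups <- groups
    scores <- NULL; labels <- NULL
    for (fold in seq_len(k)) {
      cfg$seed <- config$seed + fold
      model <- train_forest(prep[[fold]]$train$features,
                            prep[[fold]]$train$labels, cfg,
                            prep[[fold]]$train$group_index)
      s <- predict_scores(model, prep[[fold]]$test$features)
      scores <- c(scores, s)
      labels <- c(labels, prep[[fold]]$test$labels)
    }
    cc <- confusion(classify(scores, config$p_cut), labels)
    data.frame(groups = paste(groups, collapse = "+"),
               n_groups = length(groups),
               mcc = mcc(cc), f1 = f1(cc), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rank_mcc <- rank(-out$mcc, ties.method = "min")
  out$rank_f1 <- rank(-out$f1, ties.method = "min")
  rownames(out) <- NULL
  out
}

#' Feature importances
#'
#' Impurity-decrease importance accumulated over the trees of the
#' forest, normalized to sum to 1 over the included features, with the
#' feature-group of each column attached.
#'
#' @param model a `trained_model`.
#' @return data.frame `(feature, group, importance)` in training column
#'   order.
#' @export
feature_importance <- function(model) {
  imp <- model$forest$variable.importance
  imp <- pmax(imp, 0)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  group_of_col <- integer(max(unlist(model$group_index)))
  for (g in 1:7)
    group_of_col[model$group_index[[paste0("group", g)]]] <- g
  data.frame(feature = names(imp),
             group = group_of_col[model$column_idx],
             importance = as.numeric(imp),
             stringsAsFactors = FALSE)
}
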