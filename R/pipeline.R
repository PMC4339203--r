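#' Stack 2D envelope frames into a 3D volume
#'
#' Composes an ordered sequence of 2D RF-envelope frames into a 3D volume,
#' recording the in-plane pixel spacing and the slice spacing (e.g. 1 mm
#' step-wise probe movement) in the volume metadata. Frame order is
#' preserved: voxel (x, y, k) equals frame k at (x, y).
#'
#' @param frames list of numeric matrices, all the same dimension (>= 2).
#' @param slice_spacing distance between consecutive frames in mm.
#' @param pixel_spacing in-plane pixel spacing in mm (length 2).
#' @return An [envelope_volume()].
#' @export
reconstruct_volume <- function(frames, slice_spacing = 1,
                               pixel_spacing = c(1, 1)) {
  if (!is.list(frames) || length(frames) < 2L)
    stop_mnf("mnf_parameter_error", "'frames' must be a list of >= 2 matrices")
  d2 <- dim(frames[[1]])
  if (is.null(d2) || length(d2) != 2L)
    stop_mnf("mnf_parameter_error", "each frame must be a 2D matrix")
  for (k in seq_along(frames))
    if (!identical(dim(frames[[k]]), d2))
      stop_mnf("mnf_parameter_error",
               "frame %d has dimensions %s, expected %s", k,
               paste(dim(frames[[k]]), collapse = "x"),
               paste(d2, collapse = "x"))
  v <- array(unlist(frames, use.names = FALSE), c(d2, length(frames)))
  envelope_volume(v, spacing = c(pixel_spacing, slice_spacing))
}

#' Select informative slices by tumor area
#'
#' Keeps slice i iff its ROI area strictly exceeds the median slice area,
#' discarding thin peripheral sections whose texture cannot be reliably
#' characterized. If the strict rule would keep nothing (all areas equal),
#' all non-empty slices are kept with a warning.
#'
#' @param masks logical 3D array of per-slice ROI masks (slices along the
#'   third axis), or a list of logical matrices.
#' @return Integer vector of kept slice indices.
#' @export
select_slices <- function(masks) {
  if (is.list(masks)) {
    areas <- vapply(masks, function(m) sum(m != 0), numeric(1))
  } else {
    d <- dim(masks)
    if (is.null(d) || length(d) != 3L)
      stop_mnf("mnf_parameter_error",
               "'masks' must be a 3D array or list of matrices")
    areas <- apply(masks != 0, 3, sum)
  }
  if (all(areas == 0))
    stop_mnf("mnf_parameter_error", "all slice masks are empty")
  keep <- which(areas > median(areas))
  if (!length(keep)) {
    warning("all slice areas equal the median; keeping every non-empty slice")
    keep <- which(areas > 0)
  }
  keep
}

#' Gaussian naive-Bayes classifier
#'
#' Fits per-class, per-feature Gaussian class-conditionals (the
#' independence assumption of naive Bayes) with either observed class
#' frequencies or equal class priors. Zero-variance features are floored
#' at `var_floor` with a warning so a degenerate feature cannot produce
#' infinite likelihoods.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y class labels (factor or coercible; >= 2 classes, >= 2 samples
#'   each).
#' @param priors `"frequency"` (default) or `"equal"`.
#' @param var_floor minimum per-feature variance.
#' @return Object of class `nbc_model`.
#' @export
train_nbc <- function(x, y, priors = c("frequency", "equal"),
                      var_floor = 1e-9) {
  priors <- match.arg(priors)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L)
    stop_mnf("mnf_parameter_error", "need >= 2 classes")
  if (nrow(x) != length(y))
    stop_mnf("mnf_parameter_error", "nrow(x) must match length(y)")
  counts <- table(y)
  if (any(counts < 2L))
    stop_mnf("mnf_insufficient_data",
             "every class needs >= 2 samples (got: %s)",
             paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  cls <- levels(y)
  mean_m <- do.call(rbind, lapply(cls, function(cl)
    colMeans(x[y == cl, , drop = FALSE])))
  var_m <- do.call(rbind, lapply(cls, function(cl)
    apply(x[y == cl, , drop = FALSE], 2, var)))
  if (any(var_m < var_floor)) {
    warning("zero-variance feature(s): variance floored at ", var_floor)
    var_m[var_m < var_floor] <- var_floor
  }
  prior <- if (priors == "frequency") as.numeric(counts) / length(y) else
    rep(1 / length(cls), length(cls))
  structure(list(classes = cls, mean = mean_m, var = var_m,
                 prior = setNames(prior, cls), n_features = ncol(x)),
            class = "nbc_model")
}

#' @export
print.nbc_model <- function(x, ...) {
  cat(sprintf("<nbc_model> %d classes (%s), %d features, priors: %s\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              x$n_features,
              paste(signif(x$prior, 3), collapse = "/")))
  invisible(x)
}

#' Predict from a Gaussian naive-Bayes model
#'
#' @param object an `nbc_model`.
#' @param newdata numeric feature matrix.
#' @param type `"class"` for hard labels, `"posterior"` for the class
#'   posterior matrix.
#' @param ... unused.
#' @return Factor of predicted classes, or a posterior probability matrix.
#' @export
predict.nbc_model <- function(object, newdata,
                              type = c("class", "posterior"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop_mnf("mnf_parameter_error", "expected %d features, got %d",
             object$n_features, ncol(newdata))
  logp <- vapply(seq_along(object$classes), function(ci) {
    mu <- object$mean[ci, ]
    s2 <- object$var[ci, ]
    rowSums(-0.5 * (log(2 * pi * matrix(s2, nrow(newdata), ncol(newdata),
                                        byrow = TRUE)) +
                      sweep(newdata, 2, mu)^2 /
                        matrix(s2, nrow(newdata), ncol(newdata), byrow = TRUE))) +
      log(object$prior[ci])
  }, numeric(nrow(newdata)))
  logp <- matrix(logp, nrow = nrow(newdata))
  colnames(logp) <- object$classes
  if (type == "class")
    return(factor(object$classes[max.col(logp, ties.method = "first")],
                  levels = object$classes))
  post <- exp(logp - apply(logp, 1, max))
  post / rowSums(post)
}

#' Confusion-count classification metrics
#'
#' Computes the standard metric suite from positive-class confusion counts:
#' recall TP/(TP+FN), false-positive rate FP/(FP+TN), accuracy
#' (TP+TN)/total, precision TP/(TP+FP), F-measure (harmonic mean of
#' precision and recall), Jaccard index TP/(TP+FP+FN) and Dice coefficient
#' 2TP/(2TP+FP+FN).
#'
#' @param tp,fn,fp,tn confusion counts.
#' @return Named numeric vector of the seven count-based metrics.
#' @export
confusion_metrics <- function(tp, fn, fp, tn) {
  c(recall = tp / (tp + fn),
    fp_rate = fp / (fp + tn),
    accuracy = (tp + tn) / (tp + fn + fp + tn),
    precision = tp / (tp + fp),
    f_measure = 2 * tp / (2 * tp + fp + fn),
    j_index = tp / (tp + fp + fn),
    dice = 2 * tp / (2 * tp + fp + fn))
}

#' Rank-based ROC area
#'
#' Mann-Whitney estimate of the area under the ROC curve from scores for
#' the positive class, with the usual midrank handling of ties.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels class labels.
#' @param positive the positive class label.
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(scores, labels, positive) {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop_mnf("mnf_parameter_error", "need scores from both classes")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

metrics_from_predictions <- function(truth, pred, scores, positive) {
  cls <- levels(truth)
  per_class <- t(vapply(cls, function(p) {
    tp <- sum(pred == p & truth == p)
    fn <- sum(pred != p & truth == p)
    fp <- sum(pred == p & truth != p)
    tn <- sum(pred != p & truth != p)
    confusion_metrics(tp, fn, fp, tn)
  }, numeric(7)))
  macro <- colMeans(per_class)
  auc <- auc_rank(scores, truth, positive)
  list(metrics = c(macro, roc_area = auc),
       per_class = cbind(per_class,
                         roc_area = vapply(cls, function(p)
                           if (p == positive) auc else
                             auc_rank(-scores, truth, p), numeric(1))),
       positive = c(confusion_metrics(
         sum(pred == positive & truth == positive),
         sum(pred != positive & truth == positive),
         sum(pred == positive & truth != positive),
         sum(pred != positive & truth != positive)), roc_area = auc))
}

#' Cross-validated naive-Bayes evaluation
#'
#' Evaluates a Gaussian naive-Bayes classifier on a feature table by
#' leave-one-out or repeated stratified k-fold cross-validation. Folds are
#' stratified by class and drawn from a single seeded generator. Per
#' scheme, predictions are pooled across folds into one confusion matrix;
#' metrics are macro-averaged over the two classes (per-class and
#' positive-class views are also returned) and the ROC area is rank-based
#' on the pooled positive-class posteriors. For k-fold, the dispersion of
#' each metric over `repeats` runs is reported.
#'
#' @param x numeric feature matrix.
#' @param y class labels.
#' @param scheme `"loo"` or `"kfold"`.
#' @param k folds for `"kfold"` (default 5).
#' @param repeats repeated runs for `"kfold"` (default 60).
#' @param seed integer seed for fold assignment.
#' @param positive positive class (default: first factor level).
#' @param priors passed to [train_nbc()].
#' @return Object of class `mnf_metrics`: `metrics` (macro means, with
#'   `sd` over repeats for k-fold), `per_class`, `positive_class`,
#'   `scheme`.
#' @export
cross_validate <- function(x, y, scheme = c("loo", "kfold"), k = 5L,
                           repeats = 60L, seed = 1L,
                           positive = NULL, priors = "frequency") {
  scheme <- match.arg(scheme)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (is.null(positive)) positive <- levels(y)[1]
  counts <- table(y)
  if (scheme == "kfold" && any(counts < k))
    stop_mnf("mnf_parameter_error",
             "k = %d exceeds the size of the smallest class (%d)", k,
             min(counts))
  run_folds <- function(fold_id) {
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    score <- numeric(length(y))
    for (f in unique(fold_id)) {
      te <- fold_id == f
      model <- train_nbc(x[!te, , drop = FALSE], y[!te], priors = priors)
      post <- predict(model, x[te, , drop = FALSE], type = "posterior")
      pred[te] <- factor(model$classes[max.col(post, ties.method = "first")],
                         levels = levels(y))
      score[te] <- post[, positive]
    }
    metrics_from_predictions(y, pred, score, positive)
  }
  if (scheme == "loo") {
    res <- run_folds(seq_along(y))
    out <- list(scheme = "loo", metrics = res$metrics,
                per_class = res$per_class, positive_class = res$positive,
                positive = positive)
  } else {
    seeds <- derive_seeds(seed, repeats)
    runs <- lapply(seq_len(repeats), function(r) {
      fold_id <- integer(length(y))
      local_seed(seeds[r], {
        for (cl in levels(y)) {
          idx <- sample(which(y == cl))
          fold_id[idx] <- rep_len(seq_len(k), length(idx))
        }
      })
      run_folds(fold_id)
    })
    mm <- t(vapply(runs, `[[`, numeric(8), "metrics"))
    pp <- t(vapply(runs, `[[`, numeric(8), "positive"))
    out <- list(scheme = sprintf("%d-fold x %d", k, repeats),
                metrics = colMeans(mm), sd = apply(mm, 2, sd),
                positive_class = colMeans(pp), positive_sd = apply(pp, 2, sd),
                per_class = Reduce(`+`, lapply(runs, `[[`, "per_class")) /
                  repeats,
                positive = positive)
  }
  class(out) <- "mnf_metrics"
  out
}

#' @export
print.mnf_metrics <- function(x, ...) {
  cat(sprintf("<mnf_metrics> %s cross-validation (positive class: %s)\n",
              x$scheme, x$positive))
  m <- x$metrics
  for (i in seq_along(m)) {
    if (!is.null(x$sd))
      cat(sprintf("  %-10s %.3f +/- %.3f\n", names(m)[i], m[i], x$sd[i]))
    else
      cat(sprintf("  %-10s %.3f\n", names(m)[i], m[i]))
  }
  invisible(x)
}

#' Extract MNF descriptors over a cohort
#'
#' Runs the full per-volume feature pipeline — Nakagami parametric fit over
#' voxel lattices, octant wavelet-packet expansion, per-sub-band fractal
#' features with adaptive termination — for every record of a cohort (as
#' produced by [make_cohort()]) and assembles the feature table. Because
#' termination is adaptive per volume, descriptors are truncated to the
#' smallest `levels_used` in the cohort so every column is defined for
#' every row.
#'
#' @param cohort list of records with `envelope`, `mask`, `class`, `id`.
#' @param lattice_size,stride,min_samples passed to
#'   [fit_parametric_volume()].
#' @param max_levels,scales passed to [mnf_descriptor()].
#' @return data.frame with columns `id`, `class`, `levels_used`, then the
#'   feature columns.
#' @export
extract_features <- function(cohort, lattice_size = 7L, stride = "sliding",
                             min_samples = 8L, max_levels = 3L, scales = 4L) {
  descs <- lapply(cohort, function(rec) {
    pv <- fit_parametric_volume(rec$envelope, mask = rec$mask,
                                lattice_size = lattice_size, stride = stride,
                                min_samples = min_samples)
    mnf_descriptor(pv, mask = rec$mask, max_levels = max_levels,
                   scales = scales)
  })
  lev <- min(vapply(descs, `[[`, integer(1), "levels_used"))
  feat <- t(vapply(descs, function(d) {
    keep <- grepl(sprintf("_L[1-%d]_", lev), names(d$features))
    d$features[keep]
  }, numeric(2L * 8L * lev)))
  data.frame(id = vapply(cohort, `[[`, "", "id"),
             class = vapply(cohort, `[[`, "", "class"),
             levels_used = lev, feat,
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Run the full MNF pipeline from a configuration
#'
#' End-to-end orchestration: builds (or loads) the cohort, extracts MNF
#' descriptors, cross-validates the naive-Bayes classifier, and writes the
#' feature CSV, the metrics JSON and a provenance log to `out_dir`. The
#' configuration is a list (or a path to a JSON/YAML file) with elements:
#' \describe{
#'   \item{`cohort`}{either `list(synthetic = list(n_per_class, grid_size,
#'     background, class_inclusions))` describing a two-class phantom
#'     cohort, or `list(manifest = "path.csv")` with columns
#'     `volume`, `mask`, `id`, `class` naming NIfTI files.}
#'   \item{`lattice_size`, `stride`, `min_samples`, `max_levels`,
#'     `scales`}{feature-extraction settings (defaults 7, "sliding", 8, 3,
#'     4).}
#'   \item{`cv`}{`list(scheme, k, repeats)` (default LOO).}
#'   \item{`seed`}{master seed for the synthetic cohort and folds.}
#' }
#'
#' @param config list or path to a JSON/YAML config file.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the feature table, the metrics report
#'   and the output paths.
#' @export
run_mnf <- function(config, out_dir = ".") {
  cfg <- read_config(config)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  cohort <- build_cohort_from_config(cfg, seed)
  lattice <- if (is.null(cfg$lattice_size)) 7L else as.integer(cfg$lattice_size)
  stride <- if (is.null(cfg$stride)) "sliding" else cfg$stride
  min_s <- if (is.null(cfg$min_samples)) 8L else as.integer(cfg$min_samples)
  maxl <- if (is.null(cfg$max_levels)) 3L else as.integer(cfg$max_levels)
  scl <- if (is.null(cfg$scales)) 4L else as.integer(cfg$scales)
  table <- extract_features(cohort, lattice_size = lattice, stride = stride,
                            min_samples = min_s, max_levels = maxl,
                            scales = scl)
  cv <- cfg$cv
  scheme <- if (is.null(cv$scheme)) "loo" else cv$scheme
  report <- cross_validate(as.matrix(table[, -(1:3)]), table$class,
                           scheme = scheme,
                           k = if (is.null(cv$k)) 5L else as.integer(cv$k),
                           repeats = if (is.null(cv$repeats)) 60L else
                             as.integer(cv$repeats),
                           seed = seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  feat_path <- file.path(out_dir, "features.csv")
  met_path <- file.path(out_dir, "metrics.json")
  write.csv(table, feat_path, row.names = FALSE)
  write_metrics_json(report, met_path)
  prov <- list(seed = seed, scheme = scheme,
               config_hash = unname(config_hash(cfg)),
               package_version = as.character(utils::packageVersion("mnf3d")),
               r_version = R.version.string,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(features = table, metrics = report,
                 paths = c(features = feat_path, metrics = met_path)))
}

read_config <- function(config) {
  if (is.list(config)) return(config)
  if (!is.character(config) || !file.exists(config))
    stop_mnf("mnf_parameter_error", "config file not found: %s", config)
  if (grepl("\\.ya?ml$", config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_mnf("mnf_parameter_error", "YAML config requires the 'yaml' package")
    yaml::read_yaml(config)
  } else {
    jsonlite::read_json(config, simplifyVector = TRUE)
  }
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

build_cohort_from_config <- function(cfg, seed) {
  if (!is.null(cfg$cohort$synthetic)) {
    sc <- cfg$cohort$synthetic
    grid <- if (is.null(sc$grid_size)) 48L else as.integer(sc$grid_size)
    bg <- if (is.null(sc$background)) c(1, 1) else as.numeric(sc$background)
    specs <- lapply(sc$class_inclusions, function(incs)
      phantom_spec(grid, bg, lapply(incs, as.list)))
    names(specs) <- names(sc$class_inclusions)
    make_cohort(if (is.null(sc$n_per_class)) 10L else
      as.integer(sc$n_per_class), specs, seed = seed)
  } else if (!is.null(cfg$cohort$manifest)) {
    man <- read.csv(cfg$cohort$manifest, stringsAsFactors = FALSE)
    lapply(seq_len(nrow(man)), function(i) {
      if (!file.exists(man$volume[i]))
        stop_mnf("mnf_parameter_error",
                 "volume file missing for id '%s': %s", man$id[i],
                 man$volume[i])
      if (!file.exists(man$mask[i]))
        stop_mnf("mnf_parameter_error",
                 "mask file missing for id '%s': %s", man$id[i], man$mask[i])
      vol <- read_volume(man$volume[i])
      msk <- vol_data(read_volume(man$mask[i])) != 0
      list(envelope = vol, mask = msk, class = man$class[i], id = man$id[i])
    })
  } else {
    stop_mnf("mnf_parameter_error",
             "config$cohort must provide 'synthetic' or 'manifest'")
  }
}
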