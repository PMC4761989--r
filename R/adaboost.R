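# Discrete AdaBoost over decision stumps, used to delete false-positive
# candidate regions of the initial PED mask.
#
# Round t: pick the stump (feature j, threshold theta, polarity s) with
# minimum weighted error eps_t; its vote weight is
# alpha_t = 1/2 * ln((1 - eps_t) / eps_t); sample weights are updated
# w <- w * exp(-alpha * y * h) and renormalized, which leaves exactly half
# of the total weight on the misclassified samples. Training stops early on
# a perfect stump (recorded) or when no stump beats chance.

stump_predict <- function(x, threshold, polarity) {
  p <- ifelse(x >= threshold, 1, -1)
  if (polarity > 0) p else -p
}

# exhaustive best stump for one feature under sample weights w
best_stump_feature <- function(x, y, w) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]; ws <- w[ord]
  # error of "predict +1 when x >= theta" as theta sweeps the midpoints:
  # start below min(x): all predicted +1 -> error = weight of negatives
  errs_pos <- sum(ws[ys < 0]) + cumsum(ifelse(ys > 0, ws, -ws))
  keep <- which(xs[-length(xs)] != xs[-1])
  if (!length(keep)) return(NULL)
  thr <- (xs[keep] + xs[keep + 1]) / 2
  e_pos <- errs_pos[keep]
  # polarity -1 flips predictions: error complements
  e_all <- c(e_pos, 1 - e_pos)
  pol <- rep(c(1, -1), each = length(keep))
  th <- c(thr, thr)
  best <- order(e_all, th, -pol)[1]  # ties: lower threshold, then polarity +1
  list(threshold = th[best], polarity = pol[best], error = e_all[best])
}

#' Train a discrete AdaBoost ensemble of decision stumps
#'
#' @param features numeric matrix (m samples x p features) or a feature
#'   table from [build_feature_table].
#' @param labels numeric vector in `{+1, -1}` (taken from the table's
#'   `label` column when `features` is a data frame).
#' @param rounds maximum boosting rounds N (>= 1).
#' @param weights optional initial sample weights (default uniform).
#' @return `strong_classifier`: lists `stumps` (feature, threshold,
#'   polarity), `alphas`, `errors` and the training feature names.
#' @examples
#' clf <- ada_train(cbind(x = c(1, 2, 8, 9)), c(-1, -1, 1, 1), rounds = 1)
#' ada_predict(clf, cbind(x = 5.5))
#' @export
ada_train <- function(features, labels = NULL, rounds = 50L, weights = NULL) {
  if (is.data.frame(features)) {
    labels <- labels %||% features$label
    features <- as.matrix(features[feature_columns(features)])
  }
  features <- as.matrix(features)
  m <- nrow(features)
  y <- as.numeric(labels)
  if (rounds < 1) stop_param("ada_train: rounds must be >= 1")
  if (length(y) != m || !all(y %in% c(-1, 1)))
    stop_param("ada_train: labels must be +1/-1, one per sample")
  if (length(unique(y)) < 2)
    stop_param("ada_train: both classes must be present for training")
  w <- weights %||% rep(1 / m, m)
  w <- w / sum(w)
  stumps <- list(); alphas <- numeric(0); errors <- numeric(0)
  for (t in seq_len(rounds)) {
    best <- NULL
    for (j in seq_len(ncol(features))) {
      cand <- best_stump_feature(features[, j], y, w)
      if (is.null(cand)) next
      if (is.null(best) || cand$error < best$error - 1e-15) {
        best <- cand; best$feature <- j
      }
    }
    if (is.null(best) || best$error >= 0.5 - 1e-12) break
    eps <- max(best$error, 0)
    alpha <- 0.5 * log((1 - eps) / max(eps, 1e-12))
    stumps[[length(stumps) + 1L]] <-
      list(feature = best$feature, threshold = best$threshold,
           polarity = best$polarity)
    alphas <- c(alphas, alpha)
    errors <- c(errors, eps)
    if (eps <= 1e-12) break  # perfect stump recorded, then stop
    h <- stump_predict(features[, best$feature], best$threshold, best$polarity)
    w <- w * exp(-alpha * y * h)
    w <- w / sum(w)
  }
  if (!length(stumps)) stop_param("ada_train: no informative stump found")
  structure(list(stumps = stumps, alphas = alphas, errors = errors,
                 feature_names = colnames(features)),
            class = "strong_classifier")
}

#' Predict with a strong classifier
#'
#' @param clf `strong_classifier` from [ada_train].
#' @param features matrix / data frame / single named vector of feature
#'   values.
#' @return `list(score=, label=)`: the weighted vote
#'   `score = sum_t alpha_t h_t(x)` and `label = sign(score)` (+1 on a tie).
#' @export
ada_predict <- function(clf, features) {
  if (is.data.frame(features)) features <- as.matrix(features[feature_columns(features)])
  if (is.null(dim(features))) features <- matrix(features, nrow = 1,
                                                 dimnames = list(NULL, names(features)))
  score <- numeric(nrow(features))
  for (t in seq_along(clf$stumps)) {
    s <- clf$stumps[[t]]
    score <- score + clf$alphas[t] *
      unname(stump_predict(features[, s$feature], s$threshold, s$polarity))
  }
  list(score = score, label = ifelse(score >= 0, 1, -1))
}

#' Label candidate regions against a truth mask
#'
#' A region is positive iff at least `threshold` of its pixels overlap the
#' truth PED mask.
#'
#' @param regions list of `candidate_region`.
#' @param truth logical 3D truth mask.
#' @param threshold overlap fraction (default 0.5; the comparison is `>=`).
#' @return numeric vector of +1 / -1.
#' @export
make_labels <- function(regions, truth, threshold = 0.5) {
  vapply(regions, function(r) {
    hit <- truth[cbind(r$pixels[, 1] + 1L, r$bscan + 1L, r$pixels[, 2] + 1L)]
    if (mean(hit) >= threshold) 1 else -1
  }, numeric(1))
}

#' Remove regions the classifier calls background
#'
#' Keeps exactly the pixels of regions predicted positive; regions predicted
#' negative are removed whole.
#'
#' @param mask logical 3D initial mask the regions came from.
#' @param regions list of `candidate_region` covering `mask`.
#' @param features feature matrix / table aligned with `regions`.
#' @param clf `strong_classifier`.
#' @return logical 3D refined mask.
#' @export
filter_regions <- function(mask, regions, features, clf) {
  out <- array(FALSE, dim(mask))
  if (!length(regions)) return(out)
  lab <- ada_predict(clf, features)$label
  for (i in seq_along(regions)) {
    if (lab[i] > 0) {
      r <- regions[[i]]
      out[cbind(r$pixels[, 1] + 1L, r$bscan + 1L, r$pixels[, 2] + 1L)] <- TRUE
    }
  }
  out
}

#' Serialize / restore a strong classifier as JSON
#'
#' @param clf `strong_classifier`.
#' @param path JSON file path.
#' @export
save_classifier <- function(clf, path) {
  jsonlite::write_json(unclass(clf), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stumps <- lapply(seq_len(nrow(obj$stumps)), function(i) as.list(obj$stumps[i, ]))
  structure(list(stumps = stumps, alphas = obj$alphas, errors = obj$errors,
                 feature_names = obj$feature_names),
            class = "strong_classifier")
}
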