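#' Normalize features to [0, 1]
#'
#' Min-max normalization with bounds learned on the training set; test-set
#' values falling outside the training range are clipped to \code{[0, 1]}.
#' Constant training columns carry no information and are dropped with a
#' warning.
#'
#' @param x data.frame or matrix of feature columns.
#' @param bounds optional data.frame (\code{feature}, \code{min}, \code{max})
#'   from a previous call; when \code{NULL}, bounds are computed from \code{x}.
#' @return list with \code{x} (normalized data.frame, columns restricted to
#'   the bounded features) and \code{bounds}.
#' @examples
#' normalizeFeatures(data.frame(a = c(2, 4, 6)))$x$a  # 0, 0.5, 1
#' @export
normalizeFeatures <- function(x, bounds = NULL) {
  x <- as.data.frame(x)
  if (is.null(bounds)) {
    mins <- vapply(x, min, numeric(1))
    maxs <- vapply(x, max, numeric(1))
    const <- maxs <= mins
    if (all(const)) stop("all feature columns are constant; nothing to normalize")
    if (any(const)) {
      warning("dropping constant feature column(s): ",
              paste(names(x)[const], collapse = ", "))
    }
    bounds <- data.frame(feature = names(x)[!const],
                         min = unname(mins[!const]), max = unname(maxs[!const]))
  }
  out <- x[, bounds$feature, drop = FALSE]
  for (i in seq_len(nrow(bounds))) {
    v <- (out[[i]] - bounds$min[i]) / (bounds$max[i] - bounds$min[i])
    out[[i]] <- pmin(pmax(v, 0), 1)
  }
  list(x = out, bounds = bounds)
}

#' Invert the [0, 1] normalization
#'
#' @param x normalized data.frame.
#' @param bounds bounds data.frame from [normalizeFeatures()].
#' @return data.frame on the original scale.
#' @export
denormalizeFeatures <- function(x, bounds) {
  out <- as.data.frame(x)[, bounds$feature, drop = FALSE]
  for (i in seq_len(nrow(bounds))) {
    out[[i]] <- out[[i]] * (bounds$max[i] - bounds$min[i]) + bounds$min[i]
  }
  out
}

#' F-score of one feature column
#'
#' Univariate discrimination ratio between the tumor (+) and stroma (-)
#' classes: the squared deviations of the class means from the overall mean,
#' divided by the summed unbiased within-class variances. When both classes
#' are constant the score is defined as \code{Inf} if the class means differ
#' and 0 if they coincide.
#'
#' @param x numeric feature values.
#' @param labels class labels: \code{"tumor"}/\code{"stroma"}, or +1/-1
#'   (+1 = tumor).
#' @return numeric(1) >= 0.
#' @examples
#' fScore(c(0, 0, 1, 1, 2, 2, 3, 3),
#'        c(1, 1, 1, 1, -1, -1, -1, -1))  # 3
#' @export
fScore <- function(x, labels) {
  pos <- .isTumorLabel(labels)
  if (sum(pos) < 2 || sum(!pos) < 2) {
    stop("F-score requires >= 2 members in each class")
  }
  xp <- x[pos]; xn <- x[!pos]
  mu <- mean(x); mup <- mean(xp); mun <- mean(xn)
  num <- (mup - mu)^2 + (mun - mu)^2
  den <- sum((xp - mup)^2) / (length(xp) - 1) + sum((xn - mun)^2) / (length(xn) - 1)
  if (den == 0) {
    return(if (mup != mun) Inf else 0)
  }
  num / den
}

.isTumorLabel <- function(labels) {
  if (is.numeric(labels)) return(labels > 0)
  labels <- as.character(labels)
  if (!all(labels %in% c("tumor", "stroma"))) {
    stop("labels must be 'tumor'/'stroma' or +1/-1")
  }
  labels == "tumor"
}

#' Rank features by F-score and select the top k
#'
#' Scores every feature column, sorts in descending order (ties broken by the
#' canonical feature order of [featureCategories()], then column position) and
#' returns the top \code{k} as the selected set.
#'
#' @param x data.frame/matrix of feature columns.
#' @param labels class labels (see [fScore()]).
#' @param k number of features to select; default 15.
#' @return list with \code{ranking} (data.frame: \code{feature},
#'   \code{category}, \code{f_score}, descending) and \code{selected}
#'   (character vector of length \code{k}).
#' @export
rankAndSelect <- function(x, labels, k = 15) {
  x <- as.data.frame(x)
  if (k <= 0) stop("k must be positive")
  if (k > ncol(x)) stop("k exceeds the number of features")
  fs <- vapply(x, fScore, numeric(1), labels = labels)
  canon <- names(featureCategories())
  tie <- match(names(x), canon)
  tie[is.na(tie)] <- length(canon) + seq_len(sum(is.na(tie)))
  ord <- order(-fs, tie)
  cat <- featureCategories()[names(x)[ord]]
  cat[is.na(cat)] <- "?"
  ranking <- data.frame(feature = names(x)[ord], category = unname(cat),
                        f_score = unname(fs[ord]), row.names = NULL)
  list(ranking = ranking, selected = ranking$feature[seq_len(k)])
}

#' Train the RBF-kernel SVM
#'
#' Fits a soft-margin support vector machine with a Gaussian (radial basis)
#' kernel on \code{[0, 1]}-normalized features; deterministic given data and
#' hyperparameters. The returned model is self-contained (support vectors,
#' coefficients, bias, kernel width) so predictions do not depend on the
#' fitting library and survive JSON serialization exactly.
#'
#' @param x normalized feature data.frame/matrix.
#' @param labels class labels (see [fScore()]); both classes must be present.
#' @param C soft-margin cost; default 1.
#' @param gamma RBF width \eqn{\exp(-\gamma ||u - v||^2)}; default
#'   \code{1/ncol(x)}.
#' @return list of class \code{rbfSVM} with elements \code{SV}, \code{coefs},
#'   \code{rho}, \code{gamma}, \code{cost}, \code{features},
#'   \code{positiveLevel} (the class predicted for positive decision values).
#' @export
trainTissueSVM <- function(x, labels, C = 1, gamma = NULL) {
  x <- as.matrix(as.data.frame(x))
  tum <- .isTumorLabel(labels)
  if (length(unique(tum)) < 2) stop("training requires both classes")
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  y <- factor(ifelse(tum, "tumor", "stroma"), levels = c("stroma", "tumor"))
  fit <- e1071::svm(x, y, type = "C-classification", kernel = "radial",
                    cost = C, gamma = gamma, scale = FALSE)
  # libsvm sign convention: positive decision values belong to the class of
  # the first training instance (fit$labels[1])
  posLevel <- fit$levels[fit$labels[1]]
  model <- structure(list(
    version = 1L, kernel = "rbf",
    SV = unname(as.matrix(fit$SV)), coefs = as.numeric(fit$coefs),
    rho = as.numeric(fit$rho), gamma = gamma, cost = C,
    features = colnames(x), positiveLevel = posLevel,
    levels = c("stroma", "tumor")
  ), class = "rbfSVM")
  model
}

#' Decision values of an rbfSVM
#'
#' @param model an \code{rbfSVM} from [trainTissueSVM()].
#' @param x data.frame/matrix with (at least) the model's feature columns.
#' @return numeric vector; positive values predict \code{model$positiveLevel}.
#' @export
svmDecision <- function(model, x) {
  x <- as.matrix(as.data.frame(x)[, model$features, drop = FALSE])
  sv <- model$SV
  d2 <- outer(rowSums(x^2), rowSums(sv^2), "+") - 2 * x %*% t(sv)
  K <- exp(-model$gamma * pmax(d2, 0))
  as.numeric(K %*% model$coefs - model$rho)
}

#' Predict tumor/stroma with an rbfSVM
#'
#' @inheritParams svmDecision
#' @return character vector of \code{"tumor"}/\code{"stroma"}.
#' @export
svmPredict <- function(model, x) {
  f <- svmDecision(model, x)
  neg <- setdiff(model$levels, model$positiveLevel)
  ifelse(f > 0, model$positiveLevel, neg)
}

#' Classify subgraphs and propagate labels to member nuclei
#'
#' Applies the trained subgraph model (after normalizing with the training
#' bounds and restricting to the selected features) to the feature matrix of a
#' core's subgraphs, then gives every member nucleus its subgraph's label.
#'
#' @param classifier a [TissueClassifier-class].
#' @param subgraphs list of connected [CellGraph-class]s.
#' @param features optional precomputed [featureMatrix()] of the subgraphs.
#' @return list with \code{subgraphLabels} (character per subgraph) and
#'   \code{perNucleus} (data.frame: \code{label}, \code{class},
#'   \code{source = "subgraph_svm"}, \code{subgraph_id}).
#' @export
classifySubgraphs <- function(classifier, subgraphs, features = NULL) {
  if (!length(subgraphs)) {
    return(list(subgraphLabels = character(0),
                perNucleus = data.frame(label = integer(0), class = character(0),
                                        source = character(0), subgraph_id = integer(0))))
  }
  if (is.null(features)) features <- featureMatrix(subgraphs)
  norm <- normalizeFeatures(features[, setdiff(names(features), "subgraph_id"),
                                     drop = FALSE],
                            bounds = classifier@graphBounds)
  sel <- norm$x[, classifier@selectedFeatures, drop = FALSE]
  labs <- svmPredict(classifier@graphModel, sel)
  perNuc <- do.call(rbind, lapply(seq_along(subgraphs), function(i) {
    data.frame(label = graphNodes(subgraphs[[i]])$label, class = labs[i],
               source = "subgraph_svm", subgraph_id = i)
  }))
  list(subgraphLabels = labs, perNucleus = perNuc)
}

#' Ground-truth label of a subgraph
#'
#' A subgraph is labeled tumor when a strict majority of its member-nucleus
#' centroids fall inside the tumor-region mask; ties go to stroma
#' (conservative tie-break).
#'
#' @param subgraph a [CellGraph-class].
#' @param truth a [GroundTruth-class] (or logical tumor mask).
#' @return \code{"tumor"} or \code{"stroma"}.
#' @export
assignTruthLabel <- function(subgraph, truth) {
  mask <- if (is(truth, "GroundTruth")) tumorMask(truth) else truth
  nodes <- graphNodes(subgraph)
  r <- pmin(pmax(round(nodes$centroid_row), 1), nrow(mask))
  c_ <- pmin(pmax(round(nodes$centroid_col), 1), ncol(mask))
  inside <- mask[cbind(r, c_)]
  if (sum(inside) > nrow(nodes) / 2) "tumor" else "stroma"
}

#' Per-core classification accuracies
#'
#' Computes, per core, the overall accuracy (correct nuclei / all nuclei) and
#' the producer's accuracy of each class (per-class recall), then aggregates
#' as mean and standard deviation across cores. A core without nuclei of a
#' class contributes no value to that class's aggregate. A pooled per-nucleus
#' overall accuracy across all cores is reported for transparency.
#'
#' @param predicted character vector of predicted classes per nucleus.
#' @param truth character vector of true classes per nucleus.
#' @param coreIds vector identifying the core of each nucleus.
#' @return object of class \code{ClassificationReport}: list with
#'   \code{per_core} (data.frame), \code{aggregate} (data.frame with mean and
#'   sd per metric, in percent) and \code{pooled_overall} (percent).
#' @export
evaluateClassification <- function(predicted, truth, coreIds) {
  stopifnot(length(predicted) == length(truth), length(truth) == length(coreIds))
  cores <- unique(coreIds)
  rows <- lapply(cores, function(cid) {
    sel <- coreIds == cid
    p <- predicted[sel]; t <- truth[sel]
    acc <- function(cls) {
      n <- sum(t == cls)
      if (n == 0) NA_real_ else 100 * sum(p == cls & t == cls) / n
    }
    data.frame(core = cid, n_nuclei = sum(sel),
               overall = 100 * mean(p == t),
               tumor_producers = acc("tumor"),
               stroma_producers = acc("stroma"))
  })
  perCore <- do.call(rbind, rows)
  agg <- data.frame(
    metric = c("overall", "tumor_producers", "stroma_producers"),
    mean = c(mean(perCore$overall),
             mean(perCore$tumor_producers, na.rm = TRUE),
             mean(perCore$stroma_producers, na.rm = TRUE)),
    sd = c(stats::sd(perCore$overall),
           stats::sd(perCore$tumor_producers[!is.na(perCore$tumor_producers)]),
           stats::sd(perCore$stroma_producers[!is.na(perCore$stroma_producers)]))
  )
  structure(list(per_core = perCore, aggregate = agg,
                 pooled_overall = 100 * mean(predicted == truth)),
            class = "ClassificationReport")
}

#' @export
print.ClassificationReport <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("Classification over %d cores:\n", nrow(x$per_core)))
  for (i in seq_len(nrow(a))) {
    cat(sprintf("  %-18s %6.2f (+/- %5.2f)\n", a$metric[i], a$mean[i], a$sd[i]))
  }
  cat(sprintf("  pooled overall     %6.2f\n", x$pooled_overall))
  invisible(x)
}
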