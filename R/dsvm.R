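# --- hierarchical clustering of class centroids -----------------------------
#
# The decision-tree topology is obtained by agglomerative (ascending)
# hierarchical clustering of the class-mean standardized feature vectors,
# Ward criterion. The loop is written out (rather than calling hclust) so
# the tie-break is under contract: candidate pairs are scanned in the order
# of their smallest member class, and only a strictly smaller merge cost
# displaces the incumbent, so exact ties merge lowest-class-index first.

ward_cost <- function(a, b) {
  (a$size * b$size) / (a$size + b$size) * sum((a$centroid - b$centroid)^2)
}

#' Build the dendrogram decision tree from training features
#'
#' Computes per-class centroids of the standardized training features and
#' agglomerates them with the Ward criterion into a binary tree: each
#' internal node holds the two class subsets its binary SVM will
#' discriminate, leaves are single classes. Exact ties in merge cost are
#' resolved by merging the pair containing the lowest class index first.
#'
#' @param x Numeric matrix or data frame of training features.
#' @param y Class labels (coercible to factor), one per row of `x`.
#' @return A `dendrogram_tree`: list with `root` (recursive nodes with
#'   elements `classes`, `left`, `right`), `classes` (level names),
#'   `merge`/`height`/`labels` (hclust-compatible record of the
#'   agglomeration).
#' @examples
#' x <- matrix(c(1.5, 1, -1, -1.5), 4, 2) # 1<2<<3<4 geometry
#' build_dendrogram(x, 1:4)
#' @export
build_dendrogram <- function(x, y) {
  x <- as.matrix(x)
  y <- factor(y)
  lev <- levels(y)
  if (any(table(y) == 0) || nlevels(y) < 2)
    stop("every class needs at least one training sample")
  xs <- scale(x)
  xs[, attr(xs, "scaled:scale") == 0] <- 0
  K <- nlevels(y)
  clusters <- lapply(seq_len(K), function(k) list(
    classes = k,
    centroid = colMeans(xs[y == lev[k], , drop = FALSE]),
    size = 1,
    node = list(classes = k)
  ))
  merge <- matrix(0L, K - 1, 2)
  height <- numeric(K - 1)
  id <- -seq_len(K) # hclust convention: negative = singleton
  for (step in seq_len(K - 1)) {
    best <- NULL; best_cost <- Inf
    for (i in seq_len(length(clusters) - 1)) for (j in seq.int(i + 1, length(clusters))) {
      cst <- ward_cost(clusters[[i]], clusters[[j]])
      if (cst < best_cost) { best_cost <- cst; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    a <- clusters[[i]]; b <- clusters[[j]]
    # left child = subtree containing the smallest class index
    kids <- if (min(a$classes) < min(b$classes)) list(a$node, b$node)
            else list(b$node, a$node)
    node <- list(classes = sort(c(a$classes, b$classes)),
                 left = kids[[1]], right = kids[[2]])
    merged <- list(
      classes = node$classes,
      centroid = (a$size * a$centroid + b$size * b$centroid) / (a$size + b$size),
      size = a$size + b$size,
      node = node
    )
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- best_cost
    id <- c(id[-c(i, j)], step)
    clusters <- c(clusters[-c(i, j)], list(merged))
    # keep scan order by smallest class index for the tie-break contract
    ord <- order(vapply(clusters, function(cl) min(cl$classes), numeric(1)))
    clusters <- clusters[ord]
    id <- id[ord]
  }
  structure(list(root = clusters[[1]]$node, classes = lev,
                 merge = merge, height = height, labels = lev),
            class = "dendrogram_tree")
}

# Internal nodes in breadth-first (root-first) order.
tree_nodes <- function(node) {
  out <- list(); queue <- list(node)
  while (length(queue)) {
    n <- queue[[1]]; queue <- queue[-1]
    if (!is.null(n$left)) {
      out[[length(out) + 1L]] <- n
      queue <- c(queue, list(n$left, n$right))
    }
  }
  out
}

#' @export
print.dendrogram_tree <- function(x, ...) {
  cat("Dendrogram decision tree over classes:",
      paste(x$classes, collapse = ", "), "\n")
  nodes <- tree_nodes(x$root)
  for (i in seq_along(nodes)) {
    n <- nodes[[i]]
    cat(sprintf("  SVM%d: [%s] vs [%s]\n", i,
                paste(x$classes[n$left$classes], collapse = " "),
                paste(x$classes[n$right$classes], collapse = " ")))
  }
  invisible(x)
}

#' Convert a dendrogram tree to an hclust object
#' @param tree A `dendrogram_tree`.
#' @return An object of class `hclust` (for plotting and cross-checks).
#' @export
as_hclust <- function(tree) {
  leaf_order <- function(n)
    if (is.null(n$left)) n$classes else c(leaf_order(n$left), leaf_order(n$right))
  structure(list(merge = tree$merge, height = tree$height,
                 order = leaf_order(tree$root), labels = tree$labels,
                 method = "ward", dist.method = "euclidean",
                 call = match.call()),
            class = "hclust")
}

# --- the dendrogram SVM ------------------------------------------------------

svm_kernel_args <- function(kernel, gamma, p) {
  gamma <- if (is.null(gamma)) 1 / p else gamma
  switch(kernel,
         quadratic = list(kernel = "polynomial", degree = 2, coef0 = 1,
                          gamma = gamma),
         rbf = list(kernel = "radial", gamma = gamma),
         stop("unknown kernel: ", kernel))
}

#' Dendrogram multi-class support vector machine
#'
#' Fits the dendrogram SVM: a binary decision tree over the classes is
#' built by Ward hierarchical clustering of class centroids
#' ([build_dendrogram()]), and a binary SVM (quadratic-kernel by default)
#' is trained at each internal node on the training samples of that
#' node's classes, labelled by the side of the split they belong to.
#' Features are standardized with means and variances estimated from the
#' training data only. Training rows are sorted internally, so the fit is
#' invariant to the order of the input samples.
#'
#' @param x Numeric matrix or data frame of features (rows = samples), or
#'   a model formula.
#' @param y Class labels, one per row.
#' @param kernel `"quadratic"` (polynomial degree 2, `coef0 = 1`) or
#'   `"rbf"`.
#' @param cost Regularization parameter C of each node SVM.
#' @param gamma Kernel scale; default `1 / ncol(x)`.
#' @param tree Optional pre-built `dendrogram_tree`; by default the tree
#'   is (re)built from the training data.
#' @param data,formula,... Formula-interface arguments.
#' @return An object of class `dsvm` with `print`, `summary`, `predict`
#'   and `plot` methods.
#' @examples
#' ft <- simulate_features(n_subjects = 8, seed = 1)
#' fit <- dsvm(ft[, feature_names()], ft$location)
#' table(predict(fit, ft[, feature_names()]), ft$location)
#' @export
dsvm <- function(x, ...) UseMethod("dsvm")

#' @rdname dsvm
#' @export
dsvm.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- stats::model.matrix(attr(mf, "terms"), mf)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  out <- dsvm.default(x, y, ...)
  out$call <- match.call()
  out
}

#' @rdname dsvm
#' @export
dsvm.default <- function(x, y, kernel = c("quadratic", "rbf"), cost = 1,
                         gamma = NULL, tree = NULL, ...) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  y <- factor(y)
  stopifnot(nrow(x) == length(y))
  ord <- do.call(order, c(list(as.integer(y)), asplit(x, 2)))
  x <- x[ord, , drop = FALSE]
  y <- y[ord]
  center <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  stopifnot(all(is.finite(center)), all(is.finite(scl)))
  xs <- scale(x, center, scl)
  if (is.null(tree)) tree <- build_dendrogram(x, y)
  karg <- svm_kernel_args(kernel, gamma, ncol(x))
  yi <- as.integer(y)
  nodes <- tree_nodes(tree$root)
  fits <- lapply(nodes, function(n) {
    idx <- yi %in% n$classes
    side <- factor(ifelse(yi[idx] %in% n$left$classes, "L", "R"),
                   levels = c("L", "R"))
    if (any(table(side) == 0))
      stop("a node side has no training samples: [",
           paste(tree$classes[n$left$classes], collapse = " "), "] vs [",
           paste(tree$classes[n$right$classes], collapse = " "), "]")
    do.call(e1071::svm,
            c(list(x = xs[idx, , drop = FALSE], y = side,
                   type = "C-classification", cost = cost, scale = FALSE),
              karg))
  })
  structure(list(tree = tree, node_fits = fits, center = center,
                 scale = scl, levels = levels(y), kernel = kernel,
                 cost = cost, gamma = karg$gamma,
                 feature_names = colnames(x), n_train = nrow(x),
                 call = match.call()),
            class = "dsvm")
}

#' @rdname dsvm
#' @param object A fitted `dsvm`.
#' @param newdata Matrix or data frame of feature rows to classify.
#' @export
predict.dsvm <- function(object, newdata, ...) {
  if (is.data.frame(newdata) &&
      all(object$feature_names %in% names(newdata)))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  newdata <- as.matrix(newdata)
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != length(object$center))
    stop("newdata has ", ncol(newdata), " features; model expects ",
         length(object$center))
  xs <- scale(newdata, object$center, object$scale)
  out <- integer(nrow(xs))
  nodes <- tree_nodes(object$tree$root)
  descend <- function(node, idx) {
    if (!length(idx)) return(invisible())
    if (is.null(node$left)) { out[idx] <<- node$classes; return(invisible()) }
    k <- which(vapply(nodes, identical, logical(1), node))
    side <- predict(object$node_fits[[k]], xs[idx, , drop = FALSE])
    descend(node$left, idx[side == "L"])
    descend(node$right, idx[side == "R"])
  }
  descend(object$tree$root, seq_len(nrow(xs)))
  factor(object$levels[out], levels = object$levels)
}

#' @export
print.dsvm <- function(x, ...) {
  cat("Dendrogram SVM (", x$kernel, " kernel, C = ", x$cost,
      ", gamma = ", signif(x$gamma, 3), ") trained on ", x$n_train,
      " samples\n", sep = "")
  print(x$tree)
  invisible(x)
}

#' @export
summary.dsvm <- function(object, ...) {
  cat("Call: "); print(object$call)
  print(object)
  cat("Support vectors per node:",
      paste(vapply(object$node_fits, function(f) f$tot.nSV, numeric(1)),
            collapse = ", "), "\n")
  invisible(object)
}

#' @export
#' @rdname dsvm
plot.dsvm <- function(x, ...) {
  plot(as_hclust(x$tree), ylab = "Ward merge cost", sub = "", xlab = "",
       main = "Class dendrogram", ...)
}

#' Binary attended-vs-unattended SVM
#'
#' Quadratic-kernel binary SVM for the question "was the flashed letter at
#' an attended location?". The attended class is 1 in 4 by design
#' (cue location = letter location), so inverse-frequency class weights
#' are applied by default.
#'
#' @param x Feature matrix or data frame (the 6 target-locked features).
#' @param y Logical or two-level factor of attended labels.
#' @param kernel,cost,gamma As in [dsvm()].
#' @param class_weights `"inverse"` (inverse class frequency) or `"none"`.
#' @return An object of class `attended_svm` with a `predict` method.
#' @export
attended_svm <- function(x, y, kernel = c("quadratic", "rbf"), cost = 1,
                         gamma = NULL, class_weights = c("inverse", "none")) {
  kernel <- match.arg(kernel)
  class_weights <- match.arg(class_weights)
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2) stop("both labels must be present")
  ord <- do.call(order, c(list(as.integer(y)), asplit(x, 2)))
  x <- x[ord, , drop = FALSE]; y <- y[ord]
  center <- colMeans(x)
  scl <- apply(x, 2, stats::sd); scl[scl == 0 | !is.finite(scl)] <- 1
  karg <- svm_kernel_args(kernel, gamma, ncol(x))
  cw <- if (class_weights == "inverse") {
    tb <- table(y); w <- as.numeric(length(y) / (nlevels(y) * tb))
    stats::setNames(w, names(tb))
  } else NULL
  fit <- do.call(e1071::svm,
                 c(list(x = scale(x, center, scl), y = y,
                        type = "C-classification", cost = cost,
                        scale = FALSE, class.weights = cw), karg))
  structure(list(fit = fit, center = center, scale = scl,
                 levels = levels(y), feature_names = colnames(x)),
            class = "attended_svm")
}

#' @export
predict.attended_svm <- function(object, newdata, ...) {
  if (is.data.frame(newdata) &&
      all(object$feature_names %in% names(newdata)))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  newdata <- as.matrix(newdata)
  predict(object$fit, scale(newdata, object$center, object$scale))
}
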