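# Decision-tree classification of slur relevance for T-wave offset
# determination.
#
# The classifier decides whether a slur trailing the T-peak marks a real
# late-repolarization shoulder (the tangent must be taken after the slur)
# or is incidental.  It is restricted to three features: the angle between
# the slur's two limb slopes, the angle between the peak's falling and the
# slur's rising slope, and the peak/slur amplitude ratio.  The tree
# structure is plain data (JSON-serializable) and prediction is a
# deterministic traversal independent of the training backend.

TREE_FEATURES <- c("slur_limb_angle", "peak_slur_angle", "amp_ratio_peak_slur")

#' Train a slur-relevance decision tree
#'
#' Fits a pruned classification tree (CART via \pkg{rpart}) restricted to
#' the three selected features, then converts it to the package's plain
#' node structure.  Training is deterministic given the seed.
#'
#' @param examples data.frame with the three feature columns and a `label`
#'   column (`"relevant"` / `"irrelevant"`); at least 50 rows, both
#'   classes present.
#' @param max_depth maximum tree depth (default 4).
#' @param seed integer seed recorded in the tree metadata.
#' @param min_split minimum node size for a split (rpart `minsplit`).
#' @return Object of class `relevance_tree` (fields `root`, `features`,
#'   `version`), with the underlying rpart fit in attribute `rpart_fit`
#'   (not serialized).
#' @export
train_relevance_tree <- function(examples, max_depth = 4, seed = 7, min_split = 20) {
  examples <- as.data.frame(examples)
  missing <- setdiff(c(TREE_FEATURES, "label"), names(examples))
  if (length(missing))
    jt_stop("jt_training_error",
            sprintf("examples lack column(s): %s", paste(missing, collapse = ", ")))
  if (nrow(examples) < 50)
    jt_stop("jt_training_error", "need at least 50 labeled examples")
  examples$label <- factor(as.character(examples$label),
                           levels = c("irrelevant", "relevant"))
  if (length(unique(examples$label[!is.na(examples$label)])) < 2)
    jt_stop("jt_training_error", "both classes must be present")
  set.seed(seed)
  fit <- rpart::rpart(
    label ~ slur_limb_angle + peak_slur_angle + amp_ratio_peak_slur,
    data = examples, method = "class",
    control = rpart::rpart.control(maxdepth = max_depth, cp = 0.005,
                                   minsplit = min_split,
                                   xval = 0, maxcompete = 0, maxsurrogate = 0,
                                   usesurrogate = 0)
  )
  root <- rpart_to_nodes(fit)
  acc <- mean(predict(fit, examples, type = "class") == examples$label)
  tree <- structure(
    list(root = root, features = TREE_FEATURES,
         version = list(package = as.character(utils::packageVersion("jtpeak")),
                        trained_on = sprintf("synthetic-slur-corpus-n%d", nrow(examples)),
                        seed = seed, n_examples = nrow(examples),
                        training_accuracy = acc)),
    class = "relevance_tree"
  )
  attr(tree, "rpart_fit") <- fit
  tree
}

# rpart -> plain nodes.  Semantics of the result: feature value <= threshold
# goes left (ties route left).  rpart continuous splits use "< threshold
# goes left" when ncat == -1 and "< threshold goes right" when ncat == +1;
# thresholds are midpoints of observed values so the tie case does not
# arise in training data.
rpart_to_nodes <- function(fit) {
  frame <- fit$frame
  nodenums <- as.integer(rownames(frame))
  is_split <- frame$var != "<leaf>"
  split_row <- integer(nrow(frame))
  split_row[is_split] <- seq_len(sum(is_split))
  ylevels <- attr(fit, "ylevels")
  build <- function(nodenum) {
    i <- match(nodenum, nodenums)
    if (!is_split[i])
      return(list(type = "leaf", class = ylevels[frame$yval[i]]))
    sr <- split_row[i]
    thr <- unname(fit$splits[sr, "index"])
    ncat <- fit$splits[sr, "ncat"]
    left <- build(2L * nodenum)
    right <- build(2L * nodenum + 1L)
    if (ncat < 0)
      list(type = "split", feature = as.character(frame$var[i]),
           threshold = thr, left = left, right = right)
    else
      list(type = "split", feature = as.character(frame$var[i]),
           threshold = thr, left = right, right = left)
  }
  build(1L)
}

#' Classify a slur as relevant or irrelevant
#'
#' Deterministic traversal of the tree: at each split the feature value is
#' compared with the threshold, `<=` routes left.
#'
#' @param features a [compute_slur_features()] row (or any list providing
#'   the tree's features).
#' @param tree a `relevance_tree`.
#' @return `"relevant"` or `"irrelevant"`.
#' @export
classify_slur_relevance <- function(features, tree = NULL) {
  if (is.null(tree)) tree <- default_relevance_tree()
  stopifnot(inherits(tree, "relevance_tree"))
  f <- as.list(features)
  node <- tree$root
  while (identical(node$type, "split")) {
    v <- f[[node$feature]]
    if (is.null(v) || !is.finite(v))
      jt_stop("jt_classification_error",
              sprintf("missing or non-finite feature '%s'", node$feature))
    node <- if (v <= node$threshold) node$left else node$right
  }
  node$class
}

#' Serialize / load a relevance tree
#'
#' Plain JSON with version metadata, so a trained tree can be shipped,
#' versioned and overridden independently of the code.
#'
#' @param tree a `relevance_tree`.
#' @param path JSON file path.
#' @return `write_relevance_tree`: `path` invisibly;
#'   `read_relevance_tree`: the tree.
#' @export
write_relevance_tree <- function(tree, path) {
  stopifnot(inherits(tree, "relevance_tree"))
  jsonlite::write_json(unclass(tree), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_relevance_tree
#' @export
read_relevance_tree <- function(path) {
  if (!file.exists(path)) jt_stop("jt_io_error", sprintf("file not found: %s", path))
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$root) || is.null(obj$features))
    jt_stop("jt_format_error", "not a relevance tree file")
  structure(list(root = obj$root, features = unlist(obj$features),
                 version = obj$version),
            class = "relevance_tree")
}

.jt_env <- new.env(parent = emptyenv())

#' Bundled default relevance tree
#'
#' The tree shipped with the package, trained on the labeled synthetic
#' slur corpus ([make_slur_corpus()], n = 500, seed = 7) and serialized
#' under `inst/extdata/`.  Override per call via the `tree` argument of
#' [delineate_twave()] or globally by pointing `path` at another file.
#'
#' @param path alternative tree file.
#' @return A `relevance_tree`.
#' @export
default_relevance_tree <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.jt_env$default_tree)) return(.jt_env$default_tree)
    path <- system.file("extdata", "default_relevance_tree.json",
                        package = "jtpeak", mustWork = TRUE)
    tree <- read_relevance_tree(path)
    .jt_env$default_tree <- tree
    return(tree)
  }
  read_relevance_tree(path)
}

#' @export
print.relevance_tree <- function(x, ...) {
  depth <- function(node) if (identical(node$type, "leaf")) 0L else
    1L + max(depth(node$left), depth(node$right))
  cat(sprintf("<relevance_tree> depth %d over {%s}; trained on %s (n=%s)\n",
              depth(x$root), paste(x$features, collapse = ", "),
              x$version$trained_on %||% "?", x$version$n_examples %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
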