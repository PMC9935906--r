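#' Replicate-level profile matrix over the common residues
#'
#' Builds the (structure, replicate) x residue matrix of normalised
#' energy-change values used for clustering and classification. Each
#' replicate row is min-max normalised to 0-100 over its own defined
#' residues; residues absent or excluded (NA) in any structure are then
#' removed, so the matrix holds only residues common to all inputs.
#'
#' @param scans named list of `scan_result` objects (names override the
#'   stored structure ids when given)
#' @return a `profile_matrix`: list with `values` (rows = structure x
#'   replicate), `structure`, `replicate`, `residues`
#' @export
profile_matrix <- function(scans) {
  if (length(scans) < 2) stop("need at least 2 structures")
  ids <- names(scans)
  if (is.null(ids))
    ids <- vapply(scans, function(s) s$structure_id, character(1))
  per <- lapply(seq_along(scans), function(i) {
    df <- scans[[i]]$replicates
    reps <- sort(unique(df$replicate))
    pos <- sort(unique(df$position))
    m <- matrix(NA_real_, length(reps), length(pos),
                dimnames = list(NULL, as.character(pos)))
    m[cbind(match(df$replicate, reps), match(df$position, pos))] <- df$delta_reu
    norm <- t(apply(m, 1, function(v) {
      ok <- !is.na(v)
      lo <- min(v[ok]); hi <- max(v[ok])
      v[ok] <- if (hi - lo < 1e-12) 0 else 100 * (v[ok] - lo) / (hi - lo)
      v
    }))
    list(id = ids[i], m = norm, reps = reps)
  })
  common <- Reduce(intersect, lapply(per, function(p)
    colnames(p$m)[colSums(is.na(p$m)) == 0]))
  if (length(common) == 0)
    stop("no residues are common to all structures")
  common <- as.character(sort(as.integer(common)))
  values <- do.call(rbind, lapply(per, function(p) p$m[, common, drop = FALSE]))
  structure(list(values = values,
                 structure = rep(vapply(per, `[[`, "", "id"),
                                 vapply(per, function(p) nrow(p$m), 1L)),
                 replicate = unlist(lapply(per, `[[`, "reps")),
                 residues = as.integer(common)),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix> %d rows (%d structures) x %d common residues\n",
              nrow(x$values), length(unique(x$structure)), ncol(x$values)))
  invisible(x)
}

#' Euclidean distance matrix between per-structure mean profiles
#'
#' @param pm a `profile_matrix`
#' @return symmetric matrix of Euclidean distances, zero diagonal
#' @export
profile_distance_matrix <- function(pm) {
  stopifnot(inherits(pm, "profile_matrix"))
  ids <- unique(pm$structure)
  means <- t(vapply(ids, function(id)
    colMeans(pm$values[pm$structure == id, , drop = FALSE]),
    numeric(ncol(pm$values))))
  rownames(means) <- ids
  as.matrix(stats::dist(means))
}

#' Ward agglomerative clustering of a distance matrix
#'
#' Ward linkage (ward.D2 on Euclidean distances: merge heights are
#' sqrt(2 x the increase in within-cluster sum of squares)), with
#' monotone non-decreasing heights.
#'
#' @param d a `dist`, a symmetric distance matrix, or a numeric data
#'   matrix (rows = items; Euclidean distances are taken)
#' @return a `linkage_tree`: merge, height, labels (wraps `hclust`)
#' @export
ward_cluster <- function(d) {
  if (inherits(d, "dist")) {
    dd <- d
  } else {
    d <- as.matrix(d)
    is_distance <- nrow(d) == ncol(d) && all(abs(diag(d)) < 1e-12) &&
      isTRUE(all.equal(d, t(d), tolerance = 1e-8))
    dd <- if (is_distance) stats::as.dist(d) else stats::dist(d)
  }
  if (attr(dd, "Size") < 2) stop("need at least 2 items to cluster")
  h <- stats::hclust(dd, method = "ward.D2")
  structure(list(merge = h$merge, height = h$height, labels = h$labels,
                 hclust = h),
            class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("<linkage_tree> %d leaves, %d merges (Ward)\n",
              length(x$height) + 1, length(x$height)))
  invisible(x)
}

#' Agglomerate covarying residue columns into k composite features
#'
#' Ward/Euclidean merging of the column vectors down to exactly `k`
#' clusters; each reduced feature is the mean of its member columns.
#' Cluster identities are canonical (ordered by smallest member
#' residue), so the reduced matrix is invariant to input column
#' permutations.
#'
#' @param pm a `profile_matrix` or a plain numeric matrix with column names
#' @param k target number of feature clusters (default 20)
#' @return a `feature_clustering`: `assignment` (column -> cluster id),
#'   `reduced` (rows x k matrix), `members` (list per cluster)
#' @export
agglomerate_features <- function(pm, k = 20) {
  V <- if (inherits(pm, "profile_matrix")) pm$values else as.matrix(pm)
  if (is.null(colnames(V))) colnames(V) <- seq_len(ncol(V))
  if (k < 1) stop("k must be >= 1")
  if (k > ncol(V)) stop("k exceeds the number of residue columns")
  if (k == ncol(V)) {
    cl <- setNames(seq_len(ncol(V)), colnames(V))
  } else {
    h <- stats::hclust(stats::dist(t(V)), method = "ward.D2")
    cl <- stats::cutree(h, k = k)
  }
  # canonical ids ordered by each cluster's smallest member (by residue
  # number when names are numeric), so the reduced matrix is invariant
  # to input column permutations
  keyval <- suppressWarnings(as.numeric(colnames(V)))
  if (anyNA(keyval)) keyval <- rank(colnames(V))
  first <- vapply(seq_len(max(cl)), function(g) min(keyval[cl == g]),
                  numeric(1))
  relab <- rank(first)[cl]
  cl <- setNames(as.integer(relab), colnames(V))
  members <- lapply(split(colnames(V), cl), function(x) x[order(keyval[match(x, colnames(V))])])
  red <- vapply(seq_len(k), function(g)
    rowMeans(V[, cl == g, drop = FALSE]), numeric(nrow(V)))
  colnames(red) <- vapply(members, function(m)
    paste0("c", m[1], if (length(m) > 1) paste0("-", m[length(m)]) else ""),
    character(1))
  structure(list(assignment = cl, reduced = red, members = members, k = k),
            class = "feature_clustering")
}

#' @export
print.feature_clustering <- function(x, ...) {
  cat(sprintf("<feature_clustering> %d residues -> %d clusters\n",
              length(x$assignment), x$k))
  invisible(x)
}

#' Map structure subtypes to parent fibril classes
#'
#' Uses the shipped editable subtype table first, then falls back to
#' stripping subtype suffixes (`_T<k><a>`, `-PHF`, `-SF`, `_PHF`, `_SF`).
#'
#' @param ids character vector of structure ids
#' @param map optional replacement data.frame with columns subtype, parent
#' @return character vector of parent class labels
#' @export
parent_label <- function(ids, map = NULL) {
  if (is.null(map)) {
    if (is.null(.fs_cache$label_map)) {
      p <- system.file("extdata", "label_map.tsv", package = "fibrilscan",
                       mustWork = TRUE)
      .fs_cache$label_map <- read.delim(p, stringsAsFactors = FALSE)
    }
    map <- .fs_cache$label_map
  }
  out <- map$parent[match(ids, map$subtype)]
  fb <- is.na(out)
  stripped <- sub("(_T[0-9]+[a-z]?)$", "", ids[fb])
  stripped <- sub("[-_](PHF|SF)$", "", stripped)
  out[fb] <- stripped
  out
}

route_tree <- function(tr, x) {
  node <- 1L
  path <- node
  while (tr[node, "status"] != -1L) {
    v <- tr[node, "split var"]
    node <- if (x[v] <= tr[node, "split point"])
      tr[node, "left daughter"] else tr[node, "right daughter"]
    path <- c(path, node)
  }
  path
}

node_probabilities <- function(tr, X, y, n_classes) {
  counts <- matrix(0, nrow(tr), n_classes)
  for (i in seq_len(nrow(X))) {
    path <- route_tree(tr, X[i, ])
    counts[path, y[i]] <- counts[path, y[i]] + 1
  }
  visited <- rowSums(counts) > 0
  probs <- counts
  probs[visited, ] <- counts[visited, , drop = FALSE] /
    rowSums(counts[visited, , drop = FALSE])
  probs
}

forest_predict_prob <- function(report, x) {
  p <- 0
  for (t in report$trees) {
    path <- route_tree(t$tree, x)
    p <- p + t$probs[path[length(path)], ]
  }
  p / length(report$trees)
}

#' Train the replicate-split random-forest classifier
#'
#' Implements the protocol of the energetic-profile classifier: per
#' restart, each structure's replicates are split at random into
#' `n_train` training and `n_test` held-out rows; a forest of `n_trees`
#' is fit on the training rows (labels = parent fibril classes) and
#' scored on the held-out rows; the best-accuracy restart is kept (ties
#' broken by lower restart index). Class probabilities are soft votes
#' (per-tree leaf class distributions of the training rows, averaged
#' over trees), which makes the decision-path contribution
#' decomposition exact.
#'
#' @param x a `feature_clustering` reduced matrix, `profile_matrix`, or
#'   plain matrix (rows = structure x replicate)
#' @param structure structure id per row (taken from a `profile_matrix`
#'   automatically)
#' @param n_train,n_test replicates per structure used for training /
#'   held-out testing (defaults 9 / 26 of 35)
#' @param n_trees trees per forest (default 100)
#' @param restarts random split/fit restarts (default 50; the full
#'   protocol value is 2500)
#' @param seed integer seed
#' @param label_map optional subtype-to-parent table for [parent_label()]
#' @return a `classifier_report`
#' @export
train_forest <- function(x, structure = NULL, n_train = 9, n_test = 26,
                         n_trees = 100, restarts = 50, seed = 1,
                         label_map = NULL) {
  if (inherits(x, "profile_matrix")) {
    if (is.null(structure)) structure <- x$structure
    X <- x$values
  } else if (inherits(x, "feature_clustering")) {
    X <- x$reduced
  } else X <- as.matrix(x)
  if (is.null(structure) || length(structure) != nrow(X))
    stop("'structure' must give one structure id per matrix row")
  y_all <- factor(parent_label(structure, label_map))
  if (nlevels(y_all) < 2) stop("need at least 2 parent classes")
  reps_per <- table(structure)
  if (any(reps_per < n_train + n_test))
    stop("replicate count (", min(reps_per), ") is below the split sizes ",
         "n_train + n_test = ", n_train + n_test,
         "; lower n_train/n_test or provide more replicates")

  best <- NULL
  for (s in seq_len(restarts)) {
    set.seed(derive_seed(seed, s))
    train_idx <- integer(0); test_idx <- integer(0)
    for (id in unique(structure)) {
      rows <- which(structure == id)
      tr <- sample(rows, n_train)
      rest <- setdiff(rows, tr)
      te <- if (length(rest) > n_test) sample(rest, n_test) else rest
      train_idx <- c(train_idx, tr); test_idx <- c(test_idx, te)
    }
    rf <- randomForest::randomForest(X[train_idx, , drop = FALSE],
                                     y_all[train_idx], ntree = n_trees)
    pred <- predict(rf, X[test_idx, , drop = FALSE])
    acc <- mean(pred == y_all[test_idx])
    if (is.null(best) || acc > best$accuracy) {
      best <- list(rf = rf, accuracy = acc, restart = s,
                   train_idx = train_idx, test_idx = test_idx)
    }
  }

  classes <- levels(y_all)
  Xtr <- X[best$train_idx, , drop = FALSE]
  ytr <- as.integer(y_all[best$train_idx])
  trees <- lapply(seq_len(n_trees), function(k) {
    tr <- randomForest::getTree(best$rf, k, labelVar = FALSE)
    colnames(tr) <- c("left daughter", "right daughter", "split var",
                      "split point", "status", "prediction")
    list(tree = tr, probs = node_probabilities(tr, Xtr, ytr, length(classes)))
  })
  bias <- Reduce(`+`, lapply(trees, function(t) t$probs[1, ])) / length(trees)
  report <- structure(list(forest = best$rf, trees = trees, classes = classes,
                           feature_names = colnames(X),
                           accuracy = best$accuracy, restart = best$restart,
                           restarts = restarts,
                           protocol = list(n_train = n_train, n_test = n_test,
                                           n_trees = n_trees, seed = seed),
                           bias = setNames(bias, classes),
                           train_idx = best$train_idx,
                           test_idx = best$test_idx,
                           structure = structure, labels = y_all),
                      class = "classifier_report")
  report
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(paste0("<classifier_report> %d classes, %d trees, ",
                     "best of %d restarts (restart %d)\n"),
              length(x$classes), length(x$trees), x$restarts, x$restart))
  cat(sprintf("  held-out accuracy: %.4f (%d train / %d test per structure)\n",
              x$accuracy, x$protocol$n_train, x$protocol$n_test))
  invisible(x)
}

#' Soft-vote class probabilities of the trained forest
#'
#' @param report a `classifier_report`
#' @param x numeric feature vector or matrix of rows
#' @return class-probability vector (or matrix)
#' @export
predict_prob <- function(report, x) {
  if (is.matrix(x)) {
    out <- t(apply(x, 1, function(r) forest_predict_prob(report, r)))
    colnames(out) <- report$classes
    return(out)
  }
  setNames(forest_predict_prob(report, x), report$classes)
}

#' Exact decision-path contribution decomposition
#'
#' Walks every tree's decision path for the sample, attributing the
#' change in node class-probability at each split to the splitting
#' feature and averaging over trees. The identity
#' `bias + colSums(contributions) == predicted probability vector`
#' holds exactly (telescoping along each path).
#'
#' @param report a `classifier_report`
#' @param x numeric feature vector in the report's feature space
#' @return list with `bias`, `contributions` (features x classes) and
#'   `prediction`
#' @export
decompose_prediction <- function(report, x) {
  nf <- length(report$feature_names)
  if (length(x) != nf)
    stop("sample has ", length(x), " features but the forest was trained on ",
         nf)
  nc <- length(report$classes)
  contrib <- matrix(0, nf, nc,
                    dimnames = list(report$feature_names, report$classes))
  pred <- numeric(nc)
  for (t in report$trees) {
    path <- route_tree(t$tree, x)
    for (i in seq_along(path)[-1]) {
      f <- t$tree[path[i - 1], "split var"]
      contrib[f, ] <- contrib[f, ] +
        t$probs[path[i], ] - t$probs[path[i - 1], ]
    }
    pred <- pred + t$probs[path[length(path)], ]
  }
  n <- length(report$trees)
  list(bias = report$bias, contributions = contrib / n,
       prediction = setNames(pred / n, report$classes))
}

#' Export a linkage tree as Newick
#'
#' Branch lengths are differences of merge heights (leaves sit at
#' height zero), so a two-leaf tree at height h is written `(A:h,B:h);`.
#'
#' @param tree a `linkage_tree`
#' @param path output file
#' @export
export_dendrogram <- function(tree, path) {
  stopifnot(inherits(tree, "linkage_tree"))
  merge <- tree$merge; height <- tree$height
  labels <- tree$labels
  if (is.null(labels)) labels <- as.character(seq_len(nrow(merge) + 1))
  node_str <- function(i) {
    if (i < 0) return(list(s = labels[-i], h = 0))
    a <- node_str(merge[i, 1]); b <- node_str(merge[i, 2])
    list(s = sprintf("(%s:%.15g,%s:%.15g)", a$s, height[i] - a$h,
                     b$s, height[i] - b$h),
         h = height[i])
  }
  writeLines(paste0(node_str(nrow(merge))$s, ";"), path)
  invisible(path)
}
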