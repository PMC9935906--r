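toy_scans <- function(values_by_structure, replicates = 3, sigma = 0,
                      seed = 1) {
  set.seed(seed)
  out <- list()
  for (id in names(values_by_structure)) {
    mu <- values_by_structure[[id]]
    df <- expand.grid(replicate = seq_len(replicates),
                      residue = as.integer(names(mu)))
    df$bound_wt <- -100
    df$bound_mut <- -100 + mu[as.character(df$residue)] +
      rnorm(nrow(df), sd = sigma)
    df$structure_id <- id
    out[[id]] <- ingest_external_scores(df)
  }
  out
}

test_that("the profile matrix keeps only residues common to all inputs", {
  a <- setNames(runif(10, 10, 90), 301:310)
  b <- setNames(runif(8, 10, 90), 303:310)
  scans <- toy_scans(list(s1 = a, s2 = b))
  pm <- profile_matrix(scans)
  expect_equal(pm$residues, 303:310)
  expect_equal(nrow(pm$values), 6)

  # identical inputs keep every column
  pm2 <- profile_matrix(toy_scans(list(s1 = a, s2 = a)))
  expect_equal(pm2$residues, 301:310)

  # a position excluded in one structure (no rows) drops everywhere
  expect_error(profile_matrix(toy_scans(list(
    s1 = setNames(1:3, 1:3), s2 = setNames(1:3, 11:13)))), "common")
})

test_that("structure distances are Euclidean on mean profiles", {
  a <- setNames(rep(0, 2), 1:2)
  scans <- toy_scans(list(s1 = a, s2 = a, s3 = a))
  pm <- profile_matrix(scans)
  # overwrite with explicit coordinates to pin the arithmetic
  pm$values <- rbind(matrix(0, 3, 2), matrix(0, 3, 2),
                     matrix(rep(c(3, 4), each = 3), 3, 2))
  pm$structure <- rep(c("s1", "s2", "s3"), each = 3)
  d <- profile_distance_matrix(pm)
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d["s1", "s3"], 5)
  expect_equal(d["s1", "s2"], 0)
  expect_equal(d, t(d))
})

test_that("Ward linkage matches the exhaustive recompute-from-scratch oracle", {
  set.seed(12)
  for (i in 1:12) {
    n <- sample(3:6, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    tree <- ward_cluster(stats::dist(X))
    expect_equal(tree$height, ward_oracle(X), tolerance = 1e-8)
    expect_true(all(diff(tree$height) >= -1e-12))   # Ward monotonicity
  }
  # duplicated points merge first at height zero
  X <- rbind(c(0, 0), c(0, 0), c(5, 5))
  t0 <- ward_cluster(stats::dist(X))
  expect_equal(t0$height[1], 0)
})

test_that("planted Gaussian clusters are recovered by the top split", {
  hits <- 0
  for (seed in 1:40) {
    set.seed(seed)
    X <- rbind(matrix(rnorm(10, 0, 1), 5, 2),
               matrix(rnorm(10, 10, 1), 5, 2))
    tree <- ward_cluster(stats::dist(X))
    grp <- stats::cutree(tree$hclust, k = 2)
    if (length(unique(grp[1:5])) == 1 && length(unique(grp[6:10])) == 1 &&
        grp[1] != grp[10]) hits <- hits + 1
  }
  expect_equal(hits, 40)
})

test_that("feature agglomeration honours k and its identities", {
  set.seed(3)
  V <- matrix(rnorm(60), 6, 10, dimnames = list(NULL, 301:310))
  fc_n <- agglomerate_features(V, k = 10)
  expect_equal(unname(fc_n$assignment), 1:10)
  expect_equal(unname(fc_n$reduced), unname(V))

  fc_1 <- agglomerate_features(V, k = 1)
  expect_equal(unname(fc_1$reduced[, 1]), unname(rowMeans(V)))

  # duplicated columns co-cluster at any k < n
  V2 <- cbind(V, `311` = V[, "305"])
  fc <- agglomerate_features(V2, k = 10)
  expect_equal(fc$assignment[["305"]], fc$assignment[["311"]])
  expect_equal(length(unique(fc$assignment)), 10)

  expect_error(agglomerate_features(V, k = 0), ">= 1")
  expect_error(agglomerate_features(V, k = 11), "exceeds")
})

test_that("agglomeration and classification are column-order invariant", {
  pc <- planted_class_profiles(rng_seed = 3, n_classes = 3, m = 12,
                               n_replicates = 12)
  pm <- profile_matrix(lapply(generate_profiles(pc$spec),
                              ingest_external_scores))
  fc1 <- agglomerate_features(pm, k = 6)
  perm <- sample(ncol(pm$values))
  pm2 <- pm
  pm2$values <- pm$values[, perm]
  fc2 <- agglomerate_features(pm2, k = 6)
  expect_equal(fc2$reduced, fc1$reduced)
  expect_equal(fc2$members, fc1$members)
  r1 <- train_forest(fc1, pm$structure, n_train = 4, n_test = 8,
                     restarts = 3, seed = 5)
  r2 <- train_forest(fc2, pm$structure, n_train = 4, n_test = 8,
                     restarts = 3, seed = 5)
  expect_equal(r1$accuracy, r2$accuracy)
})

test_that("subtype labels map to parent classes", {
  expect_equal(parent_label(c("GGT_T1", "AD-PHF", "AD-SF", "CBD_T2", "PSP")),
               c("GGT", "AD", "AD", "CBD", "PSP"))
  # fallback rule strips unseen subtype suffixes
  expect_equal(parent_label(c("NEW_T3", "XYZ_T1a")), c("NEW", "XYZ"))
  # the shipped table is editable
  own <- data.frame(subtype = "weird", parent = "W")
  expect_equal(parent_label("weird", map = own), "W")
})

test_that("the replicate-split forest separates planted classes", {
  pc <- planted_class_profiles(rng_seed = 2, n_classes = 4, m = 24,
                               n_replicates = 20, noise_sigma = 0.5,
                               effect = 30)
  pm <- profile_matrix(lapply(generate_profiles(pc$spec),
                              ingest_external_scores))
  fc <- agglomerate_features(pm, k = 12)
  rep <- train_forest(fc, pm$structure, n_train = 6, n_test = 14,
                      restarts = 5, seed = 4)
  expect_equal(rep$accuracy, 1)           # near-zero noise: separable
  rep2 <- train_forest(fc, pm$structure, n_train = 6, n_test = 14,
                       restarts = 5, seed = 4)
  expect_identical(rep$accuracy, rep2$accuracy)
  expect_identical(rep$restart, rep2$restart)
  expect_error(train_forest(fc, pm$structure, n_train = 9, n_test = 26,
                            restarts = 2, seed = 1), "below the split")
})

test_that("decision-path contributions decompose predictions exactly", {
  pc <- planted_class_profiles(rng_seed = 5, n_classes = 3, m = 18,
                               n_replicates = 15, noise_sigma = 2)
  pm <- profile_matrix(lapply(generate_profiles(pc$spec),
                              ingest_external_scores))
  fc <- agglomerate_features(pm, k = 10)
  rep <- train_forest(fc, pm$structure, n_train = 5, n_test = 10,
                      restarts = 3, seed = 7)
  for (i in sample(nrow(fc$reduced), 8)) {
    dec <- decompose_prediction(rep, fc$reduced[i, ])
    expect_lt(max(abs(rep$bias + colSums(dec$contributions) -
                        dec$prediction)), 1e-10)
    expect_equal(dec$prediction, predict_prob(rep, fc$reduced[i, ]))
  }
  expect_error(decompose_prediction(rep, fc$reduced[1, 1:3]), "features")
})

test_that("a depth-one tree attributes the whole probability shift", {
  # two separable clusters on a single informative feature
  set.seed(21)
  X <- cbind(info = c(rnorm(10, 0), rnorm(10, 10)), noise = 0)
  y <- rep(c("a", "b"), each = 10)
  rf <- randomForest::randomForest(X, factor(y), ntree = 1, maxnodes = 2,
                                   mtry = 2)
  tr <- randomForest::getTree(rf, 1, labelVar = FALSE)
  colnames(tr) <- c("left daughter", "right daughter", "split var",
                    "split point", "status", "prediction")
  probs <- fibrilscan:::node_probabilities(tr, X, as.integer(factor(y)), 2)
  report <- structure(list(trees = list(list(tree = tr, probs = probs)),
                           classes = c("a", "b"),
                           feature_names = colnames(X),
                           bias = probs[1, ]),
                      class = "classifier_report")
  dec <- decompose_prediction(report, X[1, ])
  leaf <- fibrilscan:::route_tree(tr, X[1, ])
  expect_equal(unname(dec$contributions["info", ]),
               unname(probs[leaf[length(leaf)], ] - probs[1, ]))
  expect_equal(unname(dec$contributions["noise", ]), c(0, 0))

  # a constant feature is never split on, so its contribution is zero
  pc <- planted_class_profiles(rng_seed = 9, n_classes = 2, m = 8,
                               n_replicates = 12, noise_sigma = 1)
  pm <- profile_matrix(lapply(generate_profiles(pc$spec),
                              ingest_external_scores))
  red <- cbind(agglomerate_features(pm, k = 5)$reduced, const = 7)
  rep2 <- train_forest(red, pm$structure, n_train = 4, n_test = 8,
                       restarts = 2, seed = 2)
  dec2 <- decompose_prediction(rep2, red[3, ])
  expect_equal(unname(dec2$contributions["const", ]), c(0, 0))
})

test_that("dendrograms export as Newick and round-trip", {
  X <- rbind(A = c(0, 0), B = c(3, 4))
  tree <- ward_cluster(stats::dist(X))
  f <- tempfile(fileext = ".nwk")
  export_dendrogram(tree, f)
  expect_equal(readLines(f), "(A:5,B:5);")

  skip_if_not_installed("ape")
  set.seed(6)
  X2 <- matrix(rnorm(12), 6, 2,
               dimnames = list(paste0("s", 1:6), NULL))
  t2 <- ward_cluster(stats::dist(X2))
  f2 <- tempfile(fileext = ".nwk")
  export_dendrogram(t2, f2)
  ph <- ape::read.tree(f2)
  expect_setequal(ph$tip.label, rownames(X2))
  # leaf depths equal the root merge height (ultrametric by construction)
  depths <- ape::node.depth.edgelength(ph)[seq_along(ph$tip.label)]
  expect_equal(unname(depths), rep(max(t2$height), 6), tolerance = 1e-9)
})
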