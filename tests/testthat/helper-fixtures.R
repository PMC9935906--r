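# Shared fixtures and independent oracles. Heavy objects are memoised
# per test run so the scan-based tests reuse one computation.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

two_sided_fibril <- function() {
  memo("ts_fib", generate_fibril(fold_presets()$two_sided))
}

## Reduced-size scan configuration used throughout the suite (replicate
## count scaled down from the full 35-replicate protocol).
test_scan_config <- function(seed = 1, n_replicates = 2) {
  scan_config(n_replicates = n_replicates, rng_seed = seed)
}

two_sided_scan <- function(seed = 1) {
  memo(paste0("ts_scan_", seed),
       run_alanine_scan(two_sided_fibril(), test_scan_config(seed),
                        structure_id = "two_sided"))
}

small_fibril <- function(sequence = "SATSL", n_layers = 3, rise = 4.75,
                         twist = -1, jitter = 0, seed = 1) {
  path <- cbind(seq(0, by = 3.8, length.out = nchar(sequence)), 0)
  generate_fibril(fibril_spec(sequence, path, rise = rise, twist = twist,
                              n_layers = n_layers, jitter_sigma = jitter,
                              rng_seed = seed))
}

serpentine_path_test <- fibrilscan:::serpentine_path

## --- independent oracles -------------------------------------------------

## Dense-lattice Shrake-Rupley reimplementation in plain R (random
## rotations of a Fibonacci lattice are not needed: density is the
## oracle's authority).
sasa_oracle <- function(atoms, probe = 1.4, n_points = 10000) {
  tab <- read.delim(system.file("extdata", "element_params.tsv",
                                package = "fibrilscan"))
  R <- tab$radius[match(atoms$element, tab$element)] + probe
  k <- seq_len(n_points) - 1
  z <- 1 - (2 * k + 1) / n_points
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * k
  pts <- cbind(r * cos(phi), r * sin(phi), z)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  vapply(seq_len(nrow(atoms)), function(i) {
    sp <- sweep(pts * R[i], 2, xyz[i, ], "+")
    blocked <- rep(FALSE, n_points)
    for (j in seq_len(nrow(atoms))[-i]) {
      d2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      blocked <- blocked | d2 < R[j]^2
    }
    4 * pi * R[i]^2 * mean(!blocked)
  }, numeric(1))
}

## Brute-force rigid superposition: dense random-quaternion search plus
## Nelder-Mead refinement of the rotation (translation optimal at the
## centroids for any rotation).
superpose_oracle <- function(mobile, target, n_grid = 3000, seed = 1) {
  set.seed(seed)
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(target, 2, colMeans(target))
  quat_rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  rmsd_of <- function(q) {
    Rq <- quat_rot(q)
    sqrt(mean(rowSums((A %*% t(Rq) - B)^2)))
  }
  qs <- matrix(rnorm(4 * n_grid), ncol = 4)
  vals <- apply(qs, 1, rmsd_of)
  best <- qs[which.min(vals), ]
  opt <- optim(best, rmsd_of, method = "Nelder-Mead",
               control = list(maxit = 4000, reltol = 1e-15))
  opt2 <- optim(opt$par, rmsd_of, method = "Nelder-Mead",
                control = list(maxit = 4000, reltol = 1e-15))
  opt2$value
}

## Exhaustive Ward: at every step recompute the increase in
## within-cluster sum of squares from scratch and merge the cheapest
## pair; heights are sqrt(2 * dESS) (the ward.D2 scale).
ward_oracle <- function(X) {
  cl <- as.list(seq_len(nrow(X)))
  ess <- function(idx) {
    if (length(idx) == 1) return(0)
    m <- colMeans(X[idx, , drop = FALSE])
    sum(sweep(X[idx, , drop = FALSE], 2, m)^2)
  }
  heights <- numeric(0)
  while (length(cl) > 1) {
    best <- Inf; bi <- 0; bj <- 0
    for (i in 1:(length(cl) - 1)) {
      for (j in (i + 1):length(cl)) {
        d <- ess(c(cl[[i]], cl[[j]])) - ess(cl[[i]]) - ess(cl[[j]])
        if (d < best) { best <- d; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, sqrt(2 * best))
    cl[[bi]] <- c(cl[[bi]], cl[[bj]])
    cl[[bj]] <- NULL
  }
  heights
}

## Helper shared by the classifier tests: does every structure's
## top-contribution cluster contain one of its class's planted
## distinctive residues?
top_clusters_distinctive <- function(report, fc, pm, distinctive) {
  ok <- 0; tot <- 0
  for (id in unique(pm$structure)) {
    cls <- parent_label(id)
    mx <- colMeans(fc$reduced[pm$structure == id, , drop = FALSE])
    dec <- decompose_prediction(report, mx)
    top <- which.max(dec$contributions[, cls])
    tot <- tot + 1
    if (any(as.integer(fc$members[[top]]) %in% distinctive[[cls]]))
      ok <- ok + 1
  }
  c(ok = ok, tot = tot)
}
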