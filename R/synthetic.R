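#' Specification for a synthetic cross-beta fibril
#'
#' Describes an idealised layered fibril: a 2-D fold path in the layer
#' plane (CA positions, ~3.8 A apart), a per-layer helical rise and
#' twist, the layer count and optional coordinate jitter. The defaults
#' sit inside the canonical cross-beta spacing (rise 4.75 A) with a
#' gentle left-handed twist.
#'
#' @param sequence one-letter amino-acid string, one residue per path point
#' @param fold_path n x 2 matrix of in-plane CA positions (A)
#' @param rise inter-layer rise in A
#' @param twist inter-layer twist in degrees
#' @param n_layers number of stacked layers
#' @param jitter_sigma Gaussian coordinate noise (A) applied to all atoms
#' @param rng_seed seed for the jitter
#' @param numbering_start author number of the first residue
#' @return a `fibril_spec` list
#' @export
fibril_spec <- function(sequence, fold_path, rise = 4.75, twist = -1.0,
                        n_layers = 9, jitter_sigma = 0, rng_seed = 1,
                        numbering_start = 1) {
  fold_path <- as.matrix(fold_path)
  n <- nchar(sequence)
  if (nrow(fold_path) != n)
    stop("fold_path must have one point per residue")
  steps <- sqrt(rowSums(diff(fold_path)^2))
  if (any(abs(steps - 3.8) > 0.2))
    stop("consecutive fold-path points must be ~3.8 A apart (CA spacing)")
  structure(list(sequence = toupper(sequence), fold_path = fold_path,
                 rise = rise, twist = twist, n_layers = n_layers,
                 jitter_sigma = jitter_sigma, rng_seed = rng_seed,
                 numbering_start = numbering_start),
            class = "fibril_spec")
}

## One flat layer threaded along the fold path: backbone in the layer
## plane (carbonyl O alternating along the fibril axis), CB pointing to
## the left/right of the path on alternating residues, simplified
## zigzag side chains.
thread_layer <- function(spec, chain = "A") {
  path <- spec$fold_path
  path <- sweep(path, 2, colMeans(path))          # center on the helical axis
  n <- nrow(path)
  seq1 <- strsplit(spec$sequence, "")[[1]]
  aa3 <- aa_three(seq1)
  resno <- spec$numbering_start + seq_len(n) - 1
  p3 <- cbind(path, 0)
  tangent <- function(i) {
    a <- max(1, i - 1); b <- min(n, i + 1)
    unitv(p3[b, ] - p3[a, ])
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    t <- tangent(i)
    z <- c(0, 0, 1)
    nv <- vcross(z, t)                           # in-plane left normal
    s <- if (i %% 2 == 0) 1 else -1
    CA <- p3[i, ]
    # beta-pleat: amide N and carbonyl C dip alternately along the
    # fibril axis, giving a physical N-CA-C angle
    N <- CA - 1.20 * t + 0.40 * s * z
    C <- CA + 1.25 * t + 0.40 * s * z
    O <- C + BOND$c_o * s * z
    res <- rbind(atom_row(chain, resno[i], aa3[i], "N", N),
                 atom_row(chain, resno[i], aa3[i], "CA", CA),
                 atom_row(chain, resno[i], aa3[i], "C", C),
                 atom_row(chain, resno[i], aa3[i], "O", O))
    if (aa3[i] != "GLY") {
      f <- if (i %% 2 == 0) 1 else -1            # alternating sheet faces
      CB <- CA + BOND$ca_cb * f * nv
      res <- rbind(res, atom_row(chain, resno[i], aa3[i], "CB", CB))
      sc <- sidechain_rows(aa3[i], resno[i], chain, N, CA, CB)
      if (!is.null(sc)) res <- rbind(res, sc)
    }
    rows[[i]] <- res
  }
  do.call(rbind, rows)
}

#' Generate an idealised cross-beta fibril
#'
#' Threads the sequence onto the fold path with idealised backbone
#' geometry and side chains pointing alternately to the two sheet faces,
#' then stacks `n_layers` copies with the rigid (rise, twist) helical
#' transform about the axis through the path centroid. Deterministic
#' given `rng_seed`; optional Gaussian jitter models coordinate noise.
#'
#' @param spec a [fibril_spec()]
#' @return a `fibril_assembly` (chain A is the top layer)
#' @export
generate_fibril <- function(spec) {
  stopifnot(inherits(spec, "fibril_spec"))
  path <- spec$fold_path
  if (nrow(path) > 2) {
    d <- as.matrix(stats::dist(path))
    off <- abs(row(d) - col(d)) > 1
    if (min(d[off]) < 3.0)
      stop("self-intersecting fold path: non-adjacent CA pair closer than 3 A")
  }
  layer <- thread_layer(spec)
  down <- c(0, 0, -1)
  layers <- vector("list", spec$n_layers)
  xyz0 <- as.matrix(layer[, c("x", "y", "z")])
  for (k in seq_len(spec$n_layers)) {
    R <- rotation_about_axis(down, (k - 1) * spec$twist)
    xyz <- xyz0 %*% t(R)
    xyz[, 3] <- xyz[, 3] - (k - 1) * spec$rise
    lk <- layer
    lk$chain <- CHAIN_ID_POOL[k]
    lk[, c("x", "y", "z")] <- xyz
    layers[[k]] <- lk
  }
  atoms <- do.call(rbind, layers)
  if (spec$jitter_sigma > 0) {
    set.seed(spec$rng_seed)
    atoms[, c("x", "y", "z")] <- as.matrix(atoms[, c("x", "y", "z")]) +
      rnorm(3 * nrow(atoms), sd = spec$jitter_sigma)
  }
  a <- new_assembly(atoms, chain_order = CHAIN_ID_POOL[seq_len(spec$n_layers)],
                    provenance = list(source = "generate_fibril",
                                      log = character()))
  log_event(a, event = "generate_fibril", n_layers = spec$n_layers,
            rise = spec$rise, twist = spec$twist,
            jitter_sigma = spec$jitter_sigma, rng_seed = spec$rng_seed)
}

## Turtle-walk serpentine: strands of `strand_len` CA steps joined by
## 3-residue U-turns. Each turn's three step headings are chosen so the
## sheet-to-sheet gap equals the requested value (gap = spacing * (1 +
## 2 sin theta)); side chains of facing strands interdigitate with a
## half-period (3.8 A) lateral offset.
serpentine_path <- function(n_strands, strand_len, spacing = 3.8,
                            gaps = rep(9.2, max(0, n_strands - 1))) {
  headings <- numeric(0)
  h <- 0
  for (s in seq_len(n_strands)) {
    n_moves <- if (s == 1) strand_len - 1 else strand_len
    headings <- c(headings, rep(h, n_moves))
    if (s < n_strands) {
      sin_th <- (gaps[s] / spacing - 1) / 2
      if (sin_th <= 0 || sin_th > 1)
        stop("gap must lie in (spacing, 3*spacing]")
      theta <- asin(sin_th) / DEG
      dirs <- if (h %% 360 == 0) c(theta, 90, 180 - theta)
              else c(180 - theta, 90, theta)   # mirrored turn on the way back
      headings <- c(headings, dirs)
      h <- (h + 180) %% 360
    }
  }
  pts <- matrix(0, length(headings) + 1, 2)
  for (i in seq_along(headings))
    pts[i + 1, ] <- pts[i, ] +
      spacing * c(cos(headings[i] * DEG), sin(headings[i] * DEG))
  unname(pts)
}

#' Fold-path presets for the main fibril topology classes
#'
#' Three deterministic presets mirroring the coarse fold taxonomy of
#' tau protofilaments: `two_sided` (three-strand serpentine whose
#' central strand is buried on both faces, with Ile313/Phe314/Leu315
#' planted as buried large-nonpolar hotspots against a short-polar
#' background), `one_sided` (two-strand hairpin, C-shaped) and
#' `straight` (single-strand control).
#'
#' @return named list of `fibril_spec` objects (9 layers, rise 4.75 A,
#'   twist -1 degree)
#' @export
fold_presets <- function() {
  two_sided <- fibril_spec(
    sequence = "KSTTTSKSGSSTIFLSSSGSSTSSTKT",
    fold_path = serpentine_path(3, 7, gaps = c(9.2, 8.0)),
    numbering_start = 301)
  one_sided <- fibril_spec(
    sequence = "TSNVKLTKGSSGNASTS",
    fold_path = serpentine_path(2, 7, gaps = 8.0),
    numbering_start = 301)
  straight <- fibril_spec(
    sequence = "VQIVYKSTNSAGKTE",
    fold_path = serpentine_path(1, 15),
    numbering_start = 306)
  list(two_sided = two_sided, one_sided = one_sided, straight = straight)
}

#' Planted buried-hotspot positions of the `two_sided` preset
#' @return author residue numbers of the planted Ile/Phe/Leu
#' @export
planted_hotspots <- function() c(313L, 314L, 315L)

#' Specification for synthetic replicate-structured energy profiles
#'
#' Emulates the replicate structure of the alanine scan: per class, a
#' mean per-residue profile; per structure and replicate, the class mean
#' plus Gaussian noise clipped at zero.
#'
#' @param class_means named list mapping class name to a numeric mean
#'   profile (values on the 0-100 scale, one per residue)
#' @param n_structures structures per class
#' @param n_replicates replicates per structure (default 35)
#' @param noise_sigma replicate noise s.d.
#' @param rng_seed seed
#' @param residues author residue numbers (default 1..m)
#' @return a `profile_spec` list
#' @export
profile_spec <- function(class_means, n_structures = 2, n_replicates = 35,
                         noise_sigma = 5, rng_seed = 1, residues = NULL) {
  m <- length(class_means[[1]])
  stopifnot(all(vapply(class_means, length, 1L) == m), n_replicates >= 1)
  if (any(unlist(class_means) < 0 | unlist(class_means) > 100))
    stop("class means must lie in [0, 100]")
  if (is.null(residues)) residues <- seq_len(m)
  structure(list(class_means = class_means, n_structures = n_structures,
                 n_replicates = n_replicates, noise_sigma = noise_sigma,
                 rng_seed = rng_seed, residues = residues),
            class = "profile_spec")
}

#' Planted-class profile study: per-class means with distinctive residues
#'
#' Builds a [profile_spec()] for classifier studies: a shared base
#' profile with `n_distinctive` class-specific residues per class
#' raised by `effect` (default three noise s.d.), labelled with the
#' parent fibril class names so the subtype-to-parent mapping is
#' exercised end to end.
#'
#' @param rng_seed seed controlling the base profile and residue draw
#' @param n_classes number of parent classes (up to 7)
#' @param n_distinctive class-specific residues per class
#' @param m residues per profile
#' @param noise_sigma replicate noise s.d.
#' @param effect mean shift of distinctive residues (default 3 sigma)
#' @param n_structures structures per class
#' @param n_replicates replicates per structure
#' @return list with `spec` (a `profile_spec`) and `distinctive`
#'   (class -> residue numbers)
#' @export
planted_class_profiles <- function(rng_seed = 1, n_classes = 7,
                                   n_distinctive = 4, m = 48,
                                   noise_sigma = 5, effect = 3 * noise_sigma,
                                   n_structures = 2, n_replicates = 35) {
  classes <- c("AD", "CBD", "CTE", "PiD", "PSP", "GGT", "GPT")[seq_len(n_classes)]
  set.seed(rng_seed)
  base <- runif(m, 15, 55)
  picks <- sample(m, n_distinctive * n_classes)
  distinctive <- split(picks, rep(classes, each = n_distinctive))[classes]
  means <- lapply(classes, function(cl) {
    v <- base
    v[distinctive[[cl]]] <- pmin(v[distinctive[[cl]]] + effect, 100)
    v
  })
  names(means) <- classes
  list(spec = profile_spec(means, n_structures = n_structures,
                           n_replicates = n_replicates,
                           noise_sigma = noise_sigma,
                           rng_seed = derive_seed(rng_seed, 7)),
       distinctive = distinctive)
}

#' Generate synthetic per-residue, per-replicate score tables
#'
#' Emits one table per structure in the external-score schema accepted
#' by [ingest_external_scores()] (`bound_wt` is a constant baseline and
#' `bound_mut - bound_wt` carries the planted value).
#'
#' @param spec a [profile_spec()]
#' @return named list of data.frames, one per structure; names are
#'   structure ids of the form `<class>_T<k>`
#' @export
generate_profiles <- function(spec) {
  stopifnot(inherits(spec, "profile_spec"))
  set.seed(spec$rng_seed)
  out <- list()
  for (cl in names(spec$class_means)) {
    mu <- spec$class_means[[cl]]
    for (s in seq_len(spec$n_structures)) {
      id <- sprintf("%s_T%d", cl, s)
      rows <- expand.grid(replicate = seq_len(spec$n_replicates),
                          residue = spec$residues)
      rows <- rows[order(rows$residue, rows$replicate), ]
      vals <- rep(mu, each = spec$n_replicates) +
        rnorm(nrow(rows), sd = spec$noise_sigma)
      vals <- pmax(vals, 0)
      out[[id]] <- data.frame(structure_id = id, residue = rows$residue,
                              replicate = rows$replicate,
                              bound_mut = -100 + vals, bound_wt = -100,
                              stringsAsFactors = FALSE)
    }
  }
  out
}
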