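#' Normalise a per-residue stability profile to the 0-100 scale
#'
#' Min-max normalisation over the non-NA residues, matching the 0-100
#' plasma scale used for hotspot maps (excluded positions stay NA). A
#' degenerate profile (min == max) maps to all zeros.
#'
#' @param raw named numeric vector (names = author residue numbers) of
#'   mean energy changes, or a `scan_result` whose replicate means are
#'   used (excluded positions become NA)
#' @param structure_id identifier stored with the profile
#' @return a `residue_profile`: list with `values` (normalised),
#'   `raw_mean`, `structure_id`
#' @export
normalize_profile <- function(raw, structure_id = "structure") {
  if (inherits(raw, "scan_result")) {
    s <- summary(raw)
    v <- setNames(s$mean_delta_reu, s$position)
    if (nrow(raw$excluded)) {
      ex <- setNames(rep(NA_real_, nrow(raw$excluded)), raw$excluded$position)
      v <- c(v, ex)
      v <- v[order(as.integer(names(v)))]
    }
    structure_id <- raw$structure_id
    raw <- v
  }
  ok <- !is.na(raw)
  if (!any(ok)) stop("profile has no defined residues")
  if (sum(ok) < 2) stop("need at least 2 non-NA residues to normalise")
  lo <- min(raw[ok]); hi <- max(raw[ok])
  vals <- raw
  vals[ok] <- if (hi - lo < 1e-12) 0 else 100 * (raw[ok] - lo) / (hi - lo)
  structure(list(structure_id = structure_id, values = vals, raw_mean = raw,
                 window = NULL),
            class = "residue_profile")
}

#' @export
print.residue_profile <- function(x, ...) {
  v <- x$values
  cat(sprintf("<residue_profile> %s: %d residues (%d NA), range %s-%s\n",
              x$structure_id, length(v), sum(is.na(v)),
              names(v)[1], names(v)[length(v)]))
  invisible(x)
}

#' Centred moving average over residues
#'
#' Windows are truncated at the termini and NA values are skipped, the
#' divisor being the number of residues actually used, so motif-level
#' maps stay contiguous across excluded positions.
#'
#' @param profile a `residue_profile` or a numeric vector
#' @param w odd window width (default 5)
#' @return same shape as the input values, smoothed; a
#'   `residue_profile` input is returned with `window` filled
#' @export
window_average <- function(profile, w = 5) {
  if (w < 1 || w %% 2 == 0) stop("window width must be an odd integer >= 1")
  vals <- if (inherits(profile, "residue_profile")) profile$values else profile
  n <- length(vals)
  half <- (w - 1) / 2
  out <- vapply(seq_len(n), function(i) {
    win <- vals[max(1, i - half):min(n, i + half)]
    if (all(is.na(win))) NA_real_ else mean(win, na.rm = TRUE)
  }, numeric(1))
  names(out) <- names(vals)
  if (inherits(profile, "residue_profile")) {
    profile$window <- out
    profile
  } else out
}

#' Partition residues into stability hotspots and neutral positions
#'
#' Residues with normalised values above `top_threshold` are hotspots;
#' those below `bottom_threshold` are minimally important; the band in
#' between stays unassigned.
#'
#' @param profile a `residue_profile` (or named numeric on the 0-100 scale)
#' @param top_threshold,bottom_threshold normalised cutoffs (default 40 / 10)
#' @return list with integer vectors `top` and `bottom` (author numbers)
#' @export
identify_hotspots <- function(profile, top_threshold = 40,
                              bottom_threshold = 10) {
  vals <- if (inherits(profile, "residue_profile")) profile$values else profile
  ok <- !is.na(vals)
  list(top = as.integer(names(vals)[ok & vals > top_threshold]),
       bottom = as.integer(names(vals)[ok & vals < bottom_threshold]))
}

kyte_doolittle_scale <- function() {
  if (is.null(.fs_cache$kd)) {
    p <- system.file("extdata", "kyte_doolittle.tsv", package = "fibrilscan",
                     mustWork = TRUE)
    tab <- read.delim(p, stringsAsFactors = FALSE)
    .fs_cache$kd <- setNames(tab$value, tab$aa)
  }
  .fs_cache$kd
}

#' Kyte-Doolittle hydropathy profile of a sequence
#'
#' @param sequence one-letter amino-acid string
#' @param w odd smoothing window (1 = raw per-residue values)
#' @return list with `values` (per residue), `windowed`, `w`
#' @export
hydropathy_profile <- function(sequence, w = 5) {
  kd <- kyte_doolittle_scale()
  seq1 <- strsplit(toupper(sequence), "")[[1]]
  bad <- !seq1 %in% names(kd)
  if (any(bad)) stop("unknown amino acid letter(s): ",
                     paste(unique(seq1[bad]), collapse = ", "))
  vals <- setNames(unname(kd[seq1]), seq_along(seq1))
  list(values = vals, windowed = window_average(vals, w), w = w)
}

#' Exact two-sided Mann-Whitney test
#'
#' The U statistic counts pairs where a group-a value exceeds a group-b
#' value. Without ties and while choose(n1+n2, n1) <= 2e6 the two-sided
#' p-value is computed by full enumeration of label assignments
#' (2 * min tail, capped at 1); otherwise a midrank normal approximation
#' with tie correction (and continuity correction) is used. The `method`
#' field records which path was taken.
#'
#' @param group_a,group_b numeric vectors (n >= 1 each)
#' @return a `group_test`: u_statistic, p_two_sided, n1, n2, method
#' @export
mann_whitney_exact <- function(group_a, group_b) {
  group_a <- as.numeric(group_a); group_b <- as.numeric(group_b)
  n1 <- length(group_a); n2 <- length(group_b)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  pooled <- c(group_a, group_b)
  ranks <- rank(pooled)
  r1 <- sum(ranks[seq_len(n1)])
  u <- r1 - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  n <- n1 + n2
  if (!ties && choose(n, n1) <= 2e6) {
    idx <- combn(n, n1)
    rk <- rank(pooled)
    us <- colSums(matrix(rk[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p_le <- mean(us <= u)
    p_ge <- mean(us >= u)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    tie_corr <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * (n + 1 - tie_corr))
    z <- (u - mu)
    z <- sign(z) * max(0, abs(z) - 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approx"
  }
  structure(list(u_statistic = u, p_two_sided = max(p, .Machine$double.xmin),
                 n1 = n1, n2 = n2, method = method),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney (%s): U = %g, two-sided p = %.4g (n1 = %d, n2 = %d)\n",
              x$method, x$u_statistic, x$p_two_sided, x$n1, x$n2))
  invisible(x)
}

#' Write a profile as TSV
#'
#' Columns residue, raw_mean, normalized, windowed.
#'
#' @param profile a `residue_profile`
#' @param path output file
#' @export
write_profile <- function(profile, path) {
  win <- if (is.null(profile$window))
    window_average(profile)$window else profile$window
  df <- data.frame(residue = as.integer(names(profile$values)),
                   raw_mean = unname(profile$raw_mean),
                   normalized = unname(profile$values),
                   windowed = unname(win))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
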