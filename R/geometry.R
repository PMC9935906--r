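#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' paired coordinate sets. Mirror-image (improper) solutions are
#' forbidden by the determinant correction.
#'
#' @param mobile n x 3 matrix moved onto `target`
#' @param target n x 3 matrix
#' @return list with `rotation` (3x3), `translation` (length 3) and
#'   `rmsd` (A); `fitted = mobile %*% t(rotation) + translation`
#' @export
superpose <- function(mobile, target) {
  res <- kabsch(as.matrix(mobile), as.matrix(target))
  class(res) <- "superposition"
  res
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.6f A\n", x$rmsd))
  invisible(x)
}

#' Backbone RMSD between two assemblies
#'
#' Superposes the four backbone atom types (N, CA, C, O) of the selected
#' chains and returns the fitted RMSD.
#'
#' @param a,b `fibril_assembly` objects sharing sequence and numbering
#'   on the selected chains
#' @param chains chain ids to compare (default: all chains of `a`)
#' @return RMSD in Angstrom
#' @export
backbone_rmsd <- function(a, b, chains = a$chain_order) {
  ba <- a$atoms[a$atoms$chain %in% chains & a$atoms$elety %in% BACKBONE_ATOMS, ]
  bb <- b$atoms[b$atoms$chain %in% chains & b$atoms$elety %in% BACKBONE_ATOMS, ]
  ba <- ba[order(ba$chain, ba$resno, atom_rank(ba$elety)), ]
  bb <- bb[order(bb$chain, bb$resno, atom_rank(bb$elety)), ]
  if (nrow(ba) != nrow(bb) ||
      !identical(paste(ba$chain, ba$resno, ba$elety),
                 paste(bb$chain, bb$resno, bb$elety)))
    stop("residue/atom sets of the two assemblies do not match on the subset")
  superpose(as.matrix(ba[, c("x", "y", "z")]),
            as.matrix(bb[, c("x", "y", "z")]))$rmsd
}

#' Backbone torsion angles of every residue
#'
#' Computes phi, psi and omega per residue with the IUPAC sign
#' convention, degrees in (-180, 180]. Terminal residues and residues
#' across a chain break (peptide C-N distance > 2.5 A) carry NA for the
#' affected angles.
#'
#' @param assembly a `fibril_assembly`
#' @return data.frame with chain, resno, aa, phi, psi, omega
#' @export
backbone_torsions <- function(assembly) {
  out <- list()
  for (ch in assembly$chain_order) {
    lay <- assembly$atoms[assembly$atoms$chain == ch, , drop = FALSE]
    resnos <- sort(unique(lay$resno))
    get <- function(rn, nm) {
      r <- lay[lay$resno == rn & lay$elety == nm, c("x", "y", "z")]
      if (nrow(r) == 0) return(NULL)
      as.numeric(r[1, ])
    }
    n <- length(resnos)
    phi <- psi <- omg <- rep(NA_real_, n)
    linked <- function(i) {
      # peptide bond between residue i and i+1 intact?
      if (i < 1 || i >= n) return(FALSE)
      if (resnos[i + 1] != resnos[i] + 1) return(FALSE)
      c1 <- get(resnos[i], "C"); n2 <- get(resnos[i + 1], "N")
      !is.null(c1) && !is.null(n2) && vnorm(n2 - c1) <= 2.5
    }
    for (i in seq_len(n)) {
      Ni <- get(resnos[i], "N"); CAi <- get(resnos[i], "CA")
      Ci <- get(resnos[i], "C")
      if (linked(i - 1)) {
        Cp <- get(resnos[i - 1], "C"); CAp <- get(resnos[i - 1], "CA")
        phi[i] <- dihedral_points(Cp, Ni, CAi, Ci)
        omg[i] <- dihedral_points(CAp, Cp, Ni, CAi)
      }
      if (linked(i)) {
        Nn <- get(resnos[i + 1], "N")
        psi[i] <- dihedral_points(Ni, CAi, Ci, Nn)
      }
    }
    aa <- vapply(resnos, function(rn) aa_one(lay$resid[lay$resno == rn][1]),
                 character(1))
    out[[ch]] <- data.frame(chain = ch, resno = resnos, aa = aa,
                            phi = phi, psi = psi, omega = omg,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Load the phi/psi permissibility reference grids
#'
#' The shipped grids are synthetic stand-ins: smooth mixture densities
#' over 5 x 5 degree bins emulating the torsion statistics of alanine-like
#' and glycine residues in high-resolution globular structures. Any grid
#' in the same plain-text format (first column phi bin centers, remaining
#' columns psi bin centers) can be swapped in.
#'
#' @param ala,gly paths to replacement grids (optional)
#' @return list with `ala` and `gly` probability matrices plus bin edges
#' @export
load_permissibility_grid <- function(ala = NULL, gly = NULL) {
  rd <- function(path) {
    df <- read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1])
    rownames(m) <- df[[1]]
    m / sum(m)
  }
  if (is.null(ala))
    ala <- system.file("extdata", "synthetic_rama_ala.tsv",
                       package = "fibrilscan", mustWork = TRUE)
  if (is.null(gly))
    gly <- system.file("extdata", "synthetic_rama_gly.tsv",
                       package = "fibrilscan", mustWork = TRUE)
  list(ala = rd(ala), gly = rd(gly), edges = seq(-180, 180, by = 5))
}

contour_level <- function(g, mass) {
  v <- sort(as.vector(g), decreasing = TRUE)
  v[which(cumsum(v) >= mass)[1]]
}

#' Torsion permissibility for alanine and glycine
#'
#' A (phi, psi) pair is permissible when its bin lies inside the
#' highest-density region containing `mass` of the reference
#' distribution (default: the 99.5 percent mass contour).
#'
#' @param record list or one-row data.frame with `phi` and `psi` (deg)
#' @param reference grids from [load_permissibility_grid()]
#' @param mass density quantile defining the contour
#' @return list with logicals `allowed_for_ala` and `allowed_for_gly`
#' @export
classify_torsion_permissibility <- function(record,
                                            reference = load_permissibility_grid(),
                                            mass = 0.995) {
  phi <- record$phi; psi <- record$psi
  if (is.null(phi) || is.null(psi) || is.na(phi) || is.na(psi))
    stop("undefined phi/psi: permissibility requires both torsions")
  wrap <- function(x) ((x + 180) %% 360) - 180
  i <- findInterval(wrap(phi), reference$edges, rightmost.closed = TRUE)
  j <- findInterval(wrap(psi), reference$edges, rightmost.closed = TRUE)
  chk <- function(g) unname(g[i, j] >= contour_level(g, mass))
  list(allowed_for_ala = chk(reference$ala),
       allowed_for_gly = chk(reference$gly))
}
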