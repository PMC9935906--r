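.fs_cache <- new.env(parent = emptyenv())

element_params <- function() {
  if (is.null(.fs_cache$elem)) {
    p <- system.file("extdata", "element_params.tsv", package = "fibrilscan",
                     mustWork = TRUE)
    .fs_cache$elem <- read.delim(p, stringsAsFactors = FALSE)
  }
  .fs_cache$elem
}

atom_radii <- function(element) {
  tab <- element_params()
  r <- tab$radius[match(element, tab$element)]
  if (anyNA(r))
    stop("no van der Waals radius for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  r
}

as_atom_table <- function(x) {
  if (inherits(x, "fibril_assembly")) x$atoms else x
}

#' Per-residue solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic golden-section spiral point lattice; per-atom areas are
#' summed per residue. Hydrogens are assumed absent (the readers drop
#' them).
#'
#' @param x a `fibril_assembly` or an atom data.frame (columns chain,
#'   resno, element, x, y, z)
#' @param probe_radius probe radius in A
#' @param n_points sphere points per atom (>= 92)
#' @return data.frame chain, resno, area; per-atom areas in
#'   `attr(, "atom_area")`
#' @export
residue_sasa <- function(x, probe_radius = 1.4, n_points = 960) {
  atoms <- as_atom_table(x)
  if (n_points < 92) stop("n_points must be >= 92")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- atom_radii(atoms$element)
  area <- .sasa_kernel(xyz, rad, probe_radius, as.integer(n_points))
  key <- paste(atoms$chain, atoms$resno)
  agg <- rowsum(area, key)
  u <- !duplicated(key)
  out <- data.frame(chain = atoms$chain[u], resno = atoms$resno[u],
                    area = as.vector(agg[match(key[u], rownames(agg)), ]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "atom_area") <- area
  out
}

#' Build an extended monomer reference state
#'
#' An idealised beta-extended chain (phi = -120, psi = +120 by default)
#' with side chains in extended conformers, used as the unfolded
#' reference for folding-burial calculations.
#'
#' @param sequence one-letter sequence
#' @param numbering_start author number of the first residue
#' @param phi,psi extended-state torsions (degrees)
#' @return a one-layer `fibril_assembly`
#' @export
build_extended_monomer <- function(sequence, numbering_start = 1,
                                   phi = -120, psi = 120) {
  build_peptide(sequence, numbering_start, phi = phi, psi = psi)
}

#' Two-state folding burial per residue
#'
#' Computes per-residue SASA in three states: the fully extended
#' monomer, the central layer extracted alone, and the central layer in
#' the middle of the central three layers of the fibril. The burial
#' differences are `dsasa_single_layer = extended - monomer` and
#' `dsasa_fibril = extended - in_fibril`; extra layers only bury, so
#' `dsasa_fibril >= dsasa_single_layer` residue by residue.
#'
#' @param assembly a `fibril_assembly` with at least 3 layers
#' @param probe_radius,n_points passed to [residue_sasa()]
#' @return a `sasa_report` data.frame with columns resno, aa,
#'   sasa_extended, sasa_monomer, sasa_fibril, dsasa_single_layer,
#'   dsasa_fibril
#' @export
delta_sasa_folding <- function(assembly, probe_radius = 1.4, n_points = 960) {
  n <- n_layers(assembly)
  if (n < 3) stop("delta_sasa_folding needs >= 3 layers (central trimer)")
  res <- assembly_residues(assembly)
  mid <- (n + 1) %/% 2
  ext <- build_extended_monomer(paste(res$aa, collapse = ""),
                                numbering_start = res$resno[1])
  mono <- layer_atoms(assembly, mid)
  trimer <- assembly$atoms[assembly$atoms$chain %in%
                             assembly$chain_order[(mid - 1):(mid + 1)], ]
  s_ext <- residue_sasa(ext, probe_radius, n_points)
  s_mono <- residue_sasa(mono, probe_radius, n_points)
  s_tri <- residue_sasa(trimer, probe_radius, n_points)
  s_tri <- s_tri[s_tri$chain == assembly$chain_order[mid], ]
  out <- data.frame(resno = res$resno, aa = res$aa,
                    sasa_extended = s_ext$area[match(res$resno, s_ext$resno)],
                    sasa_monomer = s_mono$area[match(res$resno, s_mono$resno)],
                    sasa_fibril = s_tri$area[match(res$resno, s_tri$resno)])
  out$dsasa_single_layer <- out$sasa_extended - out$sasa_monomer
  out$dsasa_fibril <- out$sasa_extended - out$sasa_fibril
  attr(out, "probe_radius") <- probe_radius
  class(out) <- c("sasa_report", "data.frame")
  out
}

#' Buried nonpolar area per residue
#'
#' The solvent-accessible area of carbon and sulfur atoms lost between
#' the extended monomer and the central in-fibril layer; the surrogate's
#' per-residue measure of nonpolar burial.
#'
#' @inheritParams delta_sasa_folding
#' @return data.frame resno, aa, buried_nonpolar (A^2)
#' @export
nonpolar_burial <- function(assembly, probe_radius = 1.4, n_points = 960) {
  n <- n_layers(assembly)
  if (n < 3) stop("nonpolar_burial needs >= 3 layers")
  res <- assembly_residues(assembly)
  mid <- (n + 1) %/% 2
  ext <- build_extended_monomer(paste(res$aa, collapse = ""),
                                numbering_start = res$resno[1])
  trimer <- assembly$atoms[assembly$atoms$chain %in%
                             assembly$chain_order[(mid - 1):(mid + 1)], ]
  np_area <- function(atoms) {
    s <- residue_sasa(atoms, probe_radius, n_points)
    aa <- attr(s, "atom_area")
    np <- atoms$element %in% c("C", "S")
    agg <- rowsum(aa[np], atoms$resno[np])
    setNames(as.vector(agg), rownames(agg))
  }
  a_ext <- np_area(ext$atoms)
  mid_chain <- trimer[trimer$chain == assembly$chain_order[mid], ]
  # areas of the central chain inside the trimer
  s <- residue_sasa(trimer, probe_radius, n_points)
  aa <- attr(s, "atom_area")
  sel <- trimer$chain == assembly$chain_order[mid] &
    trimer$element %in% c("C", "S")
  agg <- rowsum(aa[sel], trimer$resno[sel])
  a_fib <- setNames(as.vector(agg), rownames(agg))
  key <- as.character(res$resno)
  data.frame(resno = res$resno, aa = res$aa,
             buried_nonpolar = unname(a_ext[key] - a_fib[key]))
}
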