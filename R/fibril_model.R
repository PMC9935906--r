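#' @useDynLib fibrilscan, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm setNames sd cor predict quantile
#' @importFrom tools file_ext
#' @importFrom utils read.delim write.table head combn
NULL

CHAIN_ID_POOL <- c(LETTERS, letters, as.character(0:9))

atom_rank <- function(elety) {
  r <- match(elety, BACKBONE_ATOMS)
  r[is.na(r)] <- length(BACKBONE_ATOMS) + 1L
  r
}

## Internal constructor. `atoms` is a data.frame with columns chain,
## resno, ins, resid, elety, element, x, y, z, o, b. When `chain_order`
## is NULL the layers are ordered by the projection of each chain's CA
## centroid onto the principal axis of the centroids ("top" = smaller
## projection).
new_assembly <- function(atoms, chain_order = NULL, provenance = list(),
                         validate = TRUE) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  atoms$ins[is.na(atoms$ins)] <- ""
  if (is.null(chain_order)) chain_order <- order_layers(atoms)
  atoms <- atoms[order(match(atoms$chain, chain_order), atoms$resno,
                       atom_rank(atoms$elety)), , drop = FALSE]
  rownames(atoms) <- NULL
  a <- structure(list(atoms = atoms, chain_order = chain_order,
                      provenance = provenance),
                 class = "fibril_assembly")
  if (validate) validate_assembly(a)
  a
}

order_layers <- function(atoms) {
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  chains <- unique(atoms$chain)
  cent <- t(vapply(chains, function(ch) {
    m <- ca[ca$chain == ch, c("x", "y", "z"), drop = FALSE]
    colMeans(as.matrix(m))
  }, numeric(3)))
  if (length(chains) == 1L) return(chains)
  cc <- sweep(cent, 2, colMeans(cent))
  sv <- svd(cc)
  ax <- sv$v[, 1]
  proj <- as.vector(cc %*% ax)
  # orient the axis so the first chain in input order sits at the top;
  # round trips then preserve the stored layer order
  if (proj[1] > proj[length(proj)]) proj <- -proj
  chains[order(proj)]
}

validate_assembly <- function(a) {
  atoms <- a$atoms
  if (!all(a$chain_order %in% atoms$chain) ||
      !all(atoms$chain %in% a$chain_order))
    stop("chain_order and atom table disagree")
  if (anyDuplicated(a$chain_order))
    stop("duplicate chain identifiers in assembly")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atomic coordinates")
  ref <- NULL
  for (ch in a$chain_order) {
    lay <- atoms[atoms$chain == ch, , drop = FALSE]
    key <- paste(lay$resno, lay$resid)[!duplicated(lay$resno)]
    for (rn in unique(lay$resno)) {
      res <- lay[lay$resno == rn, , drop = FALSE]
      miss <- setdiff(BACKBONE_ATOMS, res$elety)
      if (length(miss))
        stop(sprintf("chain %s residue %d: missing backbone atom %s",
                     ch, rn, paste(miss, collapse = ",")))
      if (anyDuplicated(res$elety))
        stop(sprintf("chain %s residue %d: duplicate atom names", ch, rn))
    }
    if (is.null(ref)) ref <- key
    else if (!identical(ref, key))
      stop(sprintf("chain %s does not match the first layer's sequence/numbering", ch))
  }
  invisible(a)
}

n_layers <- function(assembly) length(assembly$chain_order)

residues_per_layer <- function(assembly) {
  length(unique(assembly$atoms$resno[assembly$atoms$chain ==
                                       assembly$chain_order[1]]))
}

#' Residue numbering and one-letter sequence of one layer
#'
#' @param assembly a `fibril_assembly`
#' @return data.frame with columns `resno`, `resid`, `aa`
#' @export
assembly_residues <- function(assembly) {
  lay <- assembly$atoms[assembly$atoms$chain == assembly$chain_order[1], ]
  lay <- lay[!duplicated(lay$resno), c("resno", "resid")]
  lay$aa <- aa_one(lay$resid)
  rownames(lay) <- NULL
  lay
}

layer_atoms <- function(assembly, k) {
  assembly$atoms[assembly$atoms$chain == assembly$chain_order[k], , drop = FALSE]
}

assembly_xyz <- function(assembly) as.matrix(assembly$atoms[, c("x", "y", "z")])

`assembly_xyz<-` <- function(assembly, value) {
  assembly$atoms[, c("x", "y", "z")] <- value
  assembly
}

log_event <- function(assembly, ...) {
  entry <- jsonlite::toJSON(list(...), auto_unbox = TRUE)
  assembly$provenance$log <- c(assembly$provenance$log, as.character(entry))
  assembly
}

#' @export
print.fibril_assembly <- function(x, ...) {
  cat(sprintf("<fibril_assembly> %d layers x %d residues (%d atoms)\n",
              n_layers(x), residues_per_layer(x), nrow(x$atoms)))
  cat("  chains (top to bottom): ", paste(x$chain_order, collapse = ""), "\n",
      sep = "")
  seq1 <- paste(assembly_residues(x)$aa, collapse = "")
  cat("  layer sequence: ", seq1, "\n", sep = "")
  invisible(x)
}

#' @export
summary.fibril_assembly <- function(object, ...) {
  res <- assembly_residues(object)
  tr <- if (n_layers(object) >= 2) estimate_layer_transform(object) else NULL
  out <- list(n_layers = n_layers(object),
              residues_per_layer = nrow(res),
              sequence = paste(res$aa, collapse = ""),
              numbering = range(res$resno),
              rise = if (!is.null(tr)) tr$rise else NA_real_,
              twist = if (!is.null(tr)) tr$twist else NA_real_)
  class(out) <- "summary.fibril_assembly"
  out
}

#' @export
print.summary.fibril_assembly <- function(x, ...) {
  cat(sprintf("Fibril assembly: %d layers x %d residues (%d-%d)\n",
              x$n_layers, x$residues_per_layer, x$numbering[1], x$numbering[2]))
  if (is.finite(x$rise))
    cat(sprintf("  rise %.3f A, twist %.3f deg per layer\n", x$rise, x$twist))
  cat("  ", x$sequence, "\n", sep = "")
  invisible(x)
}

#' Read a fibril structure from a PDB or mmCIF coordinate file
#'
#' Each chain becomes one layer; layers are ordered along the fibril
#' axis by the projection of the chain CA centroid onto the principal
#' axis of all chain centroids. Heteroatoms, waters and hydrogens are
#' dropped; alternate locations keep altloc A; author residue numbering
#' is preserved. Non-glycine residues missing a CB atom get one rebuilt
#' from ideal backbone geometry (logged in the provenance).
#'
#' @param path coordinate file (`.pdb`/`.ent` or `.cif`)
#' @param model_index 1-based model to read from multi-model files
#' @return a `fibril_assembly`
#' @export
read_structure <- function(path, model_index = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "cif") {
    pdb <- suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
  } else {
    pdb <- bio3d::read.pdb(path, verbose = FALSE,
                           multi = model_index > 1)
  }
  at <- pdb$atom
  xyz <- if (model_index > 1) {
    if (nrow(pdb$xyz) < model_index)
      stop("model_index ", model_index, " exceeds the ", nrow(pdb$xyz),
           " models in ", path)
    matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
  } else {
    cbind(at$x, at$y, at$z)
  }
  keep <- at$type == "ATOM" & at$resid %in% names(AA1)
  at <- at[keep, , drop = FALSE]
  xyz <- xyz[keep, , drop = FALSE]
  elem <- element_from_name(at$elety)
  keep <- !elem %in% c("H", "D")
  at <- at[keep, , drop = FALSE]
  xyz <- xyz[keep, , drop = FALSE]
  elem <- elem[keep]
  if (nrow(at) == 0) stop("no protein chains found in ", path)
  atoms <- data.frame(chain = as.character(at$chain), resno = at$resno,
                      ins = ifelse(is.na(at$insert), "", as.character(at$insert)),
                      resid = at$resid, elety = at$elety, element = elem,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      o = ifelse(is.na(at$o), 1, at$o),
                      b = ifelse(is.na(at$b), 0, at$b),
                      stringsAsFactors = FALSE)
  if (length(unique(atoms$chain)) < 1) stop("zero chains in ", path)
  if (max(table(unique(atoms[, c("chain", "resno")])$chain)) < 3)
    stop("need at least one chain with >= 3 residues")
  atoms <- rebuild_missing_cb(atoms)
  a <- new_assembly(atoms,
                    provenance = list(source = basename(path), log = character()))
  log_event(a, event = "read_structure", source = basename(path),
            n_layers = n_layers(a), residues_per_layer = residues_per_layer(a))
}

rebuild_missing_cb <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno)
  for (k in unique(key)) {
    res <- atoms[key == k, , drop = FALSE]
    if (res$resid[1] == "GLY" || "CB" %in% res$elety) next
    need <- c("N", "CA", "C")
    if (!all(need %in% res$elety)) next
    p <- function(nm) unlist(res[res$elety == nm, c("x", "y", "z")][1, ])
    n <- p("N"); ca <- p("CA"); cc <- p("C")
    b1 <- unitv(ca - n); b2 <- unitv(ca - cc)
    bis <- unitv(b1 + b2); perp <- unitv(vcross(b2, b1))
    cb <- ca + 1.53 * (cos(0.9557) * bis + sin(0.9557) * perp)
    row <- res[1, ]
    row$elety <- "CB"; row$element <- "C"
    row$x <- cb[1]; row$y <- cb[2]; row$z <- cb[3]
    atoms <- rbind(atoms, row)
  }
  atoms
}

#' Write an assembly as a PDB file
#'
#' Chain identifiers are written as stored; coordinates carry the
#' format's three decimals.
#'
#' @param assembly a `fibril_assembly`
#' @param path output file
#' @export
write_structure <- function(assembly, path) {
  stopifnot(inherits(assembly, "fibril_assembly"))
  atoms <- assembly$atoms
  if (nrow(atoms) == 0) stop("empty assembly")
  if (length(assembly$chain_order) > length(CHAIN_ID_POOL))
    stop("more than ", length(CHAIN_ID_POOL),
         " chains cannot be written to the PDB chain-id field")
  if (anyDuplicated(assembly$chain_order)) stop("chain id collision")
  if (any(nchar(assembly$chain_order) != 1))
    stop("PDB chain ids must be single characters")
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(atoms[, c("x", "y", "z")]))),
                   resno = atoms$resno, chain = atoms$chain,
                   resid = atoms$resid, elety = atoms$elety,
                   eleno = seq_len(nrow(atoms)),
                   o = atoms$o, b = atoms$b, verbose = FALSE)
  invisible(path)
}

#' Restrict an assembly to the chains of one protofilament
#'
#' The retained chains must form a single stack: consecutive layers
#' (after reordering along the stacking axis) must be in contact and
#' separated by a physical rise. A subset that mixes chains of two
#' side-by-side protofilaments has near-zero axial separation between
#' some chains and is rejected.
#'
#' @param assembly a `fibril_assembly`
#' @param chains character vector of chain ids to keep
#' @return the restricted `fibril_assembly`
#' @export
select_protofilament <- function(assembly, chains) {
  stopifnot(inherits(assembly, "fibril_assembly"))
  if (!all(chains %in% assembly$chain_order))
    stop("unknown chain id(s): ",
         paste(setdiff(chains, assembly$chain_order), collapse = ", "))
  atoms <- assembly$atoms[assembly$atoms$chain %in% chains, , drop = FALSE]
  ord <- order_layers(atoms)
  if (length(ord) > 1) {
    ca <- atoms[atoms$elety == "CA", , drop = FALSE]
    cent <- t(vapply(ord, function(ch)
      colMeans(as.matrix(ca[ca$chain == ch, c("x", "y", "z")])), numeric(3)))
    cc <- sweep(cent, 2, colMeans(cent))
    ax <- svd(cc)$v[, 1]
    proj <- sort(as.vector(cc %*% ax))
    gaps <- diff(proj)
    if (any(gaps < 2) || any(gaps > 8))
      stop("selected chains do not form a single stack ",
           "(no single stacking axis): inter-layer spacings ",
           paste(sprintf("%.2f", gaps), collapse = ", "), " A")
    for (i in seq_len(length(ord) - 1)) {
      a1 <- as.matrix(ca[ca$chain == ord[i], c("x", "y", "z")])
      a2 <- as.matrix(ca[ca$chain == ord[i + 1], c("x", "y", "z")])
      dmin <- sqrt(min(outer(rowSums(a1^2), rowSums(a2^2), "+") -
                         2 * a1 %*% t(a2)))
      if (!is.finite(dmin) || dmin > 7)
        stop("selected chains do not form a single stack: chains ",
             ord[i], " and ", ord[i + 1], " are not in contact")
    }
  }
  a <- new_assembly(atoms, chain_order = ord,
                    provenance = assembly$provenance)
  log_event(a, event = "select_protofilament",
            chains = paste(chains, collapse = ""))
}

#' Estimate the rigid transform between consecutive layers
#'
#' A least-squares (Kabsch) rigid transform mapping layer i onto layer
#' i+1 is computed on backbone atoms for every consecutive pair and
#' averaged. The helical rise is the projection of the translation onto
#' the rotation axis (oriented along the stacking direction) and the
#' twist is the signed rotation angle about that axis.
#'
#' @param assembly a `fibril_assembly` with at least two layers
#' @return a `layer_transform`: rotation, translation, rise (A), twist (deg)
#' @export
estimate_layer_transform <- function(assembly) {
  n <- n_layers(assembly)
  if (n < 2) stop("need at least 2 layers to estimate a layer transform")
  Rs <- vector("list", n - 1)
  ts <- matrix(0, n - 1, 3)
  for (i in seq_len(n - 1)) {
    b1 <- backbone_coords(layer_atoms(assembly, i))
    b2 <- backbone_coords(layer_atoms(assembly, i + 1))
    if (nrow(b1) != nrow(b2))
      stop("layers ", i, " and ", i + 1, " have mismatched residue sets")
    k <- kabsch(b1, b2)
    Rs[[i]] <- k$rotation
    ts[i, ] <- k$translation
  }
  Rsum <- Reduce(`+`, Rs)
  sv <- svd(Rsum)
  R <- sv$u %*% diag(c(1, 1, sign(det(sv$u %*% t(sv$v))))) %*% t(sv$v)
  t <- colMeans(ts)
  aa <- axis_angle(R)
  if (aa$angle < 1e-7) {
    rise <- vnorm(t)
    twist <- 0
    axis <- if (rise > 1e-9) unitv(t) else c(0, 0, 1)
  } else {
    axis <- aa$axis
    twist <- aa$angle
    if (sum(t * axis) < 0) { axis <- -axis; twist <- -twist }
    rise <- sum(t * axis)
  }
  structure(list(rotation = R, translation = t, rise = rise, twist = twist,
                 axis = axis),
            class = "layer_transform")
}

#' @export
print.layer_transform <- function(x, ...) {
  cat(sprintf("<layer_transform> rise %.4f A, twist %.4f deg\n",
              x$rise, x$twist))
  invisible(x)
}

backbone_coords <- function(lay) {
  bb <- lay[lay$elety %in% BACKBONE_ATOMS, , drop = FALSE]
  bb <- bb[order(bb$resno, atom_rank(bb$elety)), , drop = FALSE]
  as.matrix(bb[, c("x", "y", "z")])
}

#' Extend or trim a fibril stack to a target number of layers
#'
#' Extension duplicates the assembly, superposes the duplicate's top two
#' layers onto the current bottom two layers using backbone atoms,
#' removes the two overlapping duplicate layers and appends the rest,
#' repeating until the target is reached; the central window is then
#' kept and chains are relettered A... from the top. For exactly
#' helical input, every consecutive-layer transform of the output is
#' identical to the input transform.
#'
#' @param assembly a `fibril_assembly` with at least two layers
#' @param n_target desired layer count (>= 2)
#' @param max_overlap_rmsd largest acceptable backbone RMSD (A) of the
#'   two-layer overlap during stitching
#' @return a `fibril_assembly` with `n_target` layers
#' @export
build_stack <- function(assembly, n_target, max_overlap_rmsd = 0.5) {
  stopifnot(inherits(assembly, "fibril_assembly"))
  n <- n_layers(assembly)
  if (n < 2) stop("extension requires at least 2 layers")
  if (n_target < 2) stop("n_target must be >= 2")
  if (n_target == n) return(assembly)

  layers <- lapply(seq_len(n), function(k) layer_atoms(assembly, k))
  while (length(layers) < n_target) {
    m <- length(layers)
    cur_bot <- rbind(layers[[m - 1]], layers[[m]])
    dup_top <- rbind(layers[[1]], layers[[2]])
    k <- kabsch(backbone_coords(dup_top), backbone_coords(cur_bot))
    if (k$rmsd > max_overlap_rmsd)
      stop(sprintf(paste0("two-layer overlap superposes with backbone RMSD ",
                          "%.3f A (> %.2f A): incompatible stacking geometry"),
                   k$rmsd, max_overlap_rmsd))
    add <- lapply(layers[-(1:2)], function(lay) {
      xyz <- apply_transform(as.matrix(lay[, c("x", "y", "z")]),
                             k$rotation, k$translation)
      lay[, c("x", "y", "z")] <- xyz
      lay
    })
    layers <- c(layers, add)
  }
  start <- ((length(layers) - n_target) %/% 2) + 1
  layers <- layers[start:(start + n_target - 1)]
  if (n_target > length(CHAIN_ID_POOL))
    stop("cannot assign unique chain ids to more than ",
         length(CHAIN_ID_POOL), " layers")
  for (i in seq_along(layers)) layers[[i]]$chain <- CHAIN_ID_POOL[i]
  atoms <- do.call(rbind, layers)
  a <- new_assembly(atoms, chain_order = CHAIN_ID_POOL[seq_len(n_target)],
                    provenance = assembly$provenance)
  log_event(a, event = "build_stack", n_from = n, n_target = n_target)
}
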