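#' Configuration for the alanine scan
#'
#' Captures the scan protocol: replicate count, the neighbourhood that
#' is perturbed and repacked around the mutation site, the harmonic
#' restraint set tethering the structure to its input coordinates, and
#' the energy backend. `sampler_note` carries pass-through parameters
#' for external engines (e.g. a backrub temperature and step count);
#' the built-in backend records but does not use them.
#'
#' @param n_replicates ensemble replicates per position (default 35)
#' @param neighborhood_radius CB-CB radius (A) defining the repacked
#'   neighbourhood around the mutation site
#' @param restraint_pair_cutoff atom-pair distance cutoff (A) for the
#'   harmonic restraints to the input coordinates
#' @param restraint_weight spring weight of those restraints
#' @param perturb_sigma_chi s.d. (degrees) of the chi1 jitter generating
#'   replicate variation
#' @param rng_seed integer seed; every replicate derives its own stream
#' @param backend energy backend name (built-in: "crossbeta")
#' @param exclude_glycine exclude glycine positions from the scan
#' @param max_sweeps coordinate-descent sweep cap during relaxation
#' @param lj_cutoff,lj_switch attractive Lennard-Jones cutoff / switch-on (A)
#' @param elec_cutoff,elec_eps screened-Coulomb cutoff (A) and dielectric
#' @param solv_n_points sphere points per atom for the solvation term
#' @param probe_radius solvent probe (A)
#' @param compute_ddg also compute the central-trimer interface ddG
#'   (needs >= 5 layers)
#' @param sampler_note free-form provenance list for external samplers
#' @return a `scan_config` list
#' @export
scan_config <- function(n_replicates = 35, neighborhood_radius = 8,
                        restraint_pair_cutoff = 9, restraint_weight = 0.02,
                        perturb_sigma_chi = 10, rng_seed = 1,
                        backend = "crossbeta", exclude_glycine = TRUE,
                        max_sweeps = 6, lj_cutoff = 6, lj_switch = 5.5,
                        elec_cutoff = 8, elec_eps = 80, solv_n_points = 92,
                        probe_radius = 1.4, compute_ddg = TRUE,
                        sampler_note = list(backrub_kT = 1.2,
                                            backrub_steps = 35000)) {
  stopifnot(n_replicates >= 1, neighborhood_radius > 0,
            restraint_pair_cutoff > 0)
  if (backend != "crossbeta")
    stop("unknown backend '", backend,
         "'; external engines are ingested via ingest_external_scores()")
  structure(as.list(environment()), class = "scan_config")
}

## Per-atom energy-function inputs for the kernels.
energy_inputs <- function(atoms) {
  tab <- element_params()
  i <- match(atoms$element, tab$element)
  if (anyNA(i))
    stop("unknown element(s) for the energy backend: ",
         paste(unique(atoms$element[is.na(i)]), collapse = ", "))
  chains <- unique(atoms$chain)
  key <- paste(atoms$chain, atoms$resno)
  ukey <- unique(key)
  list(xyz = as.matrix(atoms[, c("x", "y", "z")]),
       eps = tab$lj_eps[i], rmin = tab$radius[i],
       res = match(key, ukey) - 1L,
       chain = match(atoms$chain, chains),
       resno = as.integer(atoms$resno),
       n_res = length(ukey),
       res_chain = sub(" .*", "", ukey),
       res_resno = as.integer(sub(".* ", "", ukey)))
}

charged_atom_mask <- function(atoms) {
  chg <- rep(FALSE, nrow(atoms))
  for (res3 in names(CHARGED_GROUPS))
    chg <- chg | (atoms$resid == res3 &
                    atoms$elety %in% CHARGED_GROUPS[[res3]]$atoms)
  chg
}

charged_sites <- function(atoms) {
  sel <- charged_atom_mask(atoms)
  if (!any(sel)) return(NULL)
  sub <- atoms[sel, , drop = FALSE]
  key <- paste(sub$chain, sub$resno)
  cnt <- rowsum(rep(1, nrow(sub)), key)
  cx <- rowsum(sub$x, key) / cnt
  cy <- rowsum(sub$y, key) / cnt
  cz <- rowsum(sub$z, key) / cnt
  u <- which(!duplicated(key))
  m <- match(key[u], rownames(cnt))
  data.frame(chain = sub$chain[u], resno = sub$resno[u],
             q = vapply(sub$resid[u], function(r) CHARGED_GROUPS[[r]]$q,
                        numeric(1)),
             x = cx[m], y = cy[m], z = cz[m],
             stringsAsFactors = FALSE, row.names = NULL)
}

solvation_asp <- function(atoms) {
  tab <- element_params()
  i <- match(atoms$element, tab$element)
  asp <- tab$asp[i]
  chg <- charged_atom_mask(atoms)
  asp[chg] <- tab$asp_charged[i[chg]]
  asp
}

#' Score an assembly with the built-in CrossBetaPotential
#'
#' A documented surrogate energy function preserving the interpreted
#' term structure of full-atom force fields: a plateaued Lennard-Jones
#' attractive term (switched off at `lj_cutoff`), a clamped repulsive
#' term active inside the contact distance, a solvation term (per-atom
#' accessible area times an atomic solvation parameter) and a screened
#' Coulomb term between charged-group centroids. Deterministic given
#' coordinates. Cross terms are split half/half between partner
#' residues so the per-residue attribution sums exactly to the total.
#'
#' @param assembly a `fibril_assembly`
#' @param config a [scan_config()] (backend parameters are read from it)
#' @return an `energy_breakdown`: total, terms, per-residue and
#'   per-chain attributions
#' @export
score_assembly <- function(assembly, config = scan_config()) {
  atoms <- as_atom_table(assembly)
  ei <- energy_inputs(atoms)
  lj <- .pair_energy_kernel(ei$xyz, ei$eps, ei$rmin, ei$res, ei$chain,
                            ei$resno, ei$n_res, config$lj_cutoff,
                            config$lj_switch)
  # solvation
  rad <- atom_radii(atoms$element)
  area <- .sasa_kernel(ei$xyz, rad, config$probe_radius,
                       as.integer(config$solv_n_points))
  asp <- solvation_asp(atoms)
  solv_atom <- asp * area
  res_solv <- as.vector(rowsum(solv_atom,
                               factor(ei$res, levels = 0:(ei$n_res - 1))))
  # screened Coulomb between charged-group centroids
  res_elec <- numeric(ei$n_res)
  elec <- 0
  cs <- charged_sites(atoms)
  if (!is.null(cs) && nrow(cs) >= 2) {
    ckey <- match(paste(cs$chain, cs$resno),
                  paste(ei$res_chain, ei$res_resno))
    for (i in seq_len(nrow(cs) - 1)) {
      for (j in (i + 1):nrow(cs)) {
        r <- sqrt((cs$x[i] - cs$x[j])^2 + (cs$y[i] - cs$y[j])^2 +
                    (cs$z[i] - cs$z[j])^2)
        if (r >= config$elec_cutoff || r < 1e-6) next
        e <- 332 / config$elec_eps * cs$q[i] * cs$q[j] *
          (1 / r - 1 / config$elec_cutoff)
        elec <- elec + e
        res_elec[ckey[i]] <- res_elec[ckey[i]] + e / 2
        res_elec[ckey[j]] <- res_elec[ckey[j]] + e / 2
      }
    }
  }
  per_res <- lj$res_attractive + lj$res_repulsive + res_solv + res_elec
  per_residue <- data.frame(chain = ei$res_chain, resno = ei$res_resno,
                            energy = per_res, stringsAsFactors = FALSE)
  per_chain <- rowsum(per_res, ei$res_chain)
  per_chain <- setNames(as.vector(per_chain), rownames(per_chain))
  terms <- c(attractive = sum(lj$res_attractive),
             repulsive = sum(lj$res_repulsive),
             solvation = sum(res_solv),
             electrostatic = sum(res_elec))
  structure(list(total = sum(per_res), terms = terms,
                 per_residue = per_residue, per_chain = per_chain),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("<energy_breakdown> total %.3f\n", x$total))
  print(round(x$terms, 3))
  invisible(x)
}

#' Truncate a position to alanine in every layer
#'
#' Side chains are truncated to CB at native geometry and the residue is
#' relabelled ALA in every layer. Glycine positions are excluded by
#' default (a classed condition, caught by the scan driver); with
#' `override_glycine = TRUE` a CB is constructed from ideal backbone
#' geometry instead.
#'
#' @param assembly a `fibril_assembly`
#' @param position author residue number
#' @param override_glycine allow glycine -> alanine
#' @return the mutated `fibril_assembly`
#' @export
mutate_to_alanine <- function(assembly, position, override_glycine = FALSE) {
  res <- assembly_residues(assembly)
  i <- match(position, res$resno)
  if (is.na(i))
    stop("position ", position, " is absent from the assembly")
  if (res$resid[i] == "GLY" && !override_glycine)
    stop(errorCondition(
      paste0("position ", position, " is glycine: excluded from ",
             "alanine scanning (override_glycine = TRUE to force)"),
      class = c("fibrilscan_glycine_exclusion", "error")))
  atoms <- assembly$atoms
  at_pos <- atoms$resno == position
  keep <- !at_pos | atoms$elety %in% c(BACKBONE_ATOMS, "CB")
  atoms <- atoms[keep, , drop = FALSE]
  if (res$resid[i] == "GLY") {
    for (ch in assembly$chain_order) {
      res_at <- atoms[atoms$chain == ch & atoms$resno == position, ]
      p <- function(nm) as.numeric(res_at[res_at$elety == nm,
                                          c("x", "y", "z")][1, ])
      cb <- cb_position(p("N"), p("CA"), p("C"))
      atoms <- rbind(atoms, atom_row(ch, position, "ALA", "CB", cb))
    }
  }
  atoms$resid[atoms$resno == position] <- "ALA"
  new_assembly(atoms, chain_order = assembly$chain_order,
               provenance = assembly$provenance, validate = FALSE)
}

## Residues whose chi1 rotation moves atoms (anything with atoms beyond
## CB) lying within the repack neighbourhood of the mutation site.
movable_residues <- function(atoms, position, radius) {
  cb <- atoms[atoms$elety == "CB", , drop = FALSE]
  if (is.null(position)) {
    # global relaxation: every residue with atoms beyond CB
    key <- unique(paste(cb$chain, cb$resno))
    side_n <- vapply(key, function(k) {
      parts <- strsplit(k, " ")[[1]]
      sum(atoms$chain == parts[1] & atoms$resno == as.integer(parts[2]) &
            !atoms$elety %in% c(BACKBONE_ATOMS, "CB"))
    }, numeric(1))
    return(key[side_n > 0])
  }
  site <- cb[cb$resno == position, , drop = FALSE]
  if (nrow(site) == 0) {
    # glycine site: use CA as the neighbourhood centre
    site <- atoms[atoms$elety == "CA" & atoms$resno == position, , drop = FALSE]
  }
  sxyz <- as.matrix(site[, c("x", "y", "z")])
  cxyz <- as.matrix(cb[, c("x", "y", "z")])
  d2 <- outer(rowSums(cxyz^2), rowSums(sxyz^2), "+") - 2 * cxyz %*% t(sxyz)
  near <- apply(d2, 1, min) <= radius^2
  key <- paste(cb$chain, cb$resno)[near]
  # keep residues that actually have side atoms beyond CB
  side_n <- vapply(key, function(k) {
    parts <- strsplit(k, " ")[[1]]
    sum(atoms$chain == parts[1] & atoms$resno == as.integer(parts[2]) &
          !atoms$elety %in% c(BACKBONE_ATOMS, "CB"))
  }, numeric(1))
  key[side_n > 0]
}

#' Restrained side-chain relaxation around a site
#'
#' Perturbs the chi1 angles of all residues whose CB lies within
#' `neighborhood_radius` of the site (Gaussian jitter of
#' `perturb_sigma_chi` degrees, drawn from R's RNG so callers control
#' determinism), then relaxes them by greedy coordinate descent on the
#' pairwise backend energy plus harmonic pair restraints to the input
#' coordinates. The backbone is held fixed. Descent stops when the
#' objective improves by less than one energy unit per sweep.
#'
#' @param assembly a `fibril_assembly`
#' @param config a [scan_config()]
#' @param site author residue number at the centre of the neighbourhood;
#'   `NULL` relaxes every residue (the input-minimisation step)
#' @param perturb apply the chi1 jitter before descending
#' @return the relaxed `fibril_assembly`; `attr(, "relax")` records the
#'   objective before/after and the sweep count
#' @export
relax_assembly <- function(assembly, config, site = NULL, perturb = TRUE) {
  atoms <- assembly$atoms
  mv <- movable_residues(atoms, site, config$neighborhood_radius)
  if (length(mv) == 0) {
    out <- assembly
    attr(out, "relax") <- list(objective_start = NA_real_,
                               objective_end = NA_real_, sweeps = 0L,
                               movable = character(0))
    return(out)
  }
  ei <- energy_inputs(atoms)
  key <- paste(atoms$chain, atoms$resno)
  xyz <- ei$xyz

  side_idx <- lapply(mv, function(k) {
    which(key == k & !atoms$elety %in% c(BACKBONE_ATOMS, "CB")) - 1L
  })
  ca_idx <- vapply(mv, function(k) which(key == k & atoms$elety == "CA")[1],
                   numeric(1)) - 1L
  cb_idx <- vapply(mv, function(k) which(key == k & atoms$elety == "CB")[1],
                   numeric(1)) - 1L

  # chi1 jitter (R RNG; deterministic under the caller's seed)
  if (perturb && config$perturb_sigma_chi > 0) {
    for (m in seq_along(mv)) {
      theta <- rnorm(1, 0, config$perturb_sigma_chi)
      idx <- side_idx[[m]] + 1L
      ax <- unitv(xyz[cb_idx[m] + 1L, ] - xyz[ca_idx[m] + 1L, ])
      R <- rotation_about_axis(ax, theta)
      org <- xyz[cb_idx[m] + 1L, ]
      xyz[idx, ] <- sweep(sweep(xyz[idx, , drop = FALSE], 2, org) %*% t(R),
                          2, org, "+")
    }
  }

  # harmonic restraints to the *input* coordinates: pairs within the
  # cutoff that involve at least one movable side atom
  mv_atoms <- sort(unique(unlist(side_idx))) + 1L
  axyz <- as.matrix(assembly$atoms[, c("x", "y", "z")])
  d2 <- outer(rowSums(axyz[mv_atoms, , drop = FALSE]^2), rowSums(axyz^2), "+") -
    2 * axyz[mv_atoms, , drop = FALSE] %*% t(axyz)
  d2[d2 < 0] <- 0
  restr <- which(d2 <= config$restraint_pair_cutoff^2, arr.ind = TRUE)
  ri <- mv_atoms[restr[, 1]]
  rj <- restr[, 2]
  keepp <- ri != rj & key[ri] != key[rj]
  # deduplicate unordered pairs
  pk <- paste(pmin(ri, rj), pmax(ri, rj))
  dd <- !duplicated(pk) & keepp
  ri <- ri[dd]; rj <- rj[dd]
  d0 <- sqrt(d2[cbind(restr[dd, 1], rj)])
  restr_of <- lapply(side_idx, function(s)
    which(ri %in% (s + 1L) | rj %in% (s + 1L)) - 1L)

  movable <- lapply(seq_along(mv), function(m)
    list(side = as.integer(side_idx[[m]]), ca = as.integer(ca_idx[m]),
         cb = as.integer(cb_idx[m]), restr = as.integer(restr_of[[m]])))

  obj <- function(xx) {
    lj <- .pair_energy_kernel(xx, ei$eps, ei$rmin, ei$res, ei$chain, ei$resno,
                              ei$n_res, config$lj_cutoff, config$lj_switch)
    dd <- sqrt(rowSums((xx[ri, , drop = FALSE] - xx[rj, , drop = FALSE])^2))
    lj$attractive + lj$repulsive +
      config$restraint_weight * sum((dd - d0)^2)
  }
  start_obj <- obj(xyz)
  cand <- c(-180, -135, -90, -45, -20, -10, -5, -2, 2, 5, 10, 20, 45, 90, 135)
  out <- .relax_chi_kernel(xyz, ei$eps, ei$rmin, ei$res, ei$chain, ei$resno,
                           movable, cand,
                           as.integer(ri - 1L), as.integer(rj - 1L), d0,
                           config$restraint_weight, config$lj_cutoff,
                           config$lj_switch, 1.0, config$max_sweeps)
  if (out$sweeps >= config$max_sweeps)
    warning("relaxation hit the sweep cap before converging; ",
            "returning best-so-far coordinates", call. = FALSE)
  res <- assembly
  res$atoms[, c("x", "y", "z")] <- out$xyz
  attr(res, "relax") <- list(objective_start = start_obj,
                             objective_end = obj(out$xyz),
                             sweeps = out$sweeps, movable = mv)
  res
}

derive_seed <- function(seed, ...) {
  h <- as.double(seed %% 2147483647)
  for (v in c(...)) h <- (h * 69069 + as.double(v) + 1) %% 2147483647
  as.integer(h)
}

unbound_coords <- function(assembly) {
  n <- n_layers(assembly)
  mid <- (n + 1) %/% 2
  trimer <- assembly$chain_order[(mid - 1):(mid + 1)]
  atoms <- assembly$atoms
  sel <- atoms$chain %in% trimer
  atoms$x[sel] <- atoms$x[sel] + 500
  atoms
}

scan_one_replicate <- function(wt, position, config, rep_seed) {
  set.seed(rep_seed)
  base <- relax_assembly(wt, config, site = position, perturb = TRUE)
  branch_seed <- derive_seed(rep_seed, 1)

  set.seed(branch_seed)
  mut <- mutate_to_alanine(base, position,
                           override_glycine = !config$exclude_glycine)
  mut <- relax_assembly(mut, config, site = position, perturb = TRUE)

  set.seed(branch_seed)
  wtb <- relax_assembly(base, config, site = position, perturb = TRUE)

  sm <- score_assembly(mut, config)
  sw <- score_assembly(wtb, config)

  chains <- wt$chain_order
  pc_m <- sm$per_chain[chains]
  pc_w <- sw$per_chain[chains]

  rec <- list(bound_mut = sm$total, bound_wt = sw$total,
              delta_reu = sm$total - sw$total,
              per_chain_delta = pc_m - pc_w,
              d_terms = sm$terms - sw$terms,
              dg_mut = NA_real_, dg_wt = NA_real_,
              ddg_interface = NA_real_)
  if (config$compute_ddg && n_layers(wt) >= 5) {
    um <- score_assembly(unbound_coords(mut), config)
    uw <- score_assembly(unbound_coords(wtb), config)
    rec$dg_mut <- sm$total - um$total
    rec$dg_wt <- sw$total - uw$total
    rec$ddg_interface <- rec$dg_mut - rec$dg_wt
  }
  rec
}

#' Per-replicate assembly energy change for one alanine mutation
#'
#' For each replicate (seeded from `rng_seed`, the position and the
#' replicate index) a perturbed copy of the input is relaxed, then
#' branched into a mutant (mutate, repack the neighbourhood, relax) and
#' a wild-type (repack, relax) model; both bound states are scored and
#' the difference `bound_mut - bound_wt` is returned, together with the
#' per-layer attribution and (when the stack has >= 5 layers) the
#' central-trimer interface ddG computed from the rigidly separated
#' unbound state.
#'
#' @param wt the wild-type `fibril_assembly`
#' @param position author residue number
#' @param config a [scan_config()]
#' @return list with `replicates` (data.frame, one row per replicate),
#'   `per_chain_delta` (replicates x layers matrix) and `mean_delta_reu`
#' @export
delta_reu_assembly <- function(wt, position, config = scan_config()) {
  recs <- lapply(seq_len(config$n_replicates), function(r) {
    scan_one_replicate(wt, position, config,
                       derive_seed(config$rng_seed, position, r))
  })
  df <- do.call(rbind, lapply(seq_along(recs), function(r) {
    x <- recs[[r]]
    data.frame(replicate = r, bound_mut = x$bound_mut, bound_wt = x$bound_wt,
               delta_reu = x$delta_reu, dg_mut = x$dg_mut, dg_wt = x$dg_wt,
               ddg_interface = x$ddg_interface,
               d_attractive = x$d_terms[["attractive"]],
               d_repulsive = x$d_terms[["repulsive"]],
               d_solvation = x$d_terms[["solvation"]],
               d_electrostatic = x$d_terms[["electrostatic"]])
  }))
  pc <- do.call(rbind, lapply(recs, function(x) x$per_chain_delta))
  rownames(pc) <- NULL
  list(replicates = df, per_chain_delta = pc,
       mean_delta_reu = mean(df$delta_reu))
}

#' Central-trimer interface ddG for one alanine mutation
#'
#' The unbound state separates the central three layers rigidly from
#' the rest of the stack (500 A, beyond every interaction cutoff) and
#' rescores without further optimisation;
#' `ddG = [bound - unbound]_mut - [bound - unbound]_wt` per replicate.
#'
#' @inheritParams delta_reu_assembly
#' @return data.frame with dg_mut, dg_wt and ddg_interface per replicate
#' @export
ddg_interface <- function(wt, position, config = scan_config()) {
  if (n_layers(wt) < 5)
    stop("interface ddG needs >= 5 layers (a central trimer plus partners)")
  config$compute_ddg <- TRUE
  out <- delta_reu_assembly(wt, position, config)
  out$replicates[, c("replicate", "dg_mut", "dg_wt", "ddg_interface")]
}

#' Run the full alanine scan
#'
#' Iterates [delta_reu_assembly()] over every position of the layer
#' sequence. Glycine positions are excluded (with reason) when
#' `exclude_glycine` is set; per-position failures are collected
#' without aborting the scan. Deterministic given `rng_seed`.
#'
#' @param assembly a `fibril_assembly` built to the desired layer count
#' @param config a [scan_config()]
#' @param structure_id identifier stored with the result
#' @param minimize_input relax the whole input structure (restrained,
#'   unperturbed) before scanning, as the protocol's first step
#' @return a `scan_result`
#' @export
run_alanine_scan <- function(assembly, config = scan_config(),
                             structure_id = "structure",
                             minimize_input = TRUE) {
  if (minimize_input)
    assembly <- relax_assembly(assembly, config, site = NULL, perturb = FALSE)
  res <- assembly_residues(assembly)
  rows <- list()
  pcs <- list()
  excluded <- data.frame(position = integer(0), reason = character(0))
  for (i in seq_len(nrow(res))) {
    pos <- res$resno[i]
    if (res$resid[i] == "GLY" && config$exclude_glycine) {
      excluded <- rbind(excluded,
                        data.frame(position = pos, reason = "glycine"))
      next
    }
    out <- tryCatch(delta_reu_assembly(assembly, pos, config),
                    error = function(e) e)
    if (inherits(out, "error")) {
      excluded <- rbind(excluded,
                        data.frame(position = pos,
                                   reason = conditionMessage(out)))
      next
    }
    df <- out$replicates
    df <- cbind(data.frame(position = pos, aa = res$aa[i]), df)
    rows[[length(rows) + 1]] <- df
    pcs[[length(pcs) + 1]] <- out$per_chain_delta
  }
  replicates <- do.call(rbind, rows)
  rownames(replicates) <- NULL
  per_chain <- do.call(rbind, pcs)
  structure(list(structure_id = structure_id, config = config,
                 replicates = replicates, per_chain_delta = per_chain,
                 excluded = excluded, n_layers = n_layers(assembly)),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  np <- length(unique(x$replicates$position))
  nr <- if (np) max(x$replicates$replicate) else 0
  cat(sprintf("<scan_result> %s: %d positions x %d replicates",
              x$structure_id, np, nr))
  if (nrow(x$excluded))
    cat(sprintf(" (%d excluded)", nrow(x$excluded)))
  cat("\n")
  invisible(x)
}

#' Per-position replicate means of a scan
#'
#' @param object a `scan_result`
#' @param ... unused
#' @return data.frame position, aa, mean_delta_reu, sd_delta_reu,
#'   mean_ddg_interface, n_replicates
#' @export
summary.scan_result <- function(object, ...) {
  df <- object$replicates
  if (is.null(df) || nrow(df) == 0)
    return(data.frame(position = integer(0)))
  sp <- split(df, df$position)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(position = d$position[1],
               aa = if ("aa" %in% names(d)) d$aa[1] else NA,
               mean_delta_reu = mean(d$delta_reu),
               sd_delta_reu = if (nrow(d) > 1) sd(d$delta_reu) else 0,
               mean_ddg_interface = if (is.numeric(d$ddg_interface))
                 mean(d$ddg_interface) else NA_real_,
               n_replicates = nrow(d))
  }))
  out <- out[order(out$position), ]
  rownames(out) <- NULL
  out
}

#' Edge/internal layer decomposition of the scan energetics
#'
#' Partitions the stored per-layer attribution of every replicate's
#' energy change into the two terminal (edge) layers and the interior
#' layers; by the half-split cross-term convention
#' `edge + internal = assembly` holds exactly.
#'
#' @param scan a `scan_result` produced by [run_alanine_scan()]
#' @return data.frame with per-replicate delta_edge / delta_internal and
#'   the per-position means in `attr(, "means")`
#' @export
layer_decomposition <- function(scan) {
  stopifnot(inherits(scan, "scan_result"))
  if (is.null(scan$per_chain_delta))
    stop("this scan_result carries no per-layer attribution ",
         "(external score tables are ingested without one)")
  pc <- scan$per_chain_delta
  n <- ncol(pc)
  edge <- pc[, 1] + pc[, n]
  internal <- rowSums(pc[, -c(1, n), drop = FALSE])
  out <- data.frame(position = scan$replicates$position,
                    replicate = scan$replicates$replicate,
                    delta_edge = edge, delta_internal = internal,
                    delta_assembly = rowSums(pc))
  means <- do.call(rbind, lapply(split(out, out$position), function(d)
    data.frame(position = d$position[1],
               mean_edge = mean(d$delta_edge),
               mean_internal = mean(d$delta_internal),
               mean_assembly = mean(d$delta_assembly))))
  rownames(means) <- NULL
  attr(out, "means") <- means
  out
}

#' Ingest an external per-residue, per-replicate score table
#'
#' Reads tables in the schema `structure_id, residue, replicate,
#' bound_mut, bound_wt` (tab-separated when a path is given) as
#' produced by external energy engines, and builds `scan_result`
#' objects with `delta_reu = bound_mut - bound_wt` per row.
#'
#' @param x path to a TSV file or a data.frame
#' @return a `scan_result` (or a named list of them when the table
#'   holds several structures)
#' @export
ingest_external_scores <- function(x) {
  df <- if (is.character(x)) {
    if (!file.exists(x)) stop("file not found: ", x)
    read.delim(x, stringsAsFactors = FALSE)
  } else as.data.frame(x)
  need <- c("structure_id", "residue", "replicate", "bound_mut", "bound_wt")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("residue", "replicate", "bound_mut", "bound_wt")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("non-numeric value in column '", col, "' at row ", bad[1])
    if (anyNA(v)) stop("missing value in column '", col, "' at row ",
                       which(is.na(v))[1])
    df[[col]] <- v
  }
  build_one <- function(d) {
    dk <- paste(d$residue, d$replicate)
    if (anyDuplicated(dk)) {
      row <- which(duplicated(dk))[1]
      stop("duplicate (residue, replicate) key at row ", row,
           " of structure ", d$structure_id[1])
    }
    reps <- data.frame(position = as.integer(d$residue),
                       aa = if ("aa" %in% names(d)) d$aa else NA,
                       replicate = as.integer(d$replicate),
                       bound_mut = d$bound_mut, bound_wt = d$bound_wt,
                       delta_reu = d$bound_mut - d$bound_wt)
    reps <- reps[order(reps$position, reps$replicate), ]
    rownames(reps) <- NULL
    structure(list(structure_id = d$structure_id[1],
                   config = list(source = "external"),
                   replicates = reps, per_chain_delta = NULL,
                   excluded = data.frame(position = integer(0),
                                         reason = character(0)),
                   n_layers = NA_integer_),
              class = "scan_result")
  }
  ids <- unique(df$structure_id)
  if (length(ids) == 1) return(build_one(df))
  setNames(lapply(ids, function(id) build_one(df[df$structure_id == id, ])),
           ids)
}

#' Persist a scan result as TSV (plus a JSON config sidecar)
#'
#' @param scan a `scan_result`
#' @param path output TSV; `<path>.json` receives the config
#' @export
write_scan_result <- function(scan, path) {
  df <- scan$replicates
  out <- data.frame(structure_id = scan$structure_id,
                    residue = df$position, replicate = df$replicate,
                    bound_mut = df$bound_mut, bound_wt = df$bound_wt)
  extra <- intersect(c("aa", "ddg_interface", "d_attractive", "d_repulsive",
                       "d_solvation", "d_electrostatic"), names(df))
  out <- cbind(out, df[, extra, drop = FALSE])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- scan$config
  cfg$excluded <- scan$excluded
  jsonlite::write_json(cfg, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}
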