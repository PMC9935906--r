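# Idealised-geometry builders. Bond lengths/angles are standard peptide
# values; side chains use the simplified zigzag templates from
# aa-tables.R (chi1 = N-CA-CB-X1 is the single free side-chain dihedral,
# subsequent pseudo-dihedrals are held trans).

BOND <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
             ca_cb = 1.53, sc = 1.52)
ANGLE <- list(n_ca_c = 111.0, ca_c_n = 116.6, c_n_ca = 121.7,
              ca_c_o = 120.5, sc = 114.0)

sidechain_rows <- function(aa3, resno, chain, N, CA, CB, chi1 = 180) {
  tmpl <- SIDECHAIN_TEMPLATES[[aa3]]
  if (length(tmpl) == 0) return(NULL)       # GLY (none) / ALA (CB only)
  placed <- list(N = N, CA = CA, CB = CB)
  rows <- vector("list", length(tmpl))
  for (k in seq_along(tmpl)) {
    tm <- tmpl[[k]]
    dih <- tm$dih + if (tm$chi) chi1 else 0
    pos <- place_atom(placed[[tm$refs[1]]], placed[[tm$refs[2]]],
                      placed[[tm$refs[3]]], tm$bond, tm$angle, dih)
    placed[[tm$atom]] <- pos
    rows[[k]] <- data.frame(chain = chain, resno = resno, ins = "",
                            resid = aa3, elety = tm$atom,
                            element = element_from_name(tm$atom),
                            x = pos[1], y = pos[2], z = pos[3],
                            o = 1, b = 0, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

cb_position <- function(N, CA, C) {
  b1 <- unitv(CA - N); b2 <- unitv(CA - C)
  bis <- unitv(b1 + b2); perp <- unitv(vcross(b2, b1))
  CA + BOND$ca_cb * (cos(0.9557) * bis + sin(0.9557) * perp)
}

atom_row <- function(chain, resno, aa3, elety, pos) {
  data.frame(chain = chain, resno = resno, ins = "", resid = aa3,
             elety = elety, element = element_from_name(elety),
             x = pos[1], y = pos[2], z = pos[3], o = 1, b = 0,
             stringsAsFactors = FALSE)
}

#' Build a single peptide chain at fixed backbone torsions
#'
#' Constructs an idealised chain with the given phi/psi (and trans
#' omega), CB at ideal geometry and simplified extended side chains.
#'
#' @param sequence one-letter amino-acid string
#' @param numbering_start author number of the first residue
#' @param phi,psi,omega backbone torsions in degrees (recycled)
#' @param chain chain identifier
#' @return a one-layer `fibril_assembly`
#' @export
build_peptide <- function(sequence, numbering_start = 1,
                          phi = -120, psi = 120, omega = 180, chain = "A") {
  seq1 <- strsplit(toupper(sequence), "")[[1]]
  aa3 <- aa_three(seq1)
  n <- length(seq1)
  if (n < 1) stop("empty sequence")
  phi <- rep_len(phi, n); psi <- rep_len(psi, n); omega <- rep_len(omega, n)
  resno <- numbering_start + seq_len(n) - 1
  N <- CA <- C <- O <- matrix(0, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BOND$n_ca, 0, 0)
  ang <- ANGLE$n_ca_c * DEG
  C[1, ] <- CA[1, ] + BOND$ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           BOND$c_n, ANGLE$ca_c_n, psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            BOND$n_ca, ANGLE$c_n_ca, omega[i])
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                           BOND$ca_c, ANGLE$n_ca_c, phi[i])
    }
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         BOND$c_o, ANGLE$ca_c_o, psi[i] + 180)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    res <- rbind(atom_row(chain, resno[i], aa3[i], "N", N[i, ]),
                 atom_row(chain, resno[i], aa3[i], "CA", CA[i, ]),
                 atom_row(chain, resno[i], aa3[i], "C", C[i, ]),
                 atom_row(chain, resno[i], aa3[i], "O", O[i, ]))
    if (aa3[i] != "GLY") {
      cb <- cb_position(N[i, ], CA[i, ], C[i, ])
      res <- rbind(res, atom_row(chain, resno[i], aa3[i], "CB", cb))
      sc <- sidechain_rows(aa3[i], resno[i], chain, N[i, ], CA[i, ], cb)
      if (!is.null(sc)) res <- rbind(res, sc)
    }
    rows[[i]] <- res
  }
  new_assembly(do.call(rbind, rows), chain_order = chain,
               provenance = list(source = "build_peptide", log = character()))
}
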