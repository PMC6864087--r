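# Panel-B physicochemical descriptors from open, published contribution
# schemes. Each contribution table is embedded with its literature source;
# atoms without a table entry fall back to an element default with a warning.

# ---- atom environment helpers ----------------------------------------------

# Per-atom context used by the typing rules.
.atom_env <- function(mol) {
  atoms <- mol$atoms
  bonds <- mol$bonds
  n <- nrow(atoms)
  inc <- .incident_bonds(mol)
  nbrs <- .neighbors(mol)
  env <- vector("list", n)
  for (i in seq_len(n)) {
    ks <- inc[[i]]
    js <- nbrs[[i]]
    ords <- bonds$order[ks]
    env[[i]] <- list(
      el = atoms$element[i],
      arom = atoms$aromatic[i],
      charge = atoms$charge[i],
      h = atoms$hcount[i],
      nbr_el = atoms$element[js],
      nbr_arom = atoms$aromatic[js],
      nbr_idx = js,
      bond_order = ords,
      n_single = sum(ords == 1),
      n_double = sum(ords == 2),
      n_triple = sum(ords == 3),
      n_arom = sum(ords == 1.5),
      in_ring = atoms$in_ring[i],
      in_3ring = FALSE
    )
  }
  # triangle membership (needed for the 3-ring entries of the TPSA table)
  for (i in seq_len(n)) {
    js <- nbrs[[i]]
    if (length(js) < 2L) next
    for (a in seq_along(js)) {
      for (b in seq_len(length(js) - a)) {
        if (js[a + b] %in% nbrs[[js[a]]]) {
          env[[i]]$in_3ring <- TRUE
          break
        }
      }
      if (env[[i]]$in_3ring) break
    }
  }
  env
}

.het_set <- c("N", "O", "P", "S", "F", "Cl", "Br", "I")

# ---- TPSA -------------------------------------------------------------------

#' Topological polar surface area
#'
#' Sum of the published topological N/O fragment contributions (Ertl,
#' Rohde & Selzer, J. Med. Chem. 43 (2000) 3714-3717, Table 1) over the
#' parent fragment. Counterions are stripped first; formal charge on the
#' parent (e.g. a quaternary ammonium) is preserved and typed as the ion.
#'
#' @param mol A `molgraph` or SMILES string.
#' @return TPSA in square Angstroms.
#' @examples
#' compute_tpsa("OCCNCCO")  # diethanolamine: 12.03 + 2 * 20.23 = 52.49
#' @export
compute_tpsa <- function(mol) {
  mol <- .as_molgraph(mol)
  mol <- parent_fragment(mol)
  env <- .atom_env(mol)
  total <- 0
  for (e in env) {
    if (!e$el %in% c("N", "O")) next
    total <- total + .tpsa_contrib(e)
  }
  round(total, 2)
}

# One atom's Ertl fragment contribution. Values in Angstrom^2; each row cites
# the fragment as written in the published table.
.tpsa_contrib <- function(e) {
  h <- e$h; ch <- e$charge
  ns <- e$n_single; nd <- e$n_double; nt <- e$n_triple; na <- e$n_arom
  if (e$el == "N") {
    if (e$arom) {
      if (ch == 0) {
        if (h == 0 && na == 3 && ns == 0 && nd == 0) return(4.41)   # [n](:*)(:*):*
        if (h == 0 && na == 2 && ns == 1)            return(4.93)   # [n](-*)(:*):*
        if (h == 0 && na == 2 && nd == 1)            return(8.39)   # [n](=*)(:*):*
        if (h == 0 && na == 2)                       return(12.89)  # [n](:*):*
        if (h == 1 && na == 2)                       return(15.79)  # [nH](:*):*
      } else if (ch == 1) {
        if (h == 0 && na == 3)                       return(4.10)   # [n+](:*)(:*):*
        if (h == 0 && na == 2 && ns == 1)            return(3.88)   # [n+](-*)(:*):*
        if (h == 1 && na == 2)                       return(14.14)  # [nH+](:*):*
      }
    } else {
      if (ch == 0) {
        if (h == 0 && ns == 3 && nd == 0 && e$in_3ring) return(3.01) # [N]1(-*)-*-*-1
        if (h == 0 && ns == 3 && nd == 0)            return(3.24)   # [N](-*)(-*)-*
        if (h == 0 && ns == 1 && nd == 1)            return(12.36)  # [N](-*)=*
        if (h == 0 && nt == 1 && ns == 0)            return(23.79)  # [N]#*
        if (h == 0 && ns == 1 && nd == 2)            return(11.68)  # [N](-*)(=*)=*
        if (h == 0 && nd == 1 && nt == 1)            return(13.60)  # [N](=*)#*
        if (h == 1 && ns == 2 && e$in_3ring)         return(21.94)  # [NH]1-*-*-1
        if (h == 1 && ns == 2)                       return(12.03)  # [NH](-*)-*
        if (h == 1 && nd == 1)                       return(23.85)  # [NH]=*
        if (h == 2 && ns == 1)                       return(26.02)  # [NH2]-*
      } else if (ch == 1) {
        if (h == 0 && ns == 4)                       return(0.00)   # [N+](-*)(-*)(-*)-*
        if (h == 0 && ns == 2 && nd == 1)            return(3.01)   # [N+](-*)(-*)=*
        if (h == 0 && ns == 1 && nt == 1)            return(4.36)   # [N+](-*)#*
        if (h == 1 && ns == 3)                       return(4.44)   # [NH+](-*)(-*)-*
        if (h == 1 && ns == 1 && nd == 1)            return(13.97)  # [NH+](-*)=*
        if (h == 2 && ns == 2)                       return(16.61)  # [NH2+](-*)-*
        if (h == 2 && nd == 1)                       return(25.59)  # [NH2+]=*
        if (h == 3 && ns == 1)                       return(27.64)  # [NH3+]-*
      }
    }
  } else if (e$el == "O") {
    if (e$arom) {
      if (na == 2)                                   return(13.14)  # [o](:*):*
    } else {
      if (ch == 0) {
        if (h == 0 && ns == 2 && e$in_3ring)         return(12.53)  # [O]1-*-*-1
        if (h == 0 && ns == 2)                       return(9.23)   # [O](-*)-*
        if (h == 0 && nd == 1)                       return(17.07)  # [O]=*
        if (h == 1 && ns == 1)                       return(20.23)  # [OH]-*
      } else if (ch == -1) {
        if (ns == 1)                                 return(23.06)  # [O-]-*
      }
    }
  }
  warning("no TPSA fragment entry for an ", e$el,
          " environment; contributing 0", call. = FALSE)
  0
}

# ---- Wildman-Crippen ClogP --------------------------------------------------

# Published atom-contribution values (Wildman & Crippen, J. Chem. Inf.
# Comput. Sci. 39 (1999) 868-873, Table 1).
.wc_values <- c(
  C1 = 0.1441, C2 = 0, C3 = -0.2035, C4 = -0.2051, C5 = -0.2783,
  C6 = 0.1551, C7 = 0.0017, C8 = 0.08452, C9 = -0.1444, C10 = -0.0516,
  C11 = 0.1193, C12 = -0.0967, C13 = -0.5443, C14 = 0, C15 = 0.245,
  C16 = 0.198, C17 = 0, C18 = 0.1581, C19 = 0.2955, C20 = 0.2713,
  C21 = 0.1360, C22 = 0.4619, C23 = 0.5437, C24 = 0.1893, C25 = -0.8186,
  C26 = 0.264, C27 = 0.2148, CS = 0.08129,
  H1 = 0.1230, H2 = -0.2677, H3 = 0.2142, H4 = 0.298, HS = 0.1125,
  N1 = -1.019, N2 = -0.7096, N3 = -1.027, N4 = -0.5188, N5 = 0.08387,
  N6 = 0.1836, N7 = -0.3187, N8 = -0.4458, N9 = 0.01508, N10 = -1.950,
  N11 = -0.3239, N12 = -1.119, N13 = -0.3396, N14 = 0.2887, NS = -0.4806,
  O1 = 0.1552, O2 = -0.2893, O3 = -0.0684, O4 = -0.4195, O5 = 0.0335,
  O6 = -0.3339, O7 = -1.189, O8 = 0.1788, O9 = -0.1526, O10 = 0.1129,
  O11 = 0.4833, O12 = -1.326, OS = -0.1188,
  F = 0.4202, Cl = 0.6895, Br = 0.8456, I = 0.8857, Hal = -2.996,
  P = 0.8612, S1 = 0.6482, S2 = -0.0024, S3 = 0.6237, Me1 = -0.3808
)

# Type one heavy atom. Rules mirror the published SMARTS patterns in their
# table order (first match wins); uppercase element symbols in the patterns
# mean aliphatic, so aromatic neighbors do not satisfy them.
.wc_type <- function(e) {
  el <- e$el
  aliph_het <- any(!e$nbr_arom & e$nbr_el %in% .het_set)
  arom_nbr <- any(e$nbr_arom)
  if (el == "C") {
    if (e$arom) {
      hal <- e$nbr_el[!e$nbr_arom & e$nbr_el %in% c("F", "Cl", "Br", "I")]
      if (length(hal) > 0L)
        return(switch(hal[1], F = "C14", Cl = "C15", Br = "C16", I = "C17"))
      if (e$h >= 1) return("C18")
      single_nbr_el <- e$nbr_el[e$bond_order == 1]
      single_nbr_arom <- e$nbr_arom[e$bond_order == 1]
      double_nbr_el <- e$nbr_el[e$bond_order == 2]
      if (e$n_arom == 3) return("C19")
      if (any(single_nbr_arom)) return("C20")
      if (length(double_nbr_el) > 0L &&
          double_nbr_el[1] %in% c("C", "N", "O")) return("C25")
      if (any(single_nbr_el == "C" & !single_nbr_arom)) return("C21")
      if (any(single_nbr_el == "N" & !single_nbr_arom)) return("C22")
      if (any(single_nbr_el == "O" & !single_nbr_arom)) return("C23")
      if (any(single_nbr_el == "S" & !single_nbr_arom)) return("C24")
      return("CS")
    }
    sp3 <- e$n_double == 0 && e$n_triple == 0 && e$n_arom == 0
    if (sp3) {
      others_aliph <- all(!e$nbr_arom)
      only_c <- all(e$nbr_el == "C" & !e$nbr_arom)
      if (only_c || length(e$nbr_el) == 0L) {
        if (e$h >= 2) return("C1")
        return("C2")
      }
      if (aliph_het) {
        if (e$h == 3) return("C3")
        if (e$h == 2 && others_aliph) return("C3")
        if (e$h <= 1 && others_aliph) return("C4")
      }
      if (arom_nbr) {
        arom_c <- any(e$nbr_arom & e$nbr_el == "C")
        if (e$h == 3) return(if (arom_c) "C8" else "C9")
        if (e$h == 2) return("C10")
        if (e$h == 1) return("C11")
        return("C12")
      }
      return("C27")
    }
    if (e$n_double > 0) {
      dbl <- which(e$bond_order == 2)
      del <- e$nbr_el[dbl]; darom <- e$nbr_arom[dbl]
      if (any(del != "C" & !darom)) return("C5")
      if (any(del == "C" & !darom)) {
        if (arom_nbr) return("C26")
        return("C6")
      }
      if (any(darom)) return("C26")
    }
    if (e$n_triple > 0) return("C7")
    return("CS")
  }
  if (el == "N") {
    if (e$arom) {
      if (e$charge > 0) return("N12")
      return("N11")
    }
    if (e$charge > 0) {
      if (e$h >= 1) return("N10")
      return("N13")
    }
    if (e$charge < 0) return("N14")
    if (e$h == 2) return(if (arom_nbr) "N3" else "N1")
    if (e$h == 1) {
      if (e$n_double == 1) return("N5")
      if (arom_nbr) return("N4")
      return("N2")
    }
    if (e$n_triple == 1) return("N9")
    if (e$n_double >= 1) return("N6")
    if (arom_nbr) return("N8")
    if (e$n_single == 3) return("N7")
    return("NS")
  }
  if (el == "O") {
    if (e$arom) return("O1")
    if (e$charge < 0) {
      # carboxylate before the generic anion, as in the published order
      js <- which(e$bond_order == 1)
      if (length(js) == 1L && e$nbr_el[js] == "C") return("O12")
      return("O7")
    }
    if (e$h >= 1) return("O2")
    if (e$n_double == 1) {
      j <- which(e$bond_order == 2)
      partner_el <- e$nbr_el[j]; partner_arom <- e$nbr_arom[j]
      if (partner_el %in% c("N", "O")) return("O5")
      if (partner_el == "S") return("O6")
      if (partner_arom) return("O8")
      # dispatch on the carbonyl carbon's other neighbors
      return(attr(e, "carbonyl_type") %||% "O9")
    }
    if (e$n_single == 2) {
      if (arom_nbr) return("O4")
      return("O3")
    }
    return("OS")
  }
  if (el %in% c("F", "Cl", "Br", "I")) {
    if (e$charge < 0) return("Hal")
    return(el)
  }
  if (el == "P") return("P")
  if (el == "S") {
    if (e$arom) return("S3")
    if (e$charge != 0 || any(e$nbr_el[e$bond_order == 2] %in%
                             c("N", "O", "P", "S"))) return("S2")
    return("S1")
  }
  "Me1"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Distinguish O9/O10/O11 for a carbonyl oxygen from the carbon's substituents.
.carbonyl_o_type <- function(e, env) {
  j <- e$nbr_idx[which(e$bond_order == 2)]
  ce <- env[[j]]
  keep <- ce$nbr_el != "O" | ce$bond_order != 2  # drop the =O bond itself
  oth_el <- ce$nbr_el[keep]; oth_arom <- ce$nbr_arom[keep]
  if (ce$h >= 1) {
    if (any(oth_arom)) return("O10")
    return("O9")  # aldehyde forms [O]=[CH]C, [O]=[CH][N,O], [O]=[CH2]
  }
  # [O]=C(C)([A;!#1]): one aliphatic C plus a second aliphatic heavy atom
  if (any(oth_el == "C" & !oth_arom) && sum(!oth_arom) >= 2) return("O9")
  if (any(oth_arom)) return("O10")               # [O]=C([C,c])[a], [O]=C(c)[A]
  if (length(oth_el) >= 2 && all(oth_el != "C")) return("O11")  # =C([!#6])[!#6]
  "OS"
}

#' Crippen-style calculated logP
#'
#' Sum of the published Wildman-Crippen atom contributions over the parent
#' fragment (heavy atoms plus their attached hydrogens). Atom typing follows
#' the published environment patterns; an atom matching no pattern falls back
#' to its element-default contribution with a warning.
#'
#' @param mol A `molgraph` or SMILES string.
#' @param detail If `TRUE`, also return the per-atom type assignment.
#' @return Estimated log10 octanol/water partition coefficient, or a list
#'   when `detail = TRUE`.
#' @examples
#' compute_clogp("C")         # methane: 0.1441 + 4 * 0.1230 = 0.6361
#' compute_clogp("c1ccccc1")  # benzene: 6 * (0.1581 + 0.1230) = 1.6866
#' @export
compute_clogp <- function(mol, detail = FALSE) {
  mol <- .as_molgraph(mol)
  mol <- parent_fragment(mol)
  env <- .atom_env(mol)
  types <- character(length(env))
  total <- 0
  for (i in seq_along(env)) {
    e <- env[[i]]
    ty <- if (e$el == "O" && e$n_double == 1 && e$charge == 0 && e$h == 0 &&
              !e$arom && e$nbr_el[which(e$bond_order == 2)] == "C" &&
              !e$nbr_arom[which(e$bond_order == 2)]) {
      .carbonyl_o_type(e, env)
    } else {
      .wc_type(e)
    }
    types[i] <- ty
    total <- total + .wc_values[[ty]]
    # attached hydrogens
    if (e$h > 0) {
      htype <- .wc_h_type(e, env)
      types[i] <- paste0(types[i], "+", e$h, htype)
      total <- total + e$h * .wc_values[[htype]]
    }
  }
  if (detail) return(list(clogp = total, types = types))
  total
}

# Hydrogen typing from the heavy atom it sits on.
.wc_h_type <- function(e, env) {
  if (e$el == "C") return("H1")
  if (e$el == "N") return("H3")
  if (e$el == "O") {
    js <- e$nbr_idx[e$bond_order == 1]
    if (length(js) == 0L) return("H2")  # water
    pe <- env[[js[1]]]
    if (pe$el == "N") return("H3")                      # [#1]O[#7]
    if (pe$el %in% c("O", "S")) return("H4")            # [#1]O[O,S]
    if (pe$el == "C" && pe$n_double >= 1) {
      dbl_el <- pe$nbr_el[pe$bond_order == 2]
      if (any(dbl_el %in% c("C", "N", "O", "S"))) return("H4")  # acid OH
    }
    return("H2")
  }
  "HS"
}

# ---- molecular weight -------------------------------------------------------

.atomic_weights <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.99, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45,
  K = 39.098, Ca = 40.078, Br = 79.904, I = 126.904
)

#' Molecular weight of the parent fragment
#'
#' @param mol A `molgraph` or SMILES string.
#' @return Weight in g/mol (heavy atoms + implicit hydrogens).
#' @export
compute_mw <- function(mol) {
  mol <- .as_molgraph(mol)
  mol <- parent_fragment(mol)
  w <- .atomic_weights[mol$atoms$element]
  if (anyNA(w)) {
    warning("element(s) without a weight entry: ",
            paste(unique(mol$atoms$element[is.na(w)]), collapse = ", "),
            call. = FALSE)
    w[is.na(w)] <- 0
  }
  sum(w) + sum(mol$atoms$hcount) * .atomic_weights[["H"]]
}

# ---- polarizability ---------------------------------------------------------

# Atomic hybrid polarizability components (Miller, J. Am. Chem. Soc. 112
# (1990) 8533-8542, Table III), in Angstrom^3.
.miller_ahc <- list(
  H = c(any = 0.387),
  C = c(sp3 = 1.061, sp2 = 1.352, sp = 1.283),
  N = c(sp3 = 0.964, sp2 = 1.030, sp = 0.956),
  O = c(sp3 = 0.637, sp2 = 0.569),
  F = c(any = 0.296), Cl = c(any = 2.315), Br = c(any = 3.013),
  I = c(any = 5.415),
  S = c(sp3 = 3.000, sp2 = 3.729),
  P = c(any = 1.538)
)

.hybridization <- function(e) {
  if (e$n_triple > 0 || e$n_double >= 2) return("sp")
  if (e$n_double == 1 || e$arom) return("sp2")
  "sp3"
}

#' Additive molecular polarizability
#'
#' Sum of atomic hybrid polarizability components over the parent fragment
#' (heavy atoms by hybridization, plus attached hydrogens). The scheme is
#' strictly additive, so substituent swaps change the value by exactly the
#' difference of the atomic components.
#'
#' @param mol A `molgraph` or SMILES string.
#' @return Polarizability in cubic Angstroms.
#' @examples
#' compute_polarizability("C")  # methane: 1.061 + 4 * 0.387 = 2.609
#' compute_polarizability("O")  # water:   0.637 + 2 * 0.387 = 1.411
#' @export
compute_polarizability <- function(mol) {
  mol <- .as_molgraph(mol)
  mol <- parent_fragment(mol)
  env <- .atom_env(mol)
  total <- 0
  for (e in env) {
    tab <- .miller_ahc[[e$el]]
    if (is.null(tab)) {
      warning("no polarizability component for element ", e$el,
              "; contributing 0", call. = FALSE)
      contrib <- 0
    } else if (length(tab) == 1L) {
      contrib <- tab[[1]]
    } else {
      hy <- .hybridization(e)
      contrib <- if (hy %in% names(tab)) tab[[hy]] else tab[[length(tab)]]
    }
    total <- total + contrib + e$h * .miller_ahc$H[[1]]
  }
  total
}

# ---- rotatable bonds & aromatic proportion ---------------------------------

#' Count rotatable bonds
#'
#' Single, acyclic bonds between two heavy atoms that each carry at least one
#' other heavy neighbor (the simple definition; amide C-N bonds are counted).
#'
#' @param mol A `molgraph` or SMILES string.
#' @return Integer count (parent fragment).
#' @export
count_rotatable_bonds <- function(mol) {
  mol <- .as_molgraph(mol)
  mol <- parent_fragment(mol)
  b <- mol$bonds
  if (nrow(b) == 0L) return(0L)
  deg <- mol$atoms$degree
  sum(b$order == 1 & !b$in_ring & deg[b$a1] > 1L & deg[b$a2] > 1L)
}

#' Aromatic proportion of heavy atoms
#'
#' @param mol A `molgraph` or SMILES string.
#' @return Fraction of parent heavy atoms flagged aromatic.
#' @export
aromatic_proportion <- function(mol) {
  mol <- .as_molgraph(mol)
  mol <- parent_fragment(mol)
  mean(mol$atoms$aromatic)
}

# ---- aqueous solubility (ESOL) ---------------------------------------------

#' Estimated aqueous solubility (log scale)
#'
#' Evaluates the published ESOL linear model (Delaney, J. Chem. Inf. Comput.
#' Sci. 44 (2004) 1000-1005): log10 S (mol/L) = 0.16 - 0.63 clogP
#' - 0.0062 MW + 0.066 RB - 0.74 AP, then converts to log10(mg/mL) by adding
#' log10(MW) (1 mol/L = MW g/L = MW mg/mL).
#'
#' @param clogp Calculated logP.
#' @param mw Molecular weight, g/mol (must be > 0).
#' @param rotatable Rotatable bond count.
#' @param aromatic_prop Aromatic proportion in `[0, 1]`.
#' @return log10 aqueous solubility in mg/mL.
#' @export
compute_logs <- function(clogp, mw, rotatable, aromatic_prop) {
  if (!is.finite(mw) || mw <= 0) stop("mw must be > 0", call. = FALSE)
  logs_mol <- 0.16 - 0.63 * clogp - 0.0062 * mw + 0.066 * rotatable -
    0.74 * aromatic_prop
  logs_mol + log10(mw)
}

# ---- basic pKa lookup -------------------------------------------------------

# Functional-group pKa lookup for basic nitrogen centers. No per-molecule
# pKa engine is assumed; the table is configurable.
.default_pka_table <- c(
  primary_aliphatic_amine = 10.6,
  secondary_aliphatic_amine = 10.8,
  tertiary_aliphatic_amine = 9.8,
  diethylaminoethyl_amide_side_chain = 9.5,
  amide_substituted_piperazine = 7.8,
  aniline = 4.6
)

#' Estimate the pKa of the most basic center
#'
#' Classifies nitrogen atoms of the parent fragment by functional group and
#' returns the highest lookup pKa. Amide nitrogens (bonded to a carbonyl
#' carbon) are non-basic. A quaternary, permanently charged nitrogen returns
#' `Inf`, the sentinel for a permanent cation; a molecule with no basic
#' nitrogen returns `NA` ("none").
#'
#' @param mol A `molgraph` or SMILES string.
#' @param pka_table Named numeric lookup table (see Details in the source).
#' @return Finite pKa, `Inf` (permanent cation) or `NA` (no basic center).
#' @export
estimate_pka_basic <- function(mol, pka_table = .default_pka_table) {
  mol <- .as_molgraph(mol)
  mol <- parent_fragment(mol)
  env <- .atom_env(mol)
  n_idx <- which(vapply(env, function(e) e$el == "N", FALSE))
  if (length(n_idx) == 0L) return(NA_real_)

  is_amide_n <- function(e) {
    for (k in seq_along(e$nbr_idx)) {
      if (e$nbr_el[k] == "C" && !e$nbr_arom[k] && e$bond_order[k] == 1) {
        ce <- env[[e$nbr_idx[k]]]
        if (any(ce$bond_order == 2 & ce$nbr_el %in% c("O", "S"))) return(TRUE)
      }
    }
    FALSE
  }

  best <- NA_real_
  for (i in n_idx) {
    e <- env[[i]]
    if (e$charge > 0 && e$h == 0 && e$n_single == 4) return(Inf)
    if (e$arom) next                      # azine/azole N: not in the table
    if (e$n_double > 0 || e$n_triple > 0) next
    if (is_amide_n(e)) next               # amide N non-basic
    heavy_deg <- length(e$nbr_idx)
    group <- if (any(e$nbr_arom)) {
      "aniline"
    } else if (heavy_deg == 3L) {
      # tertiary: piperazine amide and diethylaminoethyl-amide side chains
      # get their own entries
      if (e$in_ring && .ring_partner_is_amide_n(i, env)) {
        "amide_substituted_piperazine"
      } else if (.two_bonds_from_amide_n(i, env)) {
        "diethylaminoethyl_amide_side_chain"
      } else {
        "tertiary_aliphatic_amine"
      }
    } else if (heavy_deg == 2L) {
      "secondary_aliphatic_amine"
    } else {
      "primary_aliphatic_amine"
    }
    val <- pka_table[[group]]
    if (is.null(val)) next
    if (is.na(best) || val > best) best <- val
  }
  best
}

# Is there another N in the same ring system that is an amide N?
.ring_partner_is_amide_n <- function(i, env) {
  for (j in seq_along(env)) {
    if (j == i) next
    e <- env[[j]]
    if (e$el != "N" || !e$in_ring) next
    amide <- FALSE
    for (k in seq_along(e$nbr_idx)) {
      if (e$nbr_el[k] == "C" && !e$nbr_arom[k] && e$bond_order[k] == 1) {
        ce <- env[[e$nbr_idx[k]]]
        if (any(ce$bond_order == 2 & ce$nbr_el %in% c("O", "S"))) amide <- TRUE
      }
    }
    if (amide) return(TRUE)
  }
  FALSE
}

# Tertiary amine two methylenes away from an amide nitrogen (the
# N,N-dialkylaminoethyl-amide side chain).
.two_bonds_from_amide_n <- function(i, env) {
  e <- env[[i]]
  for (k in seq_along(e$nbr_idx)) {
    c1 <- env[[e$nbr_idx[k]]]
    if (c1$el != "C" || c1$arom) next
    for (k2 in seq_along(c1$nbr_idx)) {
      c2 <- env[[c1$nbr_idx[k2]]]
      if (c2$el != "C" || c2$arom) next
      for (k3 in seq_along(c2$nbr_idx)) {
        nn <- env[[c2$nbr_idx[k3]]]
        if (nn$el != "N") next
        for (k4 in seq_along(nn$nbr_idx)) {
          if (nn$nbr_el[k4] == "C" && !nn$nbr_arom[k4] &&
              nn$bond_order[k4] == 1) {
            ce <- env[[nn$nbr_idx[k4]]]
            if (any(ce$bond_order == 2 & ce$nbr_el %in% c("O", "S")))
              return(TRUE)
          }
        }
      }
    }
  }
  FALSE
}

# ---- clogD ------------------------------------------------------------------

#' Distribution coefficient at a given pH
#'
#' For a monobasic center: clogD = clogP - log10(1 + 10^(pKa - pH)). With no
#' basic center (pKa `NA`) clogD equals clogP. A permanent cation (pKa `Inf`)
#' takes a capped hydrophilicity penalty of 4 log units.
#'
#' @param clogp Calculated logP.
#' @param pka_basic Finite pKa, `NA` (none) or `Inf` (permanent cation).
#' @param pH pH, default 7.4.
#' @return clogD estimate. Always `<=` clogP, with equality iff no basic
#'   center.
#' @export
compute_clogd <- function(clogp, pka_basic, pH = 7.4) {
  if (is.na(pka_basic)) return(clogp)
  if (is.infinite(pka_basic)) return(clogp - 4)
  clogp - log10(1 + 10 ^ (pka_basic - pH))
}

# ---- H-bond donors / acceptors ---------------------------------------------

#' Count hydrogen-bond donors and acceptors at a given pH
#'
#' Donors are N-H and O-H hydrogens; acceptors are N and O atoms bearing a
#' lone pair, excluding amide nitrogens, pyrrole-type aromatic nitrogens and
#' positively charged nitrogens. The counts are taken on the pH-adjusted
#' microspecies: a basic center whose lookup pKa exceeds `pH` is protonated,
#' which adds one donor hydrogen and removes that nitrogen as an acceptor.
#'
#' @param mol A `molgraph` or SMILES string.
#' @param pH pH for the protonation state, default 7.
#' @return Integer vector `c(hbd, hba)`.
#' @examples
#' count_hbd_hba("O")         # water: 2 donors, 1 acceptor
#' count_hbd_hba("c1ccccc1")  # benzene: 0, 0
#' @export
count_hbd_hba <- function(mol, pH = 7) {
  mol <- .as_molgraph(mol)
  mol <- parent_fragment(mol)
  env <- .atom_env(mol)
  pka <- estimate_pka_basic(mol)
  protonate <- !is.na(pka) && is.finite(pka) && pka > pH

  # locate the basic center actually protonated (highest-pKa N)
  basic_idx <- NA_integer_
  if (protonate) {
    cand <- which(vapply(env, function(e) {
      e$el == "N" && !e$arom && e$charge == 0 && e$n_double == 0 &&
        e$n_triple == 0
    }, FALSE))
    # drop amide Ns
    cand <- cand[vapply(cand, function(i) {
      e <- env[[i]]
      !any(vapply(seq_along(e$nbr_idx), function(k) {
        e$nbr_el[k] == "C" && !e$nbr_arom[k] && e$bond_order[k] == 1 &&
          any(env[[e$nbr_idx[k]]]$bond_order == 2 &
              env[[e$nbr_idx[k]]]$nbr_el %in% c("O", "S"))
      }, FALSE))
    }, FALSE)]
    # most substituted aliphatic amine = most basic under the lookup table
    if (length(cand) > 0L) basic_idx <- cand[which.max(
      vapply(cand, function(i) length(env[[i]]$nbr_idx), 0L))]
    else protonate <- FALSE
  }

  hbd <- 0L
  hba <- 0L
  for (i in seq_along(env)) {
    e <- env[[i]]
    if (!e$el %in% c("N", "O")) next
    h_here <- e$h
    charge_here <- e$charge
    if (protonate && identical(i, basic_idx)) {
      h_here <- h_here + 1L
      charge_here <- charge_here + 1L
    }
    hbd <- hbd + h_here
    if (e$el == "O") {
      hba <- hba + 1L
    } else {
      if (charge_here > 0) next
      is_amide <- any(vapply(seq_along(e$nbr_idx), function(k) {
        e$nbr_el[k] == "C" && !e$nbr_arom[k] && e$bond_order[k] == 1 &&
          any(env[[e$nbr_idx[k]]]$bond_order == 2 &
              env[[e$nbr_idx[k]]]$nbr_el %in% c("O", "S"))
      }, FALSE))
      if (is_amide) next
      pyrrole_type <- e$arom && (e$h > 0 || e$n_single == 1)
      if (pyrrole_type) next
      hba <- hba + 1L
    }
  }
  c(hbd = hbd, hba = hba)
}

# ---- panel wrapper ----------------------------------------------------------

.as_molgraph <- function(x) {
  if (inherits(x, "molgraph")) return(x)
  parse_structure(x)
}

#' Compute the full Panel-B descriptor panel for one structure
#'
#' Computes ClogP, TPSA, HBD/HBA, MW, polarizability, estimated logS, minimal
#' projection area, basic pKa and clogD on the parent fragment.
#'
#' @param x A SMILES string or `molgraph`.
#' @param seed Seed for the 3D embedding behind the MPA calculation.
#' @param include_mpa Set `FALSE` to skip the (conformer-based) MPA.
#' @param pH pH for the H-bond counts, default 7.
#' @return A one-row data.frame with columns `clogp`, `psa`, `hbd`, `hba`,
#'   `mw`, `mp`, `logs`, `mpa`, `pka_basic`, `clogd`.
#' @export
descriptor_panel <- function(x, seed = 7L, include_mpa = TRUE, pH = 7) {
  mol <- parent_fragment(.as_molgraph(x))
  clogp <- compute_clogp(mol)
  psa <- compute_tpsa(mol)
  hh <- count_hbd_hba(mol, pH = pH)
  mw <- compute_mw(mol)
  mp <- compute_polarizability(mol)
  logs <- compute_logs(clogp, mw, count_rotatable_bonds(mol),
                       aromatic_proportion(mol))
  pka <- estimate_pka_basic(mol)
  clogd <- compute_clogd(clogp, pka)
  mpa <- NA_real_
  if (include_mpa) {
    conf <- generate_conformer(mol, seed = seed)
    mpa <- compute_mpa(conf)
  }
  data.frame(clogp = clogp, psa = psa, hbd = unname(hh["hbd"]),
             hba = unname(hh["hba"]), mw = mw, mp = mp, logs = logs,
             mpa = mpa, pka_basic = pka, clogd = clogd)
}

#' Profile every compound of a library
#'
#' @param lib A `bpa_library` or a data.frame with `id` and `smiles` columns.
#' @param seed Seed for the 3D embeddings.
#' @param include_mpa Set `FALSE` to skip MPA (much faster).
#' @return data.frame with column `id` followed by the panel columns.
#' @export
profile_library <- function(lib, seed = 7L, include_mpa = TRUE) {
  tab <- if (inherits(lib, "bpa_library")) lib$compounds else lib
  stopifnot(all(c("id", "smiles") %in% names(tab)))
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    p <- descriptor_panel(tab$smiles[i], seed = seed,
                          include_mpa = include_mpa)
    cbind(data.frame(id = tab$id[i], stringsAsFactors = FALSE), p)
  })
  do.call(rbind, rows)
}

#' Format a pKa value for tabular output
#'
#' @param pka Numeric pKa (finite, `NA` for none, `Inf` for permanent
#'   cation).
#' @return Character representation (`"none"`, `"permanent_cation"` or the
#'   number).
#' @export
format_pka <- function(pka) {
  vapply(pka, function(p) {
    if (is.na(p)) "none"
    else if (is.infinite(p)) "permanent_cation"
    else format(p)
  }, "")
}
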