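# SMILES parsing and the internal molecule handle.
#
# Structure perception (parsing, canonicalization, ring/aromaticity detection,
# 2D coordinates) is delegated to ChemmineR/ChemmineOB (OpenBabel). The handle
# keeps the heavy-atom graph plus the derived per-atom annotations that the
# featurizers need; hydrogens stay implicit.

MDL_CHARGE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                `5` = -1L, `6` = -2L, `7` = -3L)

DEFAULT_VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L, F = 1L,
                     Cl = 1L, Br = 1L, I = 1L, B = 3L, Si = 4L, Se = 2L,
                     As = 3L)

#' Parse and validate a SMILES string
#'
#' Converts a SMILES string to an internal molecule handle, rejecting any
#' string that does not describe a chemically valid structure. Invalid input
#' yields `NULL` (never an error), so batch loaders can drop and log bad
#' records instead of aborting.
#'
#' @param smiles a SMILES string.
#' @return a `moltitox_mol` handle, or `NULL` if the string cannot be parsed.
#' @examples
#' \donttest{
#' mol <- parse_and_validate("CCO")
#' mol$n_atoms
#' }
#' @export
parse_and_validate <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    return(NULL)
  }
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "m"))),
    error = function(e) NULL
  )
  if (is.null(sdf) || length(sdf) < 1L) return(NULL)
  sdf1 <- sdf[[1]]
  ok <- tryCatch(ChemmineR::validSDF(sdf), error = function(e) FALSE)
  if (!isTRUE(ok[1])) {
    # ChemmineR rejects bond-free records; single heavy atoms are still valid
    return(parse_single_atom(smiles))
  }
  mol <- tryCatch(build_mol_handle(sdf1, smiles), error = function(e) NULL)
  if (is.null(mol) || mol$n_atoms < 1L) return(NULL)
  mol
}

# fallback for molecules with one heavy atom (e.g. "C", "[Na+]"), which
# ChemmineR's SDF container cannot represent
parse_single_atom <- function(smiles) {
  txt <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF", smiles)),
    error = function(e) ""
  )
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 5L) return(NULL)
  counts <- lines[4]
  n <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nb <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(n) || n != 1L || is.na(nb) || nb != 0L) return(NULL)
  fields <- strsplit(trimws(lines[5]), "\\s+")[[1]]
  symbol <- fields[4]
  charge <- unname(MDL_CHARGE[fields[6]]) %||% 0L
  if (is.na(charge)) charge <- 0L
  val <- DEFAULT_VALENCE[symbol]
  if (is.na(val)) val <- 0L
  adj <- if (symbol %in% c("N", "O", "P", "S", "B")) charge else -abs(charge)
  structure(list(
    smiles = smiles, cansmi = canonical_smiles(smiles), n_atoms = 1L,
    symbol = symbol, charge = as.integer(charge), degree = 0L,
    n_h = max(0L, as.integer(val + adj)), hybrid = "sp3", aromatic = FALSE,
    in_ring = FALSE, chiral = FALSE, radical = 0L,
    bonds = data.frame(a1 = integer(0), a2 = integer(0), order = integer(0)),
    bond_aromatic = logical(0),
    coords = matrix(0, 1L, 2L)
  ), class = "moltitox_mol")
}

canonical_smiles <- function(smiles) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles)),
    error = function(e) ""
  )
  sub("\t.*", "", sub("\n.*", "", out))
}

build_mol_handle <- function(sdf1, smiles) {
  ab <- ChemmineR::atomblock(sdf1)
  bb <- ChemmineR::bondblock(sdf1)
  n <- nrow(ab)
  symbol <- sub("_.*", "", rownames(ab))
  coords <- cbind(ab[, 1L], ab[, 2L])
  charge_code <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, n)
  charge <- unname(MDL_CHARGE[as.character(pmax(0, pmin(7, charge_code)))])
  charge[is.na(charge)] <- 0L
  stereo <- if ("C7" %in% colnames(ab)) ab[, "C7"] else rep(0, n)

  if (is.null(bb) || nrow(bb) == 0L) {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    bonds <- data.frame(a1 = as.integer(bb[, 1L]), a2 = as.integer(bb[, 2L]),
                        order = as.integer(bb[, 3L]))
  }

  # ring + aromaticity perception
  in_ring <- rep(FALSE, n)
  arom_atom <- rep(FALSE, n)
  arom_bond <- rep(FALSE, nrow(bonds))
  if (nrow(bonds) > 0L) {
    rg <- tryCatch(
      ChemmineR::rings(sdf1, upper = Inf, type = "all", arom = TRUE,
                       inner = TRUE),
      error = function(e) NULL
    )
    if (!is.null(rg) && length(rg$RINGS) > 0L) {
      ring_sets <- lapply(rg$RINGS, function(r) {
        as.integer(sub(".*_", "", r))
      })
      for (k in seq_along(ring_sets)) {
        in_ring[ring_sets[[k]]] <- TRUE
        if (isTRUE(rg$AROMATIC[k])) {
          arom_atom[ring_sets[[k]]] <- TRUE
          mem <- logical(n); mem[ring_sets[[k]]] <- TRUE
          arom_bond <- arom_bond | (mem[bonds$a1] & mem[bonds$a2])
        }
      }
    }
  }

  degree <- tabulate(c(bonds$a1, bonds$a2), nbins = n)
  bosum <- rep(0L, n)
  if (nrow(bonds) > 0L) {
    bosum <- tabulate(c(bonds$a1, bonds$a2), nbins = n) * 0L
    for (j in seq_len(nrow(bonds))) {
      bosum[bonds$a1[j]] <- bosum[bonds$a1[j]] + bonds$order[j]
      bosum[bonds$a2[j]] <- bosum[bonds$a2[j]] + bonds$order[j]
    }
  }
  val <- DEFAULT_VALENCE[symbol]
  val[is.na(val)] <- bosum[is.na(val)]          # unknown element: no implicit H
  adj <- ifelse(symbol %in% c("N", "O", "P", "S", "B"), charge, -abs(charge))
  n_h <- pmax(0L, as.integer(val + adj - bosum))

  hybrid <- rep("sp3", n)
  if (nrow(bonds) > 0L) {
    n_double <- rep(0L, n); n_triple <- rep(0L, n)
    for (j in seq_len(nrow(bonds))) {
      if (bonds$order[j] == 2L) {
        n_double[bonds$a1[j]] <- n_double[bonds$a1[j]] + 1L
        n_double[bonds$a2[j]] <- n_double[bonds$a2[j]] + 1L
      } else if (bonds$order[j] == 3L) {
        n_triple[bonds$a1[j]] <- n_triple[bonds$a1[j]] + 1L
        n_triple[bonds$a2[j]] <- n_triple[bonds$a2[j]] + 1L
      }
    }
    hybrid[n_double >= 1L | arom_atom] <- "sp2"
    hybrid[n_triple >= 1L | n_double >= 2L] <- "sp"
  }

  structure(list(
    smiles = smiles,
    cansmi = canonical_smiles(smiles),
    n_atoms = n,
    symbol = symbol,
    charge = as.integer(charge),
    degree = as.integer(degree),
    n_h = n_h,
    hybrid = hybrid,
    aromatic = arom_atom,
    in_ring = in_ring,
    chiral = stereo %in% c(1, 2),
    radical = rep(0L, n),
    bonds = bonds,
    bond_aromatic = arom_bond,
    coords = coords
  ), class = "moltitox_mol")
}

#' @export
print.moltitox_mol <- function(x, ...) {
  cat(sprintf("<moltitox_mol> %s  (%d heavy atoms, %d bonds)\n",
              x$cansmi, x$n_atoms, nrow(x$bonds)))
  invisible(x)
}

# ---- Bemis-Murcko scaffold -------------------------------------------------

#' Bemis-Murcko scaffold of a molecule
#'
#' Reduces a molecule to its ring systems plus connecting linkers by
#' iteratively pruning terminal side-chain atoms, then returns the canonical
#' SMILES of the remainder. Acyclic molecules yield the empty scaffold `""`,
#' which scaffold-aware splitting treats as one shared group.
#'
#' @param mol a `moltitox_mol` handle from [parse_and_validate()].
#' @return a scaffold SMILES string (possibly `""`).
#' @export
bemis_murcko_scaffold <- function(mol) {
  stopifnot(inherits(mol, "moltitox_mol"))
  if (!any(mol$in_ring)) return("")
  keep <- rep(TRUE, mol$n_atoms)
  bonds <- mol$bonds
  repeat {
    deg <- tabulate(c(bonds$a1[keep[bonds$a1] & keep[bonds$a2]],
                      bonds$a2[keep[bonds$a1] & keep[bonds$a2]]),
                    nbins = mol$n_atoms)
    live <- keep[bonds$a1] & keep[bonds$a2]
    # terminal atom reachable through a single bond: side-chain atom
    drop1 <- rep(FALSE, mol$n_atoms)
    for (j in which(live)) {
      if (bonds$order[j] == 1L) {
        if (deg[bonds$a1[j]] == 1L && !mol$in_ring[bonds$a1[j]]) drop1[bonds$a1[j]] <- TRUE
        if (deg[bonds$a2[j]] == 1L && !mol$in_ring[bonds$a2[j]]) drop1[bonds$a2[j]] <- TRUE
      }
    }
    # terminal atoms double/triple-bonded to a non-ring atom (chain remnants)
    for (j in which(live)) {
      if (bonds$order[j] > 1L) {
        if (deg[bonds$a1[j]] == 1L && !mol$in_ring[bonds$a1[j]] &&
            !mol$in_ring[bonds$a2[j]]) drop1[bonds$a1[j]] <- TRUE
        if (deg[bonds$a2[j]] == 1L && !mol$in_ring[bonds$a2[j]] &&
            !mol$in_ring[bonds$a1[j]]) drop1[bonds$a2[j]] <- TRUE
      }
    }
    drop1 <- drop1 & keep
    if (!any(drop1)) break
    keep[drop1] <- FALSE
  }
  atoms <- which(keep)
  if (length(atoms) == 0L) return("")
  remap <- match(seq_len(mol$n_atoms), atoms)
  bsel <- keep[bonds$a1] & keep[bonds$a2]
  sub_bonds <- data.frame(a1 = remap[bonds$a1[bsel]], a2 = remap[bonds$a2[bsel]],
                          order = bonds$order[bsel])
  mol_to_cansmi(mol$symbol[atoms], mol$charge[atoms], sub_bonds)
}

# canonical SMILES of an explicit atom/bond list via a V2000 block
mol_to_cansmi <- function(symbol, charge, bonds) {
  n <- length(symbol)
  rev_chg <- c(`3` = 1L, `2` = 2L, `1` = 3L, `0` = 0L, `-1` = 5L,
               `-2` = 6L, `-3` = 7L)
  atom_lines <- vapply(seq_len(n), function(i) {
    sprintf("    0.0000    0.0000    0.0000 %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
            symbol[i], rev_chg[as.character(charge[i])] %||% 0L)
  }, "")
  bond_lines <- if (nrow(bonds) > 0L) {
    vapply(seq_len(nrow(bonds)), function(j) {
      sprintf("%3d%3d%3d  0  0  0  0", bonds$a1[j], bonds$a2[j], bonds$order[j])
    }, "")
  } else character(0)
  mol_txt <- paste(c("scaffold", " moltitox", "",
                     sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                             n, nrow(bonds)),
                     atom_lines, bond_lines, "M  END", "$$$$"),
                   collapse = "\n")
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", mol_txt)),
    error = function(e) ""
  )
  sub("\t.*", "", sub("\n.*", "", out))
}
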