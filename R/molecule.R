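# Molecular structure container and parsing.
#
# Structures enter either as SMILES (topology only) or as V2000 SDF carrying
# the 3D geometry that the geometric descriptors require.  Parsing, kekulized
# bond orders and ring perception are delegated to ChemmineR/OpenBabel; the
# molecule object itself is a plain list so that every descriptor routine can
# work on ordinary vectors and matrices.

# Standard atomic weights (u), 2021 IUPAC abridged values.
.ATOMIC_MASS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Cr = 51.996, Mn = 54.938, Fe = 55.845,
  Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.38, As = 74.922,
  Se = 78.971, Br = 79.904, Sn = 118.71, Sb = 121.76, I = 126.904,
  Hg = 200.59, Pb = 207.2
)

.HALOGENS <- c("F", "Cl", "Br", "I", "At")

# Default valences used to resolve implicit hydrogen counts on the kekulized
# graph; formal charge shifts the valence (N+ -> 4, O- -> 1).
.DEFAULT_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, B = 3, Si = 4,
                      F = 1, Cl = 1, Br = 1, I = 1, H = 1)

#' Construct a molecule object
#'
#' Low-level constructor; most users should call [parse_smiles()] or
#' [read_sdf()], which also perform ring and aromaticity perception.
#'
#' @param id character label.
#' @param atoms data frame with columns `element`, `mass`, `charge`, `nH`
#'   (attached hydrogens, implicit + explicit), `aromatic`, `in_ring`.
#' @param bonds data frame with columns `i`, `j`, `order` (1, 2 or 3) and
#'   `aromatic`.
#' @param coords optional numeric matrix (atoms x 3) of Cartesian positions
#'   in Angstrom.
#' @param rings list of integer vectors, the smallest set of smallest rings
#'   as atom indices.
#' @return An object of class `"molecule"`.
#' @export
molecule <- function(id, atoms, bonds, coords = NULL, rings = list()) {
  stopifnot(is.data.frame(atoms), is.data.frame(bonds))
  n <- nrow(atoms)
  if (nrow(bonds)) {
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n))
      stop("bond endpoint out of range")
    if (any(bonds$i == bonds$j)) stop("self-bond not allowed")
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("duplicate bond")
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 3)
      stop("coords must be an atoms x 3 matrix")
    if (!all(is.finite(coords))) stop("non-finite coordinate")
    if (n >= 2 && max(apply(coords, 2, function(z) diff(range(z)))) == 0)
      stop("all atomic positions identical; no geometry")
  }
  structure(list(id = id, atoms = atoms, bonds = bonds, coords = coords,
                 rings = rings),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  nh <- sum(x$atoms$element != "H")
  cat(sprintf("<molecule %s: %d atoms (%d heavy), %d bonds, %s, %d ring%s>\n",
              x$id, nrow(x$atoms), nh, nrow(x$bonds),
              if (is.null(x$coords)) "no 3D" else "3D",
              length(x$rings), if (length(x$rings) == 1) "" else "s"))
  invisible(x)
}

.implicit_h <- function(element, charge, bond_order_sum) {
  val <- .DEFAULT_VALENCE[element]
  if (is.na(val)) return(0L)
  as.integer(max(0, val + charge - bond_order_sum))
}

# Old-style V2000 charge codes: 1..7 -> +3..-3 (4 = radical, charge 0).
.v2000_charge <- function(code) {
  map <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L,
           `6` = -2L, `7` = -3L)
  out <- map[as.character(code)]
  out[is.na(out)] <- 0L
  unname(out)
}

# Smallest set of smallest rings: greedy selection of size-sorted candidate
# rings whose edge-incidence vectors are independent over GF(2), up to the
# cyclomatic number of the heavy graph.
.sssr <- function(candidate_rings, bonds, n_atoms) {
  if (!length(candidate_rings)) return(list())
  n_edges <- nrow(bonds)
  ekey <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
  mu <- n_edges - n_atoms + length(unique(.components(bonds, n_atoms)))
  if (mu <= 0) return(list())
  ord <- order(vapply(candidate_rings, length, 1L))
  basis <- matrix(0L, nrow = 0, ncol = n_edges)
  chosen <- list()
  for (r in candidate_rings[ord]) {
    k <- length(r)
    e <- integer(n_edges)
    for (t in seq_len(k)) {
      a <- r[t]; b <- r[if (t == k) 1L else t + 1L]
      e[match(paste(min(a, b), max(a, b)), ekey)] <- 1L
    }
    # GF(2) reduction against current basis
    v <- e
    if (nrow(basis)) for (row in seq_len(nrow(basis))) {
      piv <- which(basis[row, ] == 1L)[1]
      if (v[piv] == 1L) v <- (v + basis[row, ]) %% 2L
    }
    if (any(v == 1L)) {
      basis <- rbind(basis, v)
      chosen[[length(chosen) + 1L]] <- r
      if (length(chosen) == mu) break
    }
  }
  chosen
}

.components <- function(bonds, n_atoms) {
  comp <- seq_len(n_atoms)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  if (nrow(bonds)) for (b in seq_len(nrow(bonds))) {
    ri <- find(bonds$i[b]); rj <- find(bonds$j[b])
    if (ri != rj) comp[ri] <- rj
  }
  vapply(seq_len(n_atoms), find, 1L)
}

# Build a molecule from one ChemmineR SDF record.
.mol_from_chemmine <- function(sdf, id, use_coords) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  n <- length(elements)
  if (n == 0) stop("record contains no atoms")
  if (!all(grepl("^[A-Z][a-z]?$", elements)))
    stop("unparseable atom block (bond-less records are not supported here)")
  charge <- .v2000_charge(if (ncol(ab) >= 5) ab[, 5] else rep(0, n))
  bonds <- if (is.null(bb) || nrow(bb) == 0) {
    data.frame(i = integer(0), j = integer(0), order = integer(0),
               aromatic = logical(0))
  } else {
    data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]), aromatic = FALSE)
  }
  # OpenBabel occasionally writes the aromatic order code 4; kekulization
  # normally prevents it, but map it to order 1 + aromatic flag if seen.
  if (any(bonds$order == 4L)) {
    bonds$aromatic[bonds$order == 4L] <- TRUE
    bonds$order[bonds$order == 4L] <- 1L
  }
  bond_sum <- numeric(n)
  h_neigh <- integer(n)
  if (nrow(bonds)) for (b in seq_len(nrow(bonds))) {
    o <- bonds$order[b]
    bond_sum[bonds$i[b]] <- bond_sum[bonds$i[b]] + o
    bond_sum[bonds$j[b]] <- bond_sum[bonds$j[b]] + o
    if (elements[bonds$j[b]] == "H") h_neigh[bonds$i[b]] <- h_neigh[bonds$i[b]] + 1L
    if (elements[bonds$i[b]] == "H") h_neigh[bonds$j[b]] <- h_neigh[bonds$j[b]] + 1L
  }
  nH_impl <- vapply(seq_len(n), function(a) {
    .implicit_h(elements[a], charge[a], bond_sum[a])
  }, 1L)
  nH_impl[elements == "H"] <- 0L
  nH <- nH_impl + h_neigh
  nH[elements == "H"] <- 0L

  # Ring + aromaticity perception on the parsed record.
  ring_atoms <- list(); arom_flags <- logical(0)
  if (nrow(bonds) >= 3) {
    ri <- tryCatch(ChemmineR::rings(sdf, upper = 14, type = "all", arom = TRUE),
                   error = function(e) list(RINGS = list(), AROMATIC = logical(0)))
    ring_atoms <- lapply(ri$RINGS, function(r) as.integer(sub("^.*_", "", r)))
    arom_flags <- as.logical(ri$AROMATIC)
  }
  atoms <- data.frame(
    element = elements,
    mass = unname(ifelse(is.na(.ATOMIC_MASS[elements]), 0, .ATOMIC_MASS[elements])),
    charge = charge, nH = nH, nH_impl = nH_impl,
    aromatic = FALSE, in_ring = FALSE,
    stringsAsFactors = FALSE
  )
  if (length(ring_atoms)) {
    for (k in seq_along(ring_atoms)) {
      atoms$in_ring[ring_atoms[[k]]] <- TRUE
      if (isTRUE(arom_flags[k])) atoms$aromatic[ring_atoms[[k]]] <- TRUE
    }
    # A bond is aromatic when it joins consecutive members of an aromatic ring.
    if (nrow(bonds)) {
      bkey <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
      for (k in which(arom_flags)) {
        r <- ring_atoms[[k]]; m <- length(r)
        for (t in seq_len(m)) {
          a <- r[t]; b2 <- r[if (t == m) 1L else t + 1L]
          hit <- match(paste(min(a, b2), max(a, b2)), bkey)
          if (!is.na(hit)) bonds$aromatic[hit] <- TRUE
        }
      }
    }
  }
  sssr <- .sssr(ring_atoms, bonds, n)
  coords <- NULL
  if (use_coords) {
    coords <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
    if (n >= 2 && max(apply(coords, 2, function(z) diff(range(z)))) == 0)
      coords <- NULL  # flat/absent geometry; caller decides how to flag
  }
  mol <- molecule(id = id, atoms = atoms, bonds = bonds, coords = coords,
                  rings = sssr)
  mol$sdf <- sdf
  mol
}

#' Parse a SMILES string
#'
#' Builds a [molecule()] with perceived aromaticity, ring membership and
#' implicit hydrogen counts.  No 3D coordinates are generated: geometric
#' descriptors require structures read from an SDF with real geometries
#' (see [read_sdf()]).
#'
#' @param smiles a single SMILES string.
#' @param id label for the molecule (defaults to the SMILES itself).
#' @return A `"molecule"` object without coordinates.
#' @examples
#' m <- parse_smiles("CNC(=O)Oc1ccccc1")  # phenyl N-methylcarbamate
#' m
#' @export
parse_smiles <- function(smiles, id = smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, id))),
    error = function(e) stop(sprintf("cannot parse SMILES '%s': %s",
                                     smiles, conditionMessage(e)), call. = FALSE))
  sdf <- sdfset[[1]]
  if (length(ChemmineR::atomblock(sdf)) == 0 || nrow(ChemmineR::atomblock(sdf)) == 0)
    stop(sprintf("cannot parse SMILES '%s': empty structure", smiles),
         call. = FALSE)
  mol <- tryCatch(.mol_from_chemmine(sdf, id, use_coords = FALSE),
                  error = function(e) {
                    # bond-less structures (single atoms, atomic ions) fall
                    # outside ChemmineR's SDF container; parse them directly
                    .mol_from_obabel_text(smiles, id)
                  })
  mol$smiles <- smiles
  mol
}

# Minimal V2000 reader for bond-less structures, fed from the OpenBabel
# converter (never used when ChemmineR can represent the record).
.mol_from_obabel_text <- function(smiles, id) {
  txt <- ChemmineOB::convertFormat("SMI", "SDF",
                                   source = sprintf("%s %s\n", smiles, id))
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  n <- as.integer(substr(lines[4], 1, 3))
  nb <- as.integer(substr(lines[4], 4, 6))
  if (is.na(n) || n < 1) stop(sprintf("cannot parse SMILES '%s'", smiles))
  at <- lines[4 + seq_len(n)]
  elements <- trimws(substr(at, 32, 34))
  charge <- integer(n)
  for (l in grep("^M  CHG", lines, value = TRUE)) {
    fld <- as.integer(strsplit(trimws(substr(l, 7, nchar(l))), "\\s+")[[1]])
    k <- fld[1]
    for (t in seq_len(k)) charge[fld[2 * t]] <- fld[2 * t + 1]
  }
  bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0),
                      aromatic = logical(0))
  if (!is.na(nb) && nb > 0) {
    bl <- lines[4 + n + seq_len(nb)]
    bonds <- data.frame(i = as.integer(substr(bl, 1, 3)),
                        j = as.integer(substr(bl, 4, 6)),
                        order = as.integer(substr(bl, 7, 9)),
                        aromatic = FALSE)
  }
  nH <- vapply(seq_len(n), function(a) {
    bs <- sum(bonds$order[bonds$i == a | bonds$j == a])
    .implicit_h(elements[a], charge[a], bs)
  }, 1L)
  atoms <- data.frame(
    element = elements,
    mass = unname(ifelse(is.na(.ATOMIC_MASS[elements]), 0, .ATOMIC_MASS[elements])),
    charge = charge, nH = nH, nH_impl = nH,
    aromatic = FALSE, in_ring = FALSE, stringsAsFactors = FALSE)
  molecule(id = id, atoms = atoms, bonds = bonds)
}

#' Read molecules from an SDF file
#'
#' Reads a V2000/V3000 SD file, one [molecule()] per record, taking 3D
#' coordinates from the atom block.  Records that fail to parse are skipped
#' with a message; records whose coordinates are all identical (no geometry)
#' are kept but flagged with `coords = NULL` and listed in the
#' `"no_geometry"` attribute.
#'
#' @param path path to an SDF file.
#' @return list of `"molecule"` objects, with attributes `"n_failed"` and
#'   `"no_geometry"`.
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read SDF '%s'", path))
  sdfset <- tryCatch(ChemmineR::read.SDFset(path),
                     error = function(e) stop(sprintf("cannot read SDF '%s': %s",
                                                      path, conditionMessage(e))))
  n <- length(sdfset)
  if (n == 0) stop(sprintf("no parseable records in '%s'", path))
  ids <- ChemmineR::sdfid(sdfset)
  out <- list(); failed <- 0L; no_geom <- character(0)
  for (k in seq_len(n)) {
    id <- if (!is.na(ids[k]) && nzchar(ids[k])) ids[k] else sprintf("record_%d", k)
    mol <- tryCatch(.mol_from_chemmine(sdfset[[k]], id, use_coords = TRUE),
                    error = function(e) {
                      message(sprintf("skipping record %d (%s): %s",
                                      k, id, conditionMessage(e)))
                      NULL
                    })
    if (is.null(mol)) { failed <- failed + 1L; next }
    if (is.null(mol$coords) && nrow(mol$atoms) >= 2) no_geom <- c(no_geom, id)
    out[[length(out) + 1L]] <- mol
  }
  if (!length(out)) stop(sprintf("no parseable records in '%s'", path))
  if (failed) message(sprintf("%d of %d records skipped", failed, n))
  attr(out, "n_failed") <- failed
  attr(out, "no_geometry") <- no_geom
  out
}

#' Write molecules to an SDF file
#'
#' @param mols list of molecules created by [parse_smiles()] or [read_sdf()].
#' @param path output file.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  sdfs <- lapply(mols, function(m) {
    if (is.null(m$sdf)) stop(sprintf("molecule %s has no structure record", m$id))
    m$sdf
  })
  ids <- vapply(mols, function(m) m$id, "")
  ChemmineR::write.SDF(methods::new("SDFset", SDF = sdfs, ID = ids), file = path)
  invisible(path)
}

#' Hydrogen-depleted molecular graph with topological distances
#'
#' Drops hydrogens and computes all-pairs shortest-path bond counts
#' (topological distances) on the remaining heavy-atom graph.  Distances
#' between disconnected fragments are `Inf`.
#'
#' @param mol a `"molecule"`.
#' @return An object of class `"heavy_graph"`: list with `nodes` (indices of
#'   the heavy atoms in `mol`), `elements`, `adjacency` (logical matrix) and
#'   `topo_dist` (numeric matrix of bond counts).
#' @export
heavy_graph <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  heavy <- which(mol$atoms$element != "H")
  if (!length(heavy)) stop("molecule has no heavy atoms")
  a <- length(heavy)
  remap <- match(seq_len(nrow(mol$atoms)), heavy)
  adj <- matrix(FALSE, a, a)
  b <- mol$bonds
  keep <- b$i %in% heavy & b$j %in% heavy
  if (any(keep)) {
    ii <- remap[b$i[keep]]; jj <- remap[b$j[keep]]
    adj[cbind(ii, jj)] <- TRUE
    adj[cbind(jj, ii)] <- TRUE
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  d <- igraph::distances(g)
  dimnames(d) <- NULL
  structure(list(nodes = heavy, elements = mol$atoms$element[heavy],
                 adjacency = adj, topo_dist = d),
            class = "heavy_graph")
}

#' @export
print.heavy_graph <- function(x, ...) {
  cat(sprintf("<heavy_graph: %d nodes, %d edges>\n",
              length(x$nodes), sum(x$adjacency) / 2))
  invisible(x)
}

#' Keep the largest heavy-atom fragment
#'
#' Dragon-class descriptors assume a connected graph; multi-fragment
#' structures (salts, mixtures) are reduced to their largest heavy-atom
#' component with a warning.
#'
#' @param mol a `"molecule"`.
#' @return A connected `"molecule"` (possibly `mol` unchanged).
#' @export
largest_fragment <- function(mol) {
  comp <- .components(mol$bonds, nrow(mol$atoms))
  heavy <- mol$atoms$element != "H"
  sizes <- tapply(heavy, comp, sum)
  if (length(sizes) <= 1) return(mol)
  warning(sprintf("molecule %s has %d fragments; keeping the largest (%d heavy atoms)",
                  mol$id, length(sizes), max(sizes)))
  keep_comp <- as.integer(names(sizes)[which.max(sizes)])
  keep <- which(comp == keep_comp)
  remap <- match(seq_len(nrow(mol$atoms)), keep)
  b <- mol$bonds[mol$bonds$i %in% keep & mol$bonds$j %in% keep, , drop = FALSE]
  b$i <- remap[b$i]; b$j <- remap[b$j]
  rings <- lapply(mol$rings, function(r) remap[r])
  rings <- rings[!vapply(rings, anyNA, TRUE)]
  out <- molecule(mol$id, mol$atoms[keep, , drop = FALSE], b,
                  coords = if (is.null(mol$coords)) NULL else mol$coords[keep, , drop = FALSE],
                  rings = rings)
  out$smiles <- mol$smiles
  out
}

#' Convert an LD50 dose to the log(1/C) toxicity response
#'
#' The oral-rat LD50 in mg/kg is converted to a molar dose C in mmol/kg
#' (`ld50 / mw` is numerically mmol/kg) and returned as the negative decadic
#' logarithm, so larger values mean higher toxicity.
#'
#' @param ld50 lethal dose, mg/kg (> 0); vectorized.
#' @param mw molecular weight, g/mol (> 0); vectorized.
#' @return `-log10(ld50 / mw)`, dimensionless.
#' @examples
#' log_inv_c(500, 250)   # -log10(2)
#' @export
log_inv_c <- function(ld50, mw) {
  if (any(!is.finite(ld50)) || any(ld50 <= 0)) stop("ld50 must be positive")
  if (any(!is.finite(mw)) || any(mw <= 0)) stop("mw must be positive")
  -log10(ld50 / mw)
}

#' Assemble a toxicity record table
#'
#' @param id compound labels.
#' @param ld50 LD50 values, mg/kg.
#' @param mw molecular weights, g/mol.
#' @return data frame with columns `id`, `ld50_mg_kg`, `mw`, `log_inv_c`.
#' @export
toxicity_records <- function(id, ld50, mw) {
  stopifnot(length(id) == length(ld50), length(ld50) == length(mw))
  data.frame(id = as.character(id), ld50_mg_kg = ld50, mw = mw,
             log_inv_c = log_inv_c(ld50, mw), stringsAsFactors = FALSE)
}

#' Molecular weight of a molecule
#'
#' Sum of atomic masses including implicit hydrogens.
#'
#' @param mol a `"molecule"`.
#' @return mass in g/mol.
#' @export
mol_weight <- function(mol) {
  impl <- if ("nH_impl" %in% names(mol$atoms)) mol$atoms$nH_impl else mol$atoms$nH
  sum(mol$atoms$mass) + sum(impl) * .ATOMIC_MASS[["H"]]
}
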