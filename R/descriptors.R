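# Structural, topological and geometric descriptors of the ten-variable
# carbamate toxicity model: LOC, SpPosA_RG, H4m, nCt, nROCON, B05[C-N],
# B05[N-O], DLS_05, plus the Unsat / Unsat-p / nNO / nC3 auxiliaries that
# feed the drug-like score.

#' Lopping centric index
#'
#' Entropy of the partition of heavy atoms by terminal-vertex pruning round:
#' degree-1 vertices are removed ("lopped") in simultaneous rounds; round r
#' contributes a class of size n_r, and the surviving core (a cycle system,
#' or the last 1-2 vertices of a path) forms the final class.  The index is
#' \eqn{-\sum_g (n_g/A) \log_2 (n_g/A)} with A the heavy-atom count, in bits.
#'
#' @param g a [heavy_graph()].
#' @return non-negative scalar, bounded by `log2(A)`.
#' @examples
#' loc_index(heavy_graph(parse_smiles("CCCC")))  # path of 4: classes {2,2} -> 1 bit
#' @export
loc_index <- function(g) {
  stopifnot(inherits(g, "heavy_graph"))
  a <- length(g$nodes)
  if (a == 0) stop("empty graph")
  if (any(!is.finite(g$topo_dist))) stop("graph is disconnected; lop the largest fragment first")
  alive <- rep(TRUE, a)
  adj <- g$adjacency
  classes <- integer(0)
  repeat {
    deg <- rowSums(adj[, alive, drop = FALSE])[alive]
    leaves <- which(alive)[deg == 1]
    if (!length(leaves)) break
    classes <- c(classes, length(leaves))
    alive[leaves] <- FALSE
  }
  if (any(alive)) classes <- c(classes, sum(alive))
  p <- classes / a
  -sum(p * log2(p))
}

.is_sp3_carbon <- function(mol) {
  n <- nrow(mol$atoms)
  sp3 <- mol$atoms$element == "C" & !mol$atoms$aromatic
  if (nrow(mol$bonds)) {
    multi <- mol$bonds$order >= 2 | mol$bonds$aromatic
    bad <- unique(c(mol$bonds$i[multi], mol$bonds$j[multi]))
    sp3[bad] <- FALSE
  }
  sp3
}

.neighbors <- function(mol, a) {
  b <- mol$bonds
  c(b$j[b$i == a], b$i[b$j == a])
}

#' Count of tertiary sp3 carbons (nCt)
#'
#' Number of sp3 carbons bonded to exactly three carbon atoms and one
#' hydrogen.
#'
#' @param mol a `"molecule"`.
#' @return non-negative integer.
#' @export
nct <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  sp3 <- .is_sp3_carbon(mol)
  cnt <- 0L
  for (a in which(sp3)) {
    nb <- .neighbors(mol, a)
    n_c <- sum(mol$atoms$element[nb] == "C")
    n_h <- mol$atoms$nH[a]  # nH already counts implicit + explicit hydrogens
    heavy_deg <- sum(mol$atoms$element[nb] != "H")
    if (n_c == 3L && n_h == 1L && heavy_deg == 3L) cnt <- cnt + 1L
  }
  cnt
}

# Locate carbamate groups: carbonyl carbon with C=O, C-N and C-O(ester).
# Returns a list of lists (c_carbonyl, o_ester, n) of atom indices.
.carbamate_groups <- function(mol) {
  out <- list()
  b <- mol$bonds
  for (a in which(mol$atoms$element == "C")) {
    nb_i <- which((b$i == a | b$j == a))
    if (!length(nb_i)) next
    other <- ifelse(b$i[nb_i] == a, b$j[nb_i], b$i[nb_i])
    ord <- b$order[nb_i]
    has_co_double <- any(mol$atoms$element[other] == "O" & ord == 2)
    n_single <- other[mol$atoms$element[other] == "N" & ord == 1]
    o_single <- other[mol$atoms$element[other] == "O" & ord == 1]
    if (has_co_double && length(n_single) && length(o_single)) {
      for (o in o_single) for (nn in n_single)
        out[[length(out) + 1L]] <- list(c_carbonyl = a, o_ester = o, n = nn)
    }
  }
  out
}

#' Aliphatic O-substituent flag of the carbamate group (nROCON)
#'
#' 1 if the molecule contains a C-O-C(=O)-N fragment in which the carbon
#' bonded to the sp3 (ester-type) oxygen is a non-aromatic, aliphatic
#' carbon; 0 otherwise (O-aryl carbamates, carbamic acids, non-carbamates).
#'
#' @param mol a `"molecule"`.
#' @return 0 or 1.
#' @examples
#' nrocon(parse_smiles("CNC(=O)OC"))         # O-methyl: 1
#' nrocon(parse_smiles("CNC(=O)Oc1ccccc1"))  # O-phenyl: 0
#' @export
nrocon <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  for (grp in .carbamate_groups(mol)) {
    nb <- .neighbors(mol, grp$o_ester)
    subst <- setdiff(nb, grp$c_carbonyl)
    for (s in subst) {
      if (mol$atoms$element[s] == "C" && !mol$atoms$aromatic[s]) return(1L)
    }
  }
  0L
}

#' Atom-pair presence at topological distance five (B05)
#'
#' 1 if some atom of element `elem_a` and some atom of element `elem_b` lie
#' at a shortest-path distance of exactly five bonds in the heavy-atom
#' graph, else 0.
#'
#' @param g a [heavy_graph()].
#' @param elem_a,elem_b element symbols, e.g. `"C"`, `"N"`.
#' @param lag bond distance (default 5).
#' @return 0 or 1.
#' @export
b05_pair <- function(g, elem_a, elem_b, lag = 5L) {
  stopifnot(inherits(g, "heavy_graph"))
  ia <- which(g$elements == elem_a)
  ib <- which(g$elements == elem_b)
  if (!length(ia) || !length(ib)) return(0L)
  d <- g$topo_dist[ia, ib, drop = FALSE]
  as.integer(any(d == lag))
}

#' Unsaturation breakdown and drug-likeness auxiliaries
#'
#' Computes the unsaturation index
#' \deqn{Unsat = NRG_{567} + nDB + 2\,nTB + (nAB + 1)/2}
#' where NRG567 counts 5-, 6- and 7-membered rings of the smallest set of
#' smallest rings, nDB/nTB count non-aromatic double/triple bonds and nAB
#' counts aromatic bonds.  By default the final term is taken as 0 for
#' molecules with no aromatic bonds (a saturated molecule has zero
#' unsaturation); `unsat_literal = TRUE` restores the printed formula, which
#' assigns (0+1)/2 = 0.5 in that case.  Also returns Unsat-p (Unsat divided
#' by the number of non-halogen heavy atoms carrying no hydrogens), nNO
#' (N + O count) and nC3 (sp3 carbon count).
#'
#' @param mol a `"molecule"`.
#' @param unsat_literal use the literal (nAB+1)/2 term even when nAB = 0.
#' @return list with fields `nrg567`, `nDB`, `nTB`, `nAB`, `unsat`,
#'   `unsat_p` (NA when its denominator is 0), `nNO`, `nC3`.
#' @export
unsat_breakdown <- function(mol, unsat_literal = FALSE) {
  stopifnot(inherits(mol, "molecule"))
  sizes <- vapply(mol$rings, length, 1L)
  nrg567 <- sum(sizes %in% 5:7)
  b <- mol$bonds
  nDB <- sum(b$order == 2 & !b$aromatic)
  nTB <- sum(b$order == 3 & !b$aromatic)
  nAB <- sum(b$aromatic)
  term <- if (nAB == 0 && !unsat_literal) 0 else (nAB + 1) / 2
  unsat <- nrg567 + nDB + 2 * nTB + term
  heavy <- mol$atoms$element != "H"
  denom <- sum(heavy & !(mol$atoms$element %in% .HALOGENS) & mol$atoms$nH == 0)
  unsat_p <- if (denom > 0) unsat / denom else NA_real_
  nNO <- sum(mol$atoms$element %in% c("N", "O"))
  nC3 <- sum(.is_sp3_carbon(mol))
  list(nrg567 = nrg567, nDB = nDB, nTB = nTB, nAB = nAB, unsat = unsat,
       unsat_p = unsat_p, nNO = nNO, nC3 = nC3)
}

#' Fifth drug-like score (DLS_05)
#'
#' Fraction of two drug-likeness rules satisfied: (i) the heteroatom ratio
#' nNO/nC3 lies in the inclusive range 0.10-1.80; (ii) Unsat-p <= 0.43.
#' A rule whose quantity is undefined (nC3 = 0, or an empty Unsat-p
#' denominator) counts as unsatisfied.
#'
#' @inheritParams unsat_breakdown
#' @return 0, 0.5 or 1.
#' @export
dls05 <- function(mol, unsat_literal = FALSE) {
  u <- unsat_breakdown(mol, unsat_literal = unsat_literal)
  rule1 <- if (u$nC3 > 0) {
    ratio <- u$nNO / u$nC3
    ratio >= 0.10 && ratio <= 1.80
  } else FALSE
  rule2 <- if (!is.na(u$unsat_p)) u$unsat_p <= 0.43 else FALSE
  (rule1 + rule2) / 2
}

.heavy_coords <- function(mol, include_h = FALSE) {
  if (is.null(mol$coords)) stop(sprintf("molecule %s has no 3D coordinates", mol$id))
  sel <- if (include_h) seq_len(nrow(mol$atoms)) else which(mol$atoms$element != "H")
  list(idx = sel, xyz = mol$coords[sel, , drop = FALSE])
}

#' Normalized positive spectral sum of the reciprocal squared geometry matrix
#'
#' Builds the symmetric matrix G with off-diagonal entries
#' \eqn{1/r_{ij}^2} (interatomic distances in Angstrom) and zero diagonal
#' over the chosen atom set, and returns the sum of its strictly positive
#' eigenvalues divided by the atom count (SpPosA_RG).
#'
#' @param mol a `"molecule"` with 3D coordinates.
#' @param include_h include hydrogens in the atom set (default heavy only).
#' @return non-negative scalar.
#' @export
sp_pos_a_rg <- function(mol, include_h = FALSE) {
  stopifnot(inherits(mol, "molecule"))
  hc <- .heavy_coords(mol, include_h)
  a <- nrow(hc$xyz)
  if (a < 2) stop("need at least 2 atoms for a geometry matrix")
  d <- as.matrix(stats::dist(hc$xyz))
  if (any(d[upper.tri(d)] < 1e-6)) stop("coincident atomic positions")
  g <- 1 / d^2
  diag(g) <- 0
  ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
  pos <- ev[ev > 1e-10 * max(abs(ev))]
  sum(pos) / a
}

#' GETAWAY H autocorrelation of lag 4, mass-weighted (H4m)
#'
#' Centers the atom-set coordinate matrix M, forms the molecular influence
#' matrix \eqn{H = M (M'M)^{-1} M'} (pseudo-inverse for planar or linear
#' geometries), and sums \eqn{H_{ij} w_i w_j} over unordered atom pairs at
#' topological distance 4 with positive H entries, using carbon-scaled
#' atomic masses \eqn{w_i = m_i / m_C} as weights.  Molecules with fewer
#' than five atoms in the set have no lag-4 pairs and score 0.
#'
#' @param mol a `"molecule"` with 3D coordinates.
#' @param include_h include hydrogens in the atom set and in the
#'   topological distances (default heavy atoms only).
#' @param lag topological distance of the autocorrelation (default 4).
#' @return non-negative scalar.
#' @export
h4m <- function(mol, include_h = FALSE, lag = 4L) {
  stopifnot(inherits(mol, "molecule"))
  hc <- .heavy_coords(mol, include_h)
  a <- nrow(hc$xyz)
  if (a <= lag) return(0)
  H <- influence_matrix(hc$xyz)
  # topological distances on the same atom set
  d <- .atomset_topo_dist(mol, hc$idx)
  w <- mol$atoms$mass[hc$idx] / .ATOMIC_MASS[["C"]]
  total <- 0
  for (i in seq_len(a - 1)) for (j in (i + 1):a) {
    if (is.finite(d[i, j]) && d[i, j] == lag && H[i, j] > 0)
      total <- total + H[i, j] * w[i] * w[j]
  }
  total
}

#' Molecular influence (leverage) matrix of a centered coordinate set
#'
#' @param xyz numeric matrix (atoms x 3) of Cartesian coordinates.
#' @return the symmetric projection matrix H = M (M'M)^- M' of the centered
#'   coordinates; its trace equals the rank of M (3 for non-planar
#'   geometries) and its diagonal entries lie in [0, 1].
#' @export
influence_matrix <- function(xyz) {
  m <- scale(as.matrix(xyz), center = TRUE, scale = FALSE)
  mtm <- crossprod(m)
  inv <- tryCatch(solve(mtm), error = function(e) NULL)
  if (is.null(inv) || rcond(mtm) < 1e-12) {
    # planar / linear geometry: Moore-Penrose pseudo-inverse
    s <- svd(mtm)
    keep <- s$d > 1e-10 * max(s$d)
    inv <- s$v[, keep, drop = FALSE] %*%
      diag(1 / s$d[keep], sum(keep)) %*% t(s$u[, keep, drop = FALSE])
  }
  m %*% inv %*% t(m)
}

# Shortest-path distances restricted to an atom subset, measured on the
# bond graph of that subset.
.atomset_topo_dist <- function(mol, idx) {
  remap <- match(seq_len(nrow(mol$atoms)), idx)
  a <- length(idx)
  adj <- matrix(FALSE, a, a)
  b <- mol$bonds
  keep <- b$i %in% idx & b$j %in% idx
  if (any(keep)) {
    ii <- remap[b$i[keep]]; jj <- remap[b$j[keep]]
    adj[cbind(ii, jj)] <- TRUE; adj[cbind(jj, ii)] <- TRUE
  }
  igraph::distances(igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
}

#' Assemble the model descriptor table
#'
#' Computes the eight structural descriptors for each molecule and joins the
#' externally supplied electronic data (EA, qC), yielding one row per
#' compound in the fixed column order EA, qC, LOC, SpPosA_RG, H4m, nCt,
#' nROCON, B05_CN, B05_NO, DLS_05.  Multi-fragment structures are reduced to
#' their largest fragment (with a warning).  Geometric descriptors of
#' molecules without 3D coordinates are `NA`, never silent zeros.
#'
#' @param mols list of `"molecule"` objects.
#' @param electronic data frame with columns `id`, `EA` (eV) and `qC`
#'   (elementary charges), one row per molecule id.
#' @param unsat_literal,getaway_include_h,sppos_include_h convention flags,
#'   see [unsat_breakdown()], [h4m()], [sp_pos_a_rg()].
#' @return data frame of class `"descriptor_table"` with columns `id` and
#'   the ten model descriptors.
#' @export
compute_descriptor_table <- function(mols, electronic,
                                     unsat_literal = FALSE,
                                     getaway_include_h = FALSE,
                                     sppos_include_h = FALSE) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  ids <- vapply(mols, function(m) m$id, "")
  missing_ids <- setdiff(ids, electronic$id)
  if (length(missing_ids))
    stop("no electronic data for: ", paste(missing_ids, collapse = ", "))
  rows <- lapply(mols, function(m) {
    m <- suppressWarnings(largest_fragment(m))
    g <- heavy_graph(m)
    has3d <- !is.null(m$coords)
    data.frame(
      id = m$id,
      EA = electronic$EA[match(m$id, electronic$id)],
      qC = electronic$qC[match(m$id, electronic$id)],
      LOC = loc_index(g),
      SpPosA_RG = if (has3d) sp_pos_a_rg(m, include_h = sppos_include_h) else NA_real_,
      H4m = if (has3d) h4m(m, include_h = getaway_include_h) else NA_real_,
      nCt = nct(m),
      nROCON = nrocon(m),
      B05_CN = b05_pair(g, "C", "N"),
      B05_NO = b05_pair(g, "N", "O"),
      DLS_05 = dls05(m, unsat_literal = unsat_literal),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("descriptor_table", "data.frame")
  out
}

#' Write a descriptor table to CSV
#'
#' Serializes with the canonical header
#' `id,set,log_inv_c,EA,qC,LOC,SpPosA_RG,H4m,nCt,nROCON,B05_CN,B05_NO,DLS_05`
#' (`set` and `log_inv_c` included when present); missing values become
#' empty cells.
#'
#' @param x a descriptor table.
#' @param path output file.
#' @export
write_descriptor_csv <- function(x, path) {
  lead <- intersect(c("id", "set", "log_inv_c"), names(x))
  cols <- c(lead, c("EA", "qC", "LOC", "SpPosA_RG", "H4m", "nCt", "nROCON",
                    "B05_CN", "B05_NO", "DLS_05"))
  utils::write.csv(x[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}
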