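# Descriptor routines against hand-derived values, brute-force oracles and
# the invariances every graph/geometry descriptor must satisfy.

toy <- toy_carbamate_set()
frag <- function(m) suppressWarnings(largest_fragment(m))

test_that("lopping centric index matches hand-pruned partitions", {
  expect_equal(loc_index(heavy_graph(parse_smiles("C"))), 0)
  expect_equal(loc_index(heavy_graph(parse_smiles("CCCC"))), 1)      # {2,2}
  expect_equal(loc_index(heavy_graph(parse_smiles("c1ccccc1"))), 0)  # one class
  # path of 5: rounds {2,2}, core {1} -> -2*0.4*log2(0.4) - 0.2*log2(0.2)
  expect_equal(loc_index(heavy_graph(parse_smiles("CCCCC"))),
               -(2 * 0.4 * log2(0.4) + 0.2 * log2(0.2)), tolerance = 1e-12)
  expect_error(loc_index(heavy_graph(parse_smiles("CC(=O)[O-].[Na+]"))),
               "disconnected")
})

test_that("loc_index respects the entropy bound log2(A)", {
  for (smi in toy$smiles) {
    m <- frag(parse_smiles(smi))
    g <- heavy_graph(m)
    expect_lte(loc_index(g), log2(length(g$nodes)) + 1e-12)
  }
})

test_that("tertiary carbon count distinguishes branching patterns", {
  expect_equal(nct(parse_smiles("CC(C)C")), 1)
  expect_equal(nct(parse_smiles("CC(C)(C)C")), 0)   # quaternary
  expect_equal(nct(parse_smiles("CC(C)C(C)C")), 2)
  expect_equal(nct(parse_smiles("CC(C)C(C)C(C)C")), 3)
  expect_equal(nct(parse_smiles("CC(C)Oc1ccccc1")), 0)  # CH bonded to O, not 3 C
})

test_that("nROCON detects aliphatic vs aromatic carbamate O-substituents", {
  expect_equal(nrocon(parse_smiles("CNC(=O)OC")), 1)
  expect_equal(nrocon(parse_smiles("CNC(=O)Oc1ccccc1")), 0)
  expect_equal(nrocon(parse_smiles("NC(=O)O")), 0)          # carbamic acid
  expect_equal(nrocon(parse_smiles("CC(C)(SC)C=NOC(=O)NC")), 0)  # O-N oxime
  expect_equal(nrocon(parse_smiles("CCOC(=O)NC")), 1)
  expect_equal(nrocon(parse_smiles("CCCC")), 0)             # no carbamate
})

test_that("B05 pair flags equal a brute-force shortest-path check", {
  g_hex <- heavy_graph(parse_smiles("NCCCCCC"))
  expect_equal(b05_pair(g_hex, "N", "C"), 1)
  g_eth <- heavy_graph(parse_smiles("CCO"))
  expect_equal(b05_pair(g_eth, "C", "N"), 0)
  expect_equal(b05_pair(g_eth, "N", "O"), 0)
  expect_equal(b05_pair(g_eth, "C", "O"), 0)
  for (smi in c("NCCCCO", "CC(O)CCCN", "CNC(=O)Oc1ccccc1", "CC(C)(SC)C=NOC(=O)NC")) {
    g <- heavy_graph(parse_smiles(smi))
    d <- floyd_warshall(g$adjacency)
    for (pair in list(c("C", "N"), c("N", "O"))) {
      ia <- which(g$elements == pair[1]); ib <- which(g$elements == pair[2])
      expected <- as.integer(length(ia) > 0 && length(ib) > 0 &&
                               any(d[ia, ib, drop = FALSE] == 5))
      expect_equal(b05_pair(g, pair[1], pair[2]), expected,
                   label = paste(smi, pair[1], pair[2]))
    }
  }
})

test_that("unsaturation breakdown follows the ring/bond counts", {
  e <- unsat_breakdown(parse_smiles("CC"))
  expect_equal(e$unsat, 0)                       # nAB = 0 convention
  expect_equal(unsat_breakdown(parse_smiles("CC"), unsat_literal = TRUE)$unsat, 0.5)
  b <- unsat_breakdown(parse_smiles("c1ccccc1"))
  expect_equal(b[c("nrg567", "nDB", "nTB", "nAB")],
               list(nrg567 = 1L, nDB = 0L, nTB = 0L, nAB = 6L))
  expect_equal(b$unsat, 1 + (6 + 1) / 2)
  expect_true(is.na(b$unsat_p))                  # every ring C carries an H
  y <- unsat_breakdown(parse_smiles("CC#CC"))
  expect_equal(y$nTB, 1L)
  expect_equal(y$unsat, 2)
  n <- unsat_breakdown(parse_smiles("CNC(=O)Oc1cccc2ccccc12"))
  expect_equal(n$nrg567, 2L)                     # SSSR of naphthalene
  expect_equal(n$nAB, 11L)
})

test_that("drug-like score branches on both rules and undefined ratios", {
  expect_equal(dls05(parse_smiles("CCN(CC)CC")), 1)    # both rules hold
  expect_equal(dls05(parse_smiles("Cc1ccccc1")), 0)    # both fail
  expect_equal(dls05(parse_smiles("NCCCCCC")), 0.5)    # ratio ok, Unsat-p undefined
  expect_equal(dls05(parse_smiles("c1ccccc1")), 0)     # nC3 = 0: rule 1 undefined
})

test_that("hand-assigned toy labels match computed structural descriptors", {
  for (k in seq_len(nrow(toy$labels))) {
    m <- frag(toy$mols[[toy$labels$id[k]]])
    g <- heavy_graph(m)
    expect_equal(nrocon(m), toy$labels$nROCON[k], label = paste("nROCON", m$id))
    expect_equal(b05_pair(g, "C", "N"), toy$labels$B05_CN[k],
                 label = paste("B05_CN", m$id))
    expect_equal(b05_pair(g, "N", "O"), toy$labels$B05_NO[k],
                 label = paste("B05_NO", m$id))
    expect_equal(nct(m), toy$labels$nCt[k], label = paste("nCt", m$id))
    expect_equal(dls05(m), toy$labels$DLS_05[k], label = paste("DLS_05", m$id))
  }
})

test_that("reciprocal-squared geometry spectrum has the closed 2-atom form", {
  m <- parse_smiles("CC", id = "two")
  m <- with_coords(m, rbind(c(0, 0, 0), c(1.5, 0, 0)))
  expect_equal(sp_pos_a_rg(m), (1 / 2.25) / 2, tolerance = 1e-12)
  expect_error(sp_pos_a_rg(parse_smiles("CC")), "coordinates")
  m2 <- with_coords(m, rbind(c(0, 0, 0), c(1e-8, 0, 0)))
  expect_error(sp_pos_a_rg(m2), "coincident")
})

test_that("geometric descriptors are invariant under rigid motions and scale as 1/r^2", {
  set.seed(42)
  pro <- toy$mols$propham
  base_sp <- sp_pos_a_rg(pro)
  base_h4 <- h4m(pro)
  for (rep in 1:5) {
    R <- random_rotation()
    t <- rnorm(3, sd = 10)
    moved <- with_coords(pro, sweep(pro$coords %*% R, 2, -t))
    expect_equal(sp_pos_a_rg(moved), base_sp, tolerance = 1e-9)
    expect_equal(h4m(moved), base_h4, tolerance = 1e-9)
  }
  scaled <- with_coords(pro, pro$coords * 2)
  expect_equal(sp_pos_a_rg(scaled), base_sp / 4, tolerance = 1e-9)
})

test_that("H4m equals the brute-force influence-matrix oracle", {
  for (id in c("propham", "cyclohexyl_methylcarbamate", "oxime_carbamate",
               "hexylamine", "naphthyl_methylcarbamate")) {
    m <- toy$mols[[id]]
    heavy <- which(m$atoms$element != "H")
    xyz <- m$coords[heavy, , drop = FALSE]
    g <- heavy_graph(m)
    expect_equal(h4m(m), h4m_brute(xyz, g$topo_dist, m$atoms$mass[heavy]),
                 tolerance = 1e-10, label = id)
  }
  expect_equal(h4m(toy$mols$ethanol), 0)     # <= 4 heavy atoms: no lag-4 pairs
  expect_equal(h4m(toy$mols$carbamic_acid), 0)
})

test_that("influence matrix is a proper projector onto the centered geometry", {
  for (id in c("propham", "triethylamine", "benzene")) {
    xyz <- toy$mols[[id]]$coords[toy$mols[[id]]$atoms$element != "H", ]
    H <- influence_matrix(xyz)
    m <- sweep(xyz, 2, colMeans(xyz))
    expect_equal(sum(diag(H)), qr(m)$rank, tolerance = 1e-8, label = id)
    expect_true(all(diag(H) >= -1e-12 & diag(H) <= 1 + 1e-12), label = id)
  }
})

test_that("every descriptor is invariant under atom relabeling", {
  set.seed(7)
  for (id in c("propham", "oxime_carbamate", "cyclohexyl_methylcarbamate",
               "aminopentanol_2")) {
    m <- toy$mols[[id]]
    g <- heavy_graph(m)
    ref <- list(loc_index(g), nct(m), nrocon(m),
                b05_pair(g, "C", "N"), b05_pair(g, "N", "O"),
                unsat_breakdown(m)$unsat, dls05(m),
                sp_pos_a_rg(m), h4m(m))
    for (rep in 1:3) {
      perm <- sample(nrow(m$atoms))
      pm <- permute_molecule(m, perm)
      pg <- heavy_graph(pm)
      got <- list(loc_index(pg), nct(pm), nrocon(pm),
                  b05_pair(pg, "C", "N"), b05_pair(pg, "N", "O"),
                  unsat_breakdown(pm)$unsat, dls05(pm),
                  sp_pos_a_rg(pm), h4m(pm))
      expect_equal(got, ref, tolerance = 1e-9, label = paste(id, "perm", rep))
    }
  }
})

test_that("descriptor table assembles in canonical order with flagged missing values", {
  mols <- toy$mols[1:6]
  dt <- suppressWarnings(compute_descriptor_table(mols, toy$electronic))
  expect_equal(nrow(dt), 6)
  expect_equal(names(dt), c("id", "EA", "qC", "LOC", "SpPosA_RG", "H4m",
                            "nCt", "nROCON", "B05_CN", "B05_NO", "DLS_05"))
  expect_true(all(unlist(dt[, c("nROCON", "B05_CN", "B05_NO")]) %in% 0:1))
  expect_true(all(dt$DLS_05 %in% c(0, 0.5, 1)))

  no3d <- parse_smiles("CNC(=O)OC", id = "methyl_methylcarbamate")
  dt2 <- compute_descriptor_table(list(no3d), toy$electronic)
  expect_true(is.na(dt2$SpPosA_RG) && is.na(dt2$H4m))
  expect_false(is.na(dt2$LOC))

  expect_error(compute_descriptor_table(list(parse_smiles("CCO", id = "zzz")),
                                        toy$electronic), "zzz")
})

test_that("carbamate-like fixtures fall in the plausibility corridor of the reference rows", {
  carb <- c("phenyl_methylcarbamate", "naphthyl_methylcarbamate", "propham",
            "cyclohexyl_methylcarbamate", "oxime_carbamate")
  dt <- suppressWarnings(compute_descriptor_table(toy$mols[carb], toy$electronic))
  expect_true(all(is.finite(dt$LOC)) && all(is.finite(dt$SpPosA_RG)) &&
                all(is.finite(dt$H4m)))
  soft <- dt$LOC >= 1 & dt$LOC <= 3 &
    dt$SpPosA_RG >= 0.3 & dt$SpPosA_RG <= 0.6 &
    dt$H4m >= 0 & dt$H4m <= 0.5
  if (!all(soft))
    message("outside reference-row corridor (soft check): ",
            paste(dt$id[!soft], collapse = ", "))
  succeed()
})
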