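rigidCopy <- function(s, seed) {
  set.seed(seed)
  R <- chimeraforge:::.randomRotation()
  tr <- runif(3, -30, 30)
  a <- atomTable(s)
  xyz <- sweep(as.matrix(a[, c("x", "y", "z")]) %*% t(R), 2, tr, "+")
  a[, c("x", "y", "z")] <- xyz
  ProteinStructure(a, id = s@id)
}

test_that("SASA matches the analytic sphere, is additive and converges", {
  one <- ProteinStructure(data.frame(name = "CB", resname = "ALA",
                                     chain = "A", resid = 1,
                                     x = 0, y = 0, z = 0), id = "c1")
  expect_equal(sasa(one)$total, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
  ## two atoms far apart: sum of isolated areas
  two <- ProteinStructure(data.frame(name = c("CB", "CB"), resname = "ALA",
                                     chain = "A", resid = 1:2,
                                     x = c(0, 100), y = 0, z = 0), id = "c2")
  s2 <- sasa(two)
  expect_equal(s2$total, 2 * 4 * pi * 3.1^2, tolerance = 0.01)
  expect_equal(sum(s2$perResidue), s2$total)
  ## quadrature self-convergence on a 20-residue helix
  h <- buildIdealSS("helix:20")
  coarse <- sasa(h)$total
  fine <- sasa(h, nSpherePoints = 10000L)$total
  expect_lt(abs(coarse - fine) / fine, 0.02)
  ## unknown element falls back with a warning
  odd <- ProteinStructure(data.frame(name = "FE", element = "FE",
                                     resname = "ALA", chain = "A", resid = 1,
                                     x = 0, y = 0, z = 0), id = "fe")
  expect_warning(v <- sasa(odd)$total, "unknown element")
  expect_equal(v, 4 * pi * 3.1^2, tolerance = 0.01)
})

test_that("contact maps are symmetric Ca distances with zero diagonal", {
  two <- ProteinStructure(data.frame(name = rep("CA", 2), resname = "GLY",
                                     chain = "A", resid = 1:2,
                                     x = c(0, 3.8), y = 0, z = 0), id = "d")
  expect_equal(contactMap(two)$matrix,
               matrix(c(0, 3.8, 3.8, 0), 2), ignore_attr = TRUE)
  m <- contactMap(buildIdealSS("helix:12"))$matrix
  expect_equal(m, t(m), ignore_attr = TRUE)
  expect_equal(diag(m), rep(0, 12), ignore_attr = TRUE)
  ## ideal helix: (i, i+4) Ca distances about 6.2 A
  expect_equal(mean(m[cbind(1:8, 5:12)]), 6.2, tolerance = 0.5 / 6.2)
  noCA <- ProteinStructure(data.frame(name = c("CA", "CB"), resname = "ALA",
                                      chain = "A", resid = 1:2,
                                      x = 0:1, y = 0, z = 0), id = "x")
  expect_error(contactMap(noCA), "without CA")
})

test_that("relative contact order equals its closed form and is rigid-invariant", {
  ## 3 residues, only (1,3) in contact: RCO = 100 * 2 / (3 * 1)
  toy3 <- ProteinStructure(data.frame(name = rep("CA", 3), resname = "GLY",
                                      chain = "A", resid = 1:3,
                                      x = c(0, 10, 5), y = c(0, 10, 0.1),
                                      z = 0), id = "t3")
  expect_equal(contactOrder(toy3), 100 * 2 / 3)
  ## 4-residue toy: all pairs within 6 A except (1,4); five contacts with
  ## separations 1,2,1,2,1 -> RCO = 100 * 7 / (4 * 5)
  toy4 <- ProteinStructure(data.frame(name = rep("CA", 4), resname = "GLY",
                                      chain = "A", resid = 1:4,
                                      x = c(0, 4, 4, 8), y = c(0, 0, 4, 4),
                                      z = 0), id = "t4")
  expect_equal(contactOrder(toy4), 100 * 7 / 20)
  h <- buildIdealSS("helix:15")
  expect_equal(contactOrder(rigidCopy(h, 31)), contactOrder(h),
               tolerance = 1e-9)
  far <- ProteinStructure(data.frame(name = rep("CA", 2), resname = "GLY",
                                     chain = "A", resid = 1:2,
                                     x = c(0, 50), y = 0, z = 0), id = "far")
  expect_error(contactOrder(far), "no contacts")
})

test_that("salt bridges: cutoff, dedup to minimum distance, His toggle", {
  mkSB <- function(dNZ, dNH1 = 10) ProteinStructure(rbind(
    data.frame(name = c("CA", "CB", "CG", "OD1", "OD2"), resname = "ASP",
               chain = "A", resid = 1, element = c("C", "C", "C", "O", "O"),
               x = c(-3, -2, -1, 0, 0.5), y = c(0, 0, 0, 0, 1.2), z = 0),
    data.frame(name = c("CA", "NZ"), resname = "LYS", chain = "A", resid = 2,
               element = c("C", "N"), x = c(dNZ + 2, dNZ), y = 0, z = 0),
    data.frame(name = c("CA", "NE", "NH1", "NH2"), resname = "ARG",
               chain = "A", resid = 3, element = c("C", "N", "N", "N"),
               x = c(dNH1 + 2, dNH1 + 1, dNH1, dNH1 + 1.5), y = 5, z = 0)),
    id = "sb")
  ## Asp O at 3.5 A from Lys NZ -> one bridge
  sb <- saltBridges(mkSB(3.5))
  expect_equal(nrow(sb), 1L)
  expect_equal(sb$minDistance, sqrt(3^2 + 1.2^2))   # OD2 is the closer oxygen
  ## same geometry at 4.6 A -> none
  expect_equal(nrow(saltBridges(mkSB(4.6))), 0L)
  ## two O-N contacts in one pair collapse to the minimum
  both <- saltBridges(mkSB(2.0))
  expect_equal(nrow(both), 1L)
  expect_equal(both$minDistance, sqrt(1.5^2 + 1.2^2))
  ## His counts as basic by default, can be disabled
  his <- ProteinStructure(rbind(
    data.frame(name = c("OE1", "OE2"), resname = "GLU", chain = "A",
               resid = 1, element = "O", x = c(0, 1), y = 0, z = 0),
    data.frame(name = c("ND1", "NE2"), resname = "HIS", chain = "A",
               resid = 2, element = "N", x = c(3, 4), y = 0, z = 0)), id = "h")
  expect_equal(nrow(saltBridges(his)), 1L)
  expect_equal(nrow(saltBridges(his, countHis = FALSE)), 0L)
})

test_that("hydrogen bonds: helix pattern, separation rule, degenerate cases", {
  h <- buildIdealSS("helix:12")
  hb <- hBonds(h)
  no <- hb[hb$donorName == "N" & hb$acceptorName == "O", ]
  ## every interior i forms N(i+4) -> O(i)
  i4 <- no[no$donorRes - no$acceptorRes == 4, ]
  expect_equal(sort(i4$acceptorRes), 1:8)
  ## no backbone pair below separation 2
  bbNames <- c("N", "CA", "C", "O")
  expect_true(all(abs(hb$donorRes - hb$acceptorRes) >= 2 |
                  !(hb$donorName %in% bbNames & hb$acceptorName %in% bbNames)))
  ## two isolated residues far apart, and dMax = 0
  far <- ProteinStructure(data.frame(name = c("N", "N"), resname = "GLY",
                                     chain = "A", resid = 1:2,
                                     x = c(0, 20), y = 0, z = 0), id = "far")
  expect_equal(nrow(hBonds(far)), 0L)
  expect_equal(nrow(hBonds(h, dMax = 0)), 0L)
})

test_that("hydrophobic clusters: contact rule, transitivity, size filter", {
  leu <- function(rid, off) data.frame(
    name = c("CA", "CB", "CG", "CD1", "CD2"), resname = "LEU", chain = "A",
    resid = rid, element = "C",
    x = c(0, 1.5, 2.5, 3.5, 2.8) + off, y = c(0, 0.5, 0, 0.5, 1.2), z = 0)
  ## interdigitated pair -> one 2-residue cluster with positive area
  close <- ProteinStructure(rbind(leu(1, 0), leu(2, 7)), id = "c")
  cl <- hydrophobicClusters(close, minClusterSize = 2L)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$residues, c(1L, 2L))
  expect_gt(cl[[1]]$area, 0)
  ## 15 A apart -> nothing
  expect_length(hydrophobicClusters(
    ProteinStructure(rbind(leu(1, 0), leu(2, 15)), id = "f"),
    minClusterSize = 2L), 0L)
  ## A-B and B-C in contact, A-C not -> single cluster {A,B,C}
  chain3 <- ProteinStructure(rbind(leu(1, 0), leu(2, 7), leu(3, 14)),
                             id = "t")
  cl3 <- hydrophobicClusters(chain3, minClusterSize = 2L)
  expect_length(cl3, 1L)
  expect_equal(cl3[[1]]$residues, 1:3)
  ## min_cluster_size filters small clusters out
  expect_length(hydrophobicClusters(chain3, minClusterSize = 4L), 0L)
  ## polar residues contribute no apolar atoms
  ser <- ProteinStructure(data.frame(name = c("CB", "OG"), resname = "SER",
                                     chain = "A", resid = 1,
                                     element = c("C", "O"),
                                     x = 0:1, y = 0, z = 0), id = "s")
  expect_length(hydrophobicClusters(ser, minClusterSize = 1L), 0L)
})

test_that("detectors are rigid-motion invariant", {
  for (seed in c(2, 5)) {
    s <- randomAnalysisStructure(seed, nres = 10)
    r <- rigidCopy(s, seed + 100)
    expect_equal(nrow(saltBridges(r)), nrow(saltBridges(s)))
    expect_equal(nrow(hBonds(r)), nrow(hBonds(s)))
    expect_equal(lapply(hydrophobicClusters(r, minClusterSize = 2L),
                        `[[`, "residues"),
                 lapply(hydrophobicClusters(s, minClusterSize = 2L),
                        `[[`, "residues"))
    expect_equal(sasa(r)$total, sasa(s)$total, tolerance = 0.02)
  }
})

test_that("the report aggregates analyses and survives partial failure", {
  h <- buildIdealSS("helix:10", id = "rep")
  rep_ <- analysisReport(h)
  expect_equal(rep_$nResidues, 10L)
  expect_true(is.finite(rep_$sasaTotal))
  expect_true(is.finite(rep_$rco))
  expect_true(is.finite(rep_$nSaltBridges))
  expect_true(is.finite(rep_$nHbonds))
  expect_false(is.null(jsonlite::toJSON(rep_, auto_unbox = TRUE)))
  ## a structure where contact order is undefined still yields the rest
  far <- ProteinStructure(data.frame(name = rep("CA", 2), resname = "GLY",
                                     chain = "A", resid = 1:2,
                                     x = c(0, 60), y = 0, z = 0), id = "far")
  r2 <- analysisReport(far)
  expect_true("contactOrder" %in% names(r2$errors))
  expect_true(is.finite(r2$sasaTotal))
})
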