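## Structural-analysis battery: SASA (Shrake-Rupley), contact maps, relative
## contact order, salt bridges, hydrogen bonds, hydrophobic clusters.

.heavyAtoms <- function(x) {
  a <- x@atoms
  a[toupper(a$element) != "H", , drop = FALSE]
}

#' Solvent accessible surface area (Shrake-Rupley)
#'
#' Sphere-sampling quadrature: each heavy atom is inflated by the probe
#' radius, covered with a deterministic quasi-uniform point set, and the
#' fraction of points not buried inside any neighbouring inflated sphere
#' gives its accessible area. Van der Waals radii: C 1.7, N 1.55, O 1.52,
#' S 1.8 Angstrom; unknown elements fall back to 1.7 with a warning.
#'
#' @param x a \linkS4class{ProteinStructure} (heavy atoms used).
#' @param probe probe radius, Angstrom (water = 1.4).
#' @param nSpherePoints quadrature points per atom; 960 gives ~1-2 percent
#'   accuracy, larger values converge further.
#' @return list with \code{total} (Angstrom^2) and \code{perResidue}
#'   (named numeric vector, one entry per residue index; their sum equals
#'   \code{total}).
#' @examples
#' sasa(buildIdealSS("helix:8"))$total
#' @export
sasa <- function(x, probe = 1.4, nSpherePoints = 960L) {
  a <- .heavyAtoms(x)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  r <- .vdwRadius(a$element) + probe
  pts <- .spherePoints(nSpherePoints)
  n <- nrow(a)
  area <- numeric(n)
  maxr <- max(r)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(d < r[i] + maxr & seq_len(n) != i)
    nb <- nb[d[nb] < r[i] + r[nb]]
    if (!length(nb)) {
      area[i] <- 4 * pi * r[i]^2
      next
    }
    p <- sweep(pts * r[i], 2L, xyz[i, ], "+")
    buried <- rep(FALSE, nSpherePoints)
    for (j in nb) {
      if (all(buried)) break
      dj <- rowSums(sweep(p, 2L, xyz[j, ])^2)
      buried <- buried | dj < r[j]^2
    }
    area[i] <- 4 * pi * r[i]^2 * mean(!buried)
  }
  perRes <- tapply(area, a$resindex, sum)
  list(total = sum(area),
       perResidue = stats::setNames(as.numeric(perRes), names(perRes)))
}

#' Ca-Ca contact map
#'
#' @param x a \linkS4class{ProteinStructure}; every residue must have a Ca.
#' @return list with \code{matrix} (L x L symmetric Ca-Ca distances,
#'   Angstrom, zero diagonal).
#' @export
contactMap <- function(x) {
  ca <- caCoords(x)
  m <- .crossDist(ca, ca)
  diag(m) <- 0
  list(matrix = m)
}

#' Relative contact order
#'
#' Average sequence separation of residues in spatial contact, normalized by
#' chain length and expressed as a percent:
#' \deqn{RCO = \frac{100}{L N} \sum_{contacts} |i - j|}
#' where the sum runs over the N heavy-atom pairs closer than
#' \code{contactDist} between residues separated by at least
#' \code{minSeqSep} in sequence.
#'
#' @param x a \linkS4class{ProteinStructure}.
#' @param contactDist heavy-atom contact threshold, Angstrom.
#' @param minSeqSep minimum residue sequence separation counted as a contact.
#' @return percent in (0, 100); rigid-motion invariant.
#' @export
contactOrder <- function(x, contactDist = 6.0, minSeqSep = 1L) {
  a <- .heavyAtoms(x)
  L <- max(a$resindex)
  if (L < 2L) .stopf("contact order needs at least 2 residues")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d <- .crossDist(xyz, xyz)
  sep <- abs(outer(a$resindex, a$resindex, "-"))
  inContact <- d < contactDist & sep >= minSeqSep & upper.tri(d)
  n <- sum(inContact)
  if (n == 0L) .stopf("no contacts: contact order undefined")
  100 * sum(sep[inContact]) / (L * n)
}

.acidicAtoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.basicAtoms  <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                     HIS = c("ND1", "NE2"))

.chargedSideAtoms <- function(a, table) {
  keep <- rep(FALSE, nrow(a))
  for (rn in names(table))
    keep <- keep | (a$resname == rn & a$name %in% table[[rn]])
  a[keep, , drop = FALSE]
}

#' Detect salt bridges
#'
#' One record per (acidic, basic) residue pair whose closest carboxylate
#' oxygen (Asp OD1/OD2, Glu OE1/OE2) to basic side-chain nitrogen
#' (Lys NZ; Arg NE/NH1/NH2; His ND1/NE2) distance lies below the cutoff,
#' deduplicated to the minimum distance per pair. Charged residues lacking
#' their side-chain atoms are skipped with a warning.
#'
#' @param x a \linkS4class{ProteinStructure}.
#' @param cutoff Angstrom; default 4.
#' @param countHis whether His counts as basic.
#' @return data.frame with columns \code{acidicRes}, \code{basicRes}
#'   (residue indices), \code{acidicName}, \code{basicName},
#'   \code{minDistance}.
#' @export
saltBridges <- function(x, cutoff = 4.0, countHis = TRUE) {
  a <- .heavyAtoms(x)
  basicTab <- .basicAtoms
  if (!countHis) basicTab$HIS <- NULL
  acid <- .chargedSideAtoms(a, .acidicAtoms)
  base <- .chargedSideAtoms(a, basicTab)
  missing_ <- unique(a$resindex[a$resname %in% c(names(.acidicAtoms),
                                                 names(basicTab)) &
                                !a$resindex %in% c(acid$resindex, base$resindex)])
  if (length(missing_))
    warning("charged residue(s) without side-chain atoms skipped: ",
            paste(missing_, collapse = ", "), call. = FALSE)
  empty <- data.frame(acidicRes = integer(), basicRes = integer(),
                      acidicName = character(), basicName = character(),
                      minDistance = numeric())
  if (!nrow(acid) || !nrow(base)) return(empty)
  d <- .crossDist(as.matrix(acid[, c("x", "y", "z")]),
                  as.matrix(base[, c("x", "y", "z")]))
  hitIdx <- which(d < cutoff, arr.ind = TRUE)
  if (!nrow(hitIdx)) return(empty)
  res <- data.frame(acidicRes = acid$resindex[hitIdx[, 1L]],
                    basicRes = base$resindex[hitIdx[, 2L]],
                    acidicName = acid$resname[hitIdx[, 1L]],
                    basicName = base$resname[hitIdx[, 2L]],
                    minDistance = d[hitIdx], stringsAsFactors = FALSE)
  res <- res[res$acidicRes != res$basicRes, , drop = FALSE]
  if (!nrow(res)) return(empty)
  res <- res[order(res$acidicRes, res$basicRes, res$minDistance), ]
  res <- res[!duplicated(res[, c("acidicRes", "basicRes")]), ]
  rownames(res) <- NULL
  res
}

#' Detect hydrogen bonds (heavy-atom criterion)
#'
#' Chimeric models carry no hydrogens, so detection is by donor/acceptor
#' heavy-atom distance: N/O atom pairs closer than \code{dMax}, excluding
#' same-residue pairs, and requiring a sequence separation of at least 2 for
#' backbone-backbone pairs (closer backbone pairs are covalent geometry).
#' When one atom is N and the other O, the N is reported as donor; for
#' like-element pairs the lower residue index is reported first.
#'
#' @param x a \linkS4class{ProteinStructure}.
#' @param dMax donor-acceptor distance cutoff, Angstrom.
#' @param useAngle reserved; angle screening applies only when hydrogens are
#'   present, which the package's models never are.
#' @return data.frame with columns \code{donorRes}, \code{acceptorRes},
#'   \code{donorName}, \code{acceptorName}, \code{distance}.
#' @export
hBonds <- function(x, dMax = 3.5, useAngle = FALSE) {
  a <- .heavyAtoms(x)
  no <- a[a$element %in% c("N", "O"), , drop = FALSE]
  empty <- data.frame(donorRes = integer(), acceptorRes = integer(),
                      donorName = character(), acceptorName = character(),
                      distance = numeric())
  if (nrow(no) < 2L || dMax <= 0) return(empty)
  d <- .crossDist(as.matrix(no[, c("x", "y", "z")]),
                  as.matrix(no[, c("x", "y", "z")]))
  bb <- no$name %in% .backboneNames
  cand <- which(upper.tri(d) & d < dMax, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  i <- cand[, 1L]; j <- cand[, 2L]
  sep <- abs(no$resindex[i] - no$resindex[j])
  ok <- sep >= 1L & !(bb[i] & bb[j] & sep < 2L)
  i <- i[ok]; j <- j[ok]
  if (!length(i)) return(empty)
  ## orient: N donates to O; ties by residue order
  swap <- (no$element[i] == "O" & no$element[j] == "N") |
    (no$element[i] == no$element[j] & no$resindex[i] > no$resindex[j])
  di <- ifelse(swap, j, i); ai <- ifelse(swap, i, j)
  out <- data.frame(donorRes = no$resindex[di], acceptorRes = no$resindex[ai],
                    donorName = no$name[di], acceptorName = no$name[ai],
                    distance = d[cbind(di, ai)], stringsAsFactors = FALSE)
  out[order(out$donorRes, out$acceptorRes), , drop = FALSE]
}

#' Hydrophobic clusters (CSU-style contact graph)
#'
#' Apolar atoms are the side-chain carbons and sulfurs of hydrophobic-class
#' residues (ALA, VAL, LEU, ILE, MET, PHE, TRP, PRO, CYS). Two atoms are in
#' contact when their centres lie within \code{r_vdw(a) + r_vdw(b) +
#' 2*contactPad} (the pad is the solvent probe radius: a water molecule
#' cannot pass between them). Clusters are the connected components of the
#' residue graph linked by at least one atomic contact, filtered by
#' \code{minClusterSize}. The area of a cluster sums, over its atomic
#' contacts, the spherical-cap area of the smaller atom facing its partner,
#' estimated with the same quadrature as [sasa()]. This distance-threshold
#' contact graph approximates the CSU contact classification.
#'
#' @param x a \linkS4class{ProteinStructure} with side-chain heavy atoms.
#' @param contactPad Angstrom added per atom to the van der Waals contact
#'   test (default 1.4, the water probe).
#' @param minClusterSize minimum residues per reported cluster.
#' @param nSpherePoints quadrature points for the cap-area estimate.
#' @return list of clusters sorted by residue count descending, each a list
#'   with \code{residues} (integer indices), \code{nAtoms}, and \code{area}
#'   (Angstrom^2 of summed pairwise contact surface).
#' @export
hydrophobicClusters <- function(x, contactPad = 1.4, minClusterSize = 4L,
                                nSpherePoints = 960L) {
  a <- .heavyAtoms(x)
  apolar <- a[residueClass(a$resname) == "hydrophobic" &
              a$element %in% c("C", "S") &
              !a$name %in% .backboneNames, , drop = FALSE]
  if (!nrow(apolar)) return(list())
  xyz <- as.matrix(apolar[, c("x", "y", "z")])
  r <- .vdwRadius(apolar$element)
  d <- .crossDist(xyz, xyz)
  thr <- outer(r, r, "+") + 2 * contactPad
  touch <- d <= thr & upper.tri(d) & outer(apolar$resindex, apolar$resindex, "!=")
  pair <- which(touch, arr.ind = TRUE)
  resIds <- sort(unique(apolar$resindex))
  g <- igraph::make_empty_graph(length(resIds), directed = FALSE)
  igraph::V(g)$name <- as.character(resIds)
  if (nrow(pair)) {
    edges <- unique(cbind(pmin(apolar$resindex[pair[, 1L]], apolar$resindex[pair[, 2L]]),
                          pmax(apolar$resindex[pair[, 1L]], apolar$resindex[pair[, 2L]])))
    g <- igraph::add_edges(g, t(matrix(as.character(edges), ncol = 2L)))
  }
  comp <- igraph::components(g)
  pts <- .spherePoints(nSpherePoints)
  capArea <- function(i, j) {
    ## cap of the smaller atom's contact sphere facing atom j
    if (r[j] < r[i]) { k <- i; i <- j; j <- k }
    ri <- r[i] + contactPad; rj <- r[j] + contactPad
    p <- sweep(pts * ri, 2L, xyz[i, ], "+")
    inside <- rowSums(sweep(p, 2L, xyz[j, ])^2) <= rj^2
    4 * pi * ri^2 * mean(inside)
  }
  out <- list()
  for (k in seq_len(comp$no)) {
    members <- resIds[comp$membership == k]
    if (length(members) < minClusterSize) next
    inK <- apolar$resindex %in% members
    pk <- pair[inK[pair[, 1L]] & inK[pair[, 2L]], , drop = FALSE]
    area <- sum(vapply(seq_len(nrow(pk)),
                       function(m) capArea(pk[m, 1L], pk[m, 2L]), 0))
    out[[length(out) + 1L]] <-
      list(residues = members,
           nAtoms = sum(inK),
           area = area)
  }
  out[order(-vapply(out, function(cl) length(cl$residues), 0L))]
}

#' Run the full analysis battery
#'
#' Computes SASA, relative contact order, salt bridges, hydrogen bonds and
#' hydrophobic clusters with default parameters, aggregating per-analysis
#' errors instead of aborting the rest.
#'
#' @param x a \linkS4class{ProteinStructure}.
#' @return JSON-serializable list with elements \code{id}, \code{nResidues},
#'   \code{sasaTotal}, \code{rco}, \code{nSaltBridges}, \code{nHbonds},
#'   \code{clusters} (sizes and areas) and \code{errors} (named messages for
#'   any sub-analysis that failed).
#' @export
analysisReport <- function(x) {
  stopifnot(methods::is(x, "ProteinStructure"))
  errors <- list()
  grab <- function(name, expr) {
    tryCatch(suppressWarnings(expr), error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  sa <- grab("sasa", sasa(x)$total)
  rco <- grab("contactOrder", contactOrder(x))
  sb <- grab("saltBridges", nrow(saltBridges(x)))
  hb <- grab("hBonds", nrow(hBonds(x)))
  cl <- grab("hydrophobicClusters", hydrophobicClusters(x))
  list(id = structureId(x), nResidues = nResidues(x),
       sasaTotal = sa, rco = rco, nSaltBridges = sb, nHbonds = hb,
       clusters = lapply(cl, function(ck)
         list(size = length(ck$residues), area = ck$area)),
       errors = errors)
}
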