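## Independent oracles and fixture builders. Everything here is deliberately
## written by a different route than the package code it checks: closed
## forms, quaternion eigen-decomposition, and plain double loops.

## ---- quaternion (Horn) superposition: minimum RMSD without SVD ----
oracleKabschRMSD <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  n <- nrow(A)
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  M <- t(Bc) %*% Ac
  S <- function(i, j) M[i, j]
  K <- matrix(c(
    S(1,1)+S(2,2)+S(3,3), S(2,3)-S(3,2),        S(3,1)-S(1,3),        S(1,2)-S(2,1),
    S(2,3)-S(3,2),        S(1,1)-S(2,2)-S(3,3), S(1,2)+S(2,1),        S(3,1)+S(1,3),
    S(3,1)-S(1,3),        S(1,2)+S(2,1),       -S(1,1)+S(2,2)-S(3,3), S(2,3)+S(3,2),
    S(1,2)-S(2,1),        S(3,1)+S(1,3),        S(2,3)+S(3,2),       -S(1,1)-S(2,2)+S(3,3)),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(Ac^2) + sum(Bc^2) - 2 * lambda) / n))
}

## ---- plain double-loop detectors ----
bruteClash <- function(chimera, dClash = 2.5) {
  a <- atomTable(chimera)
  bb <- a[a$name %in% c("N", "CA", "C", "O"), ]
  prov <- provenance(chimera)[bb$resindex]
  junction <- sum(provenance(chimera) == provenance(chimera)[1])
  for (i in seq_len(nrow(bb))) for (j in seq_len(nrow(bb))) {
    if (prov[i] == prov[j]) next
    ri <- bb$resindex[i]; rj <- bb$resindex[j]
    if (ri %in% c(junction, junction + 1) && rj %in% c(junction, junction + 1))
      next
    d <- sqrt(sum((bb[i, c("x", "y", "z")] - bb[j, c("x", "y", "z")])^2))
    if (d < dClash) return(TRUE)
  }
  FALSE
}

bruteSaltBridges <- function(s, cutoff = 4.0) {
  a <- atomTable(s)
  acid <- a[(a$resname == "ASP" & a$name %in% c("OD1", "OD2")) |
            (a$resname == "GLU" & a$name %in% c("OE1", "OE2")), ]
  base <- a[(a$resname == "LYS" & a$name == "NZ") |
            (a$resname == "ARG" & a$name %in% c("NE", "NH1", "NH2")) |
            (a$resname == "HIS" & a$name %in% c("ND1", "NE2")), ]
  found <- list()
  for (i in seq_len(nrow(acid))) for (j in seq_len(nrow(base))) {
    d <- sqrt(sum((acid[i, c("x", "y", "z")] - base[j, c("x", "y", "z")])^2))
    if (d < cutoff) {
      key <- paste(acid$resindex[i], base$resindex[j])
      if (is.null(found[[key]]) || d < found[[key]]) found[[key]] <- d
    }
  }
  found
}

bruteHBonds <- function(s, dMax = 3.5) {
  a <- atomTable(s)
  no <- a[a$element %in% c("N", "O"), ]
  bb <- no$name %in% c("N", "CA", "C", "O")
  cnt <- 0L
  n <- nrow(no)
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sep <- abs(no$resindex[i] - no$resindex[j])
    if (sep < 1) next
    if (bb[i] && bb[j] && sep < 2) next
    d <- sqrt(sum((no[i, c("x", "y", "z")] - no[j, c("x", "y", "z")])^2))
    if (d < dMax) cnt <- cnt + 1L
  }
  cnt
}

## residue partition of the apolar-contact graph, by repeated set expansion
bruteClusterPartition <- function(s, contactPad = 1.4) {
  rad <- c(C = 1.70, S = 1.80)
  a <- atomTable(s)
  ap <- a[residueClass(a$resname) == "hydrophobic" &
          a$element %in% c("C", "S") &
          !a$name %in% c("N", "CA", "C", "O"), ]
  if (!nrow(ap)) return(list())
  res <- sort(unique(ap$resindex))
  touches <- function(r1, r2) {
    a1 <- ap[ap$resindex == r1, ]; a2 <- ap[ap$resindex == r2, ]
    for (i in seq_len(nrow(a1))) for (j in seq_len(nrow(a2))) {
      thr <- rad[[a1$element[i]]] + rad[[a2$element[j]]] + 2 * contactPad
      if (sqrt(sum((a1[i, c("x","y","z")] - a2[j, c("x","y","z")])^2)) <= thr)
        return(TRUE)
    }
    FALSE
  }
  n <- length(res)
  adj <- matrix(FALSE, n, n)
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n)
    adj[i, j] <- adj[j, i] <- touches(res[i], res[j])
  ## label propagation to a fixed point
  label <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && label[j] != label[i]) {
        m <- min(label[i], label[j])
        label[i] <- label[j] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  groups <- unname(lapply(split(res, label), sort))
  groups[order(-lengths(groups))]
}

## ---- union-find over a node/edge list ----
unionFindComponents <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (length(edges)) for (e in edges) parent[[find(e[1])]] <- find(e[2])
  roots <- vapply(nodes, find, "")
  unname(lapply(split(nodes, roots), sort))
}

## ---- random fixtures ----

## random compact structure with charged + hydrophobic side chains
randomAnalysisStructure <- function(seed, nres = 8, box = 12) {
  set.seed(seed)
  types <- sample(c("ASP", "GLU", "LYS", "ARG", "HIS", "LEU", "ILE",
                    "ALA", "SER"), nres, replace = TRUE)
  side <- list(
    ASP = c("CB", "CG", "OD1", "OD2"), GLU = c("CB", "CG", "CD", "OE1", "OE2"),
    LYS = c("CB", "CG", "CD", "CE", "NZ"),
    ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
    HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
    LEU = c("CB", "CG", "CD1", "CD2"), ILE = c("CB", "CG1", "CG2", "CD1"),
    ALA = "CB", SER = c("CB", "OG"))
  rows <- list()
  for (i in seq_len(nres)) {
    ca <- runif(3, 0, box)
    nm <- c("N", "CA", "C", "O", side[[types[i]]])
    off <- rbind(c(-1.2, 0.4, 0), c(0, 0, 0), c(1.3, 0.4, 0), c(1.8, 1.5, 0),
                 matrix(runif(3 * length(side[[types[i]]]), -2, 2),
                        ncol = 3))
    el <- substr(nm, 1, 1); el[nm == "CA"] <- "C"
    rows[[i]] <- data.frame(name = nm, element = el, resname = types[i],
                            chain = "A", resid = i,
                            x = ca[1] + off[, 1], y = ca[2] + off[, 2],
                            z = ca[3] + off[, 3])
  }
  ProteinStructure(do.call(rbind, rows), id = paste0("rand", seed))
}

## random hit table over invented domains (for network property tests)
randomHitTable <- function(seed, nDomains = 12, nHits = 25) {
  set.seed(seed)
  doms <- sprintf("d%04da_", seq_len(nDomains))
  aln <- strrep("A", 15)
  h <- data.frame(query_id = sample(doms, nHits, replace = TRUE),
                  subject_id = sample(doms, nHits, replace = TRUE),
                  q_cluster = sample(1:3, nHits, replace = TRUE),
                  s_cluster = sample(1:3, nHits, replace = TRUE),
                  q_start = 0L, q_end = 15L, s_start = 0L, s_end = 15L,
                  q_aln = aln, s_aln = aln,
                  probability = runif(nHits, 50, 100),
                  rmsd = runif(nHits, 1, 4),
                  tm_score = runif(nHits, 0.1, 0.7),
                  identity = runif(nHits, 5, 40),
                  q_scop = sample(c("c.37.1.10", "c.2.1.2", "c.2.1.5"),
                                  nHits, replace = TRUE),
                  s_scop = sample(c("c.37.1.10", "c.2.1.2", "c.2.1.5"),
                                  nHits, replace = TRUE))
  methods::new("HitSet", hits = h)
}

## a hit of a structure against itself (full-length, ungapped)
selfHit <- function(s, cluster2 = 2L) {
  L <- nResidues(s)
  aln <- paste(rep("A", L), collapse = "")
  methods::new("HitSet", hits = data.frame(
    query_id = structureId(s), subject_id = structureId(s),
    q_cluster = 1L, s_cluster = cluster2,
    q_start = 0L, q_end = L, s_start = 0L, s_end = L,
    q_aln = aln, s_aln = aln, probability = 99, rmsd = 0,
    tm_score = 0.5, identity = 100,
    q_scop = "c.1.1.1", s_scop = "c.1.1.1"))
}

toyHitsPath <- function() {
  system.file("extdata", "toy_hits.tsv", package = "chimeraforge")
}
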