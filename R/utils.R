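## Residue chemistry tables and small geometry helpers shared across modules.

.backboneNames <- c("N", "CA", "C", "O")

.hydrophobicSet <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO", "CYS")
.acidicSet      <- c("ASP", "GLU")
.basicSet       <- c("LYS", "ARG", "HIS")

.aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

## van der Waals radii (Angstrom) used by SASA and contact tests
.vdwRadii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
.vdwDefault <- 1.70

.vdwRadius <- function(element) {
  r <- .vdwRadii[toupper(element)]
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(element[is.na(r)]), collapse = ", "),
            "; using fallback radius ", .vdwDefault, " Angstrom", call. = FALSE)
    r[is.na(r)] <- .vdwDefault
  }
  unname(r)
}

#' Chemical classes of a residue
#'
#' Deterministic classification by 3-letter code: hydrophobic
#' (ALA, VAL, LEU, ILE, MET, PHE, TRP, PRO, CYS), acidic (ASP, GLU),
#' basic (LYS, ARG, HIS); everything else standard is polar.
#'
#' @param name3 character vector of 3-letter residue codes.
#' @return character vector of class labels, one per input.
#' @examples
#' residueClass(c("LEU", "ASP", "LYS", "SER"))
#' @export
residueClass <- function(name3) {
  name3 <- toupper(name3)
  ifelse(name3 %in% .hydrophobicSet, "hydrophobic",
         ifelse(name3 %in% .acidicSet, "acidic",
                ifelse(name3 %in% .basicSet, "basic", "polar")))
}

## Deterministic quasi-uniform points on the unit sphere (golden-section
## spiral); used by the SASA quadrature and the cluster-area cap estimate.
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

## Euclidean distances between rows of a and rows of b (na x nb matrix).
.crossDist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

## Apply a rigid transform x -> R x + t to an n x 3 coordinate matrix.
.applyRigid <- function(coords, rotation, translation) {
  sweep(as.matrix(coords) %*% t(rotation), 2L, translation, "+")
}

## Random rotation matrix (uniform via QR of Gaussian), for tests/fixtures.
.randomRotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3L))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

## Evaluate an expression under a temporary RNG state seeded with `seed`,
## restoring the caller's stream afterwards.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
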