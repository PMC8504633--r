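## Fragment superposition: least-squares optimal rigid fit (Kabsch), the
## gap-delimited segment partition, global/partial superposition of an
## alignment, and the TM-score.

#' Optimal rigid superposition of paired point sets (Kabsch)
#'
#' Finds the rotation and translation minimizing the RMSD of \code{coordsB}
#' onto \code{coordsA} under positional correspondence, with reflection
#' correction, via singular value decomposition of the covariance matrix.
#'
#' @param coordsA,coordsB N x 3 coordinate matrices (Angstrom), N >= 3.
#' @return a \linkS4class{Superposition} mapping b to
#'   \code{rotation \%*\% b + translation}.
#' @examples
#' a <- matrix(rnorm(30), 10)
#' s <- kabsch(a, a)           # identity fit, rmsd 0
#' @export
kabsch <- function(coordsA, coordsB) {
  A <- as.matrix(coordsA); B <- as.matrix(coordsB)
  if (nrow(A) != nrow(B) || ncol(A) != 3L || ncol(B) != 3L)
    .stopf("coordinate sets must be N x 3 with equal N")
  n <- nrow(A)
  if (n < 3L) .stopf("at least 3 point pairs are required")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2L, ca); Bc <- sweep(B, 2L, cb)
  H <- crossprod(Bc, Ac)             # 3x3 covariance
  sv <- svd(H)
  if (min(sv$d) < 1e-10 * max(sv$d, 1e-12))
    warning("degenerate (near-collinear/planar) point set; solution may be unstable",
            call. = FALSE)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(ca - R %*% cb)
  Bt <- .applyRigid(B, R, tr)
  dist <- sqrt(rowSums((A - Bt)^2))
  methods::new("Superposition", rotation = R, translation = tr,
               rmsd = sqrt(mean(dist^2)), pairDistances = dist,
               fitted = rep(TRUE, n))
}

#' Partition an alignment into gap-delimited segments
#'
#' Splits a pair of equal-length gapped alignment strings into the maximal
#' runs of columns where both strings are non-gap. These runs are the
#' "shorter regions" the partial superposition mode fits independently;
#' alignment gaps are the boundaries.
#'
#' @param qAln,sAln gapped alignment strings (letters and \code{"-"}).
#' @return a \linkS4class{SegmentPartition} with 0-based half-open column
#'   ranges.
#' @examples
#' partitionSegments("AA--AA", "AAAAAA")   # [0,2) and [4,6)
#' @export
partitionSegments <- function(qAln, sAln) {
  if (nchar(qAln) != nchar(sAln)) .stopf("alignment strings differ in length")
  q <- strsplit(qAln, "")[[1L]]; s <- strsplit(sAln, "")[[1L]]
  both <- q != "-" & s != "-"
  if (!any(both)) .stopf("empty partition: no gap-free alignment columns")
  r <- rle(both)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values
  seg <- data.frame(start = starts[keep] - 1L, end = ends[keep])
  methods::new("SegmentPartition", segments = seg)
}

## columns (0-based) -> which segment they fall in (NA if none)
.segmentOf <- function(columns, partition) {
  seg <- partition@segments
  out <- rep(NA_integer_, length(columns))
  for (k in seq_len(nrow(seg)))
    out[columns >= seg$start[k] & columns < seg$end[k]] <- k
  out
}

#' Superpose the shared fragment of an alignment map
#'
#' Global mode fits one rigid transform over all aligned Ca pairs. Partial
#' mode fits each gap-delimited segment independently (segments shorter than
#' \code{minSegLen} aligned pairs are excluded, and their columns carry no
#' distance), measuring each column's Ca-Ca distance under its own segment's
#' transform.
#'
#' @param map an \linkS4class{AlignmentMap}.
#' @param mode \code{"global"} or \code{"partial"}.
#' @param minSegLen minimum aligned pairs per usable segment (partial mode).
#' @return named list of \linkS4class{Superposition} objects: one element
#'   \code{"global"} in global mode, one \code{"segment<k>"} per usable
#'   segment in partial mode. Each carries \code{pairDistances} for all
#'   aligned columns of the map (NA outside its governance) and
#'   \code{fitted} flags for the positions it was fitted on.
#' @export
superposeFragment <- function(map, mode = c("global", "partial"),
                              minSegLen = 3L) {
  mode <- match.arg(mode)
  p <- map@pairs
  if (nrow(p) < 3L) .stopf("need at least 3 aligned pairs to superpose")
  qca <- caCoords(map@qStruct, p$qIdx)
  sca <- caCoords(map@sStruct, p$sIdx)
  if (mode == "global") {
    sup <- kabsch(qca, sca)
    names(sup@pairDistances) <- p$column
    return(list(global = sup))
  }
  segIdx <- .segmentOf(p$column, map@partition)
  usable <- names(which(table(segIdx) >= minSegLen))
  if (!length(usable))
    .stopf(paste("all segments have fewer than %d aligned pairs;",
                 "use mode = \"global\" instead"), minSegLen)
  out <- list()
  for (k in as.integer(usable)) {
    in_k <- which(segIdx == k)
    sup <- kabsch(qca[in_k, , drop = FALSE], sca[in_k, , drop = FALSE])
    d <- rep(NA_real_, nrow(p)); f <- rep(FALSE, nrow(p))
    d[in_k] <- sup@pairDistances; f[in_k] <- TRUE
    names(d) <- p$column
    out[[paste0("segment", k)]] <-
      methods::new("Superposition", rotation = sup@rotation,
                   translation = sup@translation, rmsd = sup@rmsd,
                   pairDistances = d, fitted = f)
  }
  out
}

#' TM-score from aligned-pair distances
#'
#' Standard length-normalized structural-similarity score:
#' \deqn{TM = \frac{1}{L} \sum_i \frac{1}{1 + (d_i/d_0)^2},\quad
#'       d_0 = 1.24 (L - 15)^{1/3} - 1.8}
#' with \code{d0} floored at 0.5 Angstrom (and a warning) when
#' \code{lTarget <= 15}. Equals (number of pairs)/L at zero distances, 1 for
#' a perfect full-coverage superposition, and decreases monotonically in
#' every distance.
#'
#' @param pairDistances aligned Ca-Ca distances, Angstrom (NA entries dropped).
#' @param lTarget normalizing chain length L (residues).
#' @return unitless score in (0, 1].
#' @examples
#' tmScore(rep(0, 100), 100)   # 1
#' @export
tmScore <- function(pairDistances, lTarget) {
  d <- pairDistances[!is.na(pairDistances)]
  if (any(d < 0)) .stopf("distances must be >= 0")
  if (lTarget <= 15) {
    warning("L <= 15: using d0 floor of 0.5 Angstrom", call. = FALSE)
    d0 <- 0.5
  } else {
    d0 <- max(1.24 * (lTarget - 15)^(1 / 3) - 1.8, 0.5)
  }
  sum(1 / (1 + (d / d0)^2)) / lTarget
}
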