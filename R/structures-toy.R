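## Synthetic parent-pair generator with engineered fusion points.

#' Generate a synthetic parent pair with a known number of fusion points
#'
#' Builds two ideal-geometry structures sharing an \code{nShared}-residue
#' fragment, perturbed so that after least-squares superposition of the
#' fragment's Ca atoms exactly \code{nFusable} aligned pairs lie below the
#' 1 Angstrom fusion cutoff. The shared fragment is cut from one extended
#' (strand-geometry) chain: the query keeps an N-terminal flank, the subject
#' a C-terminal flank, so every chimera assembled at an engineered fusion
#' point reconstitutes a clash-free chain. Fusable fragment residues of the
#' subject are displaced by ~0.2 Angstrom, non-fusable ones by ~1.8 Angstrom,
#' and the whole subject is then moved by a random rigid transform. The
#' construction is verified internally against an actual superposition
#' (resampling the perturbation directions if any engineered margin is
#' violated) and is reproducible: the same seed yields identical output.
#'
#' @param nShared fragment length in residues (>= 3).
#' @param nFusable number of aligned pairs engineered below 1 Angstrom
#'   (0 <= nFusable <= nShared).
#' @param seed integer seed.
#' @param flank residues of unique sequence flanking the fragment on the
#'   query N-terminus and subject C-terminus.
#' @return list with elements \code{query}, \code{subject}
#'   (\linkS4class{ProteinStructure}) and \code{hit} (a one-row
#'   \linkS4class{HitSet} whose fragment bounds are 0-based half-open on the
#'   internal residue index, with an ungapped alignment).
#' @examples
#' toy <- makeToyPair(20, 5, seed = 1)
#' toy$hit
#' @export
makeToyPair <- function(nShared, nFusable, seed, flank = 4L) {
  if (nShared < 3L) .stopf("nShared must be >= 3")
  if (nFusable < 0L || nFusable > nShared)
    .stopf("nFusable must lie in [0, nShared]")
  .withSeed(as.integer(seed), {
    chainLen <- flank + nShared + flank
    chain <- buildIdealSS(data.frame(kind = "strand", length = chainLen))
    query <- .sliceStructure(chain, 1L, flank + nShared, id = "toyq")
    fusable <- sort(sample.int(nShared, nFusable))
    magn <- ifelse(seq_len(nShared) %in% fusable, 0.2, 1.8)

    for (try in 1:100) {
      subject <- .sliceStructure(chain, flank + 1L, chainLen, id = "toys")
      sa <- subject@atoms
      ## rigid per-residue displacement of the fragment residues
      for (i in seq_len(nShared)) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2)) * magn[i]
        sel <- sa$resindex == i
        sa$x[sel] <- sa$x[sel] + u[1L]
        sa$y[sel] <- sa$y[sel] + u[2L]
        sa$z[sel] <- sa$z[sel] + u[3L]
      }
      ## random rigid placement of the whole subject
      R <- .randomRotation(); tr <- stats::runif(3, -20, 20)
      xyz <- .applyRigid(as.matrix(sa[, c("x", "y", "z")]), R, tr)
      sa$x <- xyz[, 1L]; sa$y <- xyz[, 2L]; sa$z <- xyz[, 3L]
      subject@atoms <- sa

      ## verify the engineered count with an actual fragment superposition
      qca <- caCoords(query, flank + seq_len(nShared))
      sca <- caCoords(subject, seq_len(nShared))
      sup <- suppressWarnings(kabsch(qca, sca))
      d <- sup@pairDistances
      nonfusable <- setdiff(seq_len(nShared), fusable)
      if (all(d[fusable] < 0.75) && all(d[nonfusable] > 1.25))
        break
      if (try == 100L)
        .stopf("failed to realize the requested fusion-point pattern")
    }

    aln <- paste(rep("A", nShared), collapse = "")
    hit <- data.frame(query_id = "toyq", subject_id = "toys",
                      q_cluster = 1L, s_cluster = 1L,
                      q_start = flank, q_end = flank + nShared,
                      s_start = 0L, s_end = nShared,
                      q_aln = aln, s_aln = aln,
                      probability = 99, rmsd = round(sup@rmsd, 3),
                      tm_score = round(suppressWarnings(
                        tmScore(d, nShared + flank)), 3),
                      identity = 100,
                      q_scop = "c.37.1.10", s_scop = "c.2.1.2",
                      stringsAsFactors = FALSE)
    list(query = query, subject = subject,
         hit = methods::new("HitSet", hits = hit))
  })
}
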