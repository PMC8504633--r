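## Chimera construction: map a hit's alignment onto the two parent
## structures, find fusion points, assemble both single-crossover
## combinations per point, and reject models with backbone clashes.

#' Map a hit's alignment onto the two parent structures
#'
#' Walks the gapped alignment strings from the fragment start positions and
#' pairs each gap-free column with its query and subject residues (internal
#' 1-based indices); columns with a gap on either side carry no pair.
#' Alignment letters are checked against the structures' one-letter
#' sequences; mismatches above the tolerated fraction abort with per-column
#' diagnostics.
#'
#' @param hit a one-row \linkS4class{HitSet} (or a HitSet plus \code{row}).
#' @param q,s query and subject \linkS4class{ProteinStructure}s.
#' @param row which hit row to use.
#' @param minSeqIdentity minimum tolerated fraction of alignment letters
#'   matching the structure sequence, per side.
#' @return an \linkS4class{AlignmentMap}.
#' @export
mapAlignment <- function(hit, q, s, row = 1L, minSeqIdentity = 0.9) {
  stopifnot(methods::is(hit, "HitSet"))
  h <- hit@hits[row, ]
  qa <- strsplit(h$q_aln, "")[[1L]]
  sa <- strsplit(h$s_aln, "")[[1L]]
  if (h$q_end > nResidues(q))
    .stopf("mapping error: fragment bound %d exceeds %s length %d",
           h$q_end, structureId(q), nResidues(q))
  if (h$s_end > nResidues(s))
    .stopf("mapping error: fragment bound %d exceeds %s length %d",
           h$s_end, structureId(s), nResidues(s))
  qi <- h$q_start; si <- h$s_start          # 0-based cursors
  cols <- qIdx <- sIdx <- integer(0)
  for (col in seq_along(qa)) {
    qg <- qa[col] == "-"; sg <- sa[col] == "-"
    if (!qg && !sg) {
      cols <- c(cols, col - 1L)
      qIdx <- c(qIdx, qi + 1L); sIdx <- c(sIdx, si + 1L)
    }
    if (!qg) qi <- qi + 1L
    if (!sg) si <- si + 1L
  }
  for (side in c("query", "subject")) {
    st <- if (side == "query") q else s
    letters_ <- if (side == "query") qa[cols + 1L] else sa[cols + 1L]
    idx <- if (side == "query") qIdx else sIdx
    seq1 <- sequence1(st)[idx]
    ok <- letters_ == seq1 | seq1 == "X"
    if (mean(ok) < minSeqIdentity)
      .stopf(paste0("mapping error: %s alignment disagrees with the %s ",
                    "sequence at column(s) %s"),
             side, structureId(st),
             paste(utils::head(cols[!ok], 10L), collapse = ", "))
  }
  methods::new("AlignmentMap",
               pairs = data.frame(column = cols, qIdx = qIdx, sIdx = sIdx),
               qStruct = q, sStruct = s,
               partition = partitionSegments(h$q_aln, h$s_aln),
               hit = hit@hits[row, , drop = FALSE])
}

#' Theoretical maximum number of chimeras for an alignment map
#'
#' Every gap-free aligned column could in the ideal case become a fusion
#' point, and each fusion point yields two combinations, so the ceiling is
#' twice the number of aligned positions.
#'
#' @param map an \linkS4class{AlignmentMap}.
#' @return integer count.
#' @export
theoreticalMaxChimeras <- function(map) {
  stopifnot(methods::is(map, "AlignmentMap"))
  2L * nrow(map@pairs)
}

#' Find fusion points of an aligned fragment pair
#'
#' Superposes the fragment ([superposeFragment()]) and returns exactly the
#' aligned columns whose post-superposition Ca-Ca distance lies below the
#' cutoff, in sequence order. In partial mode each column is measured under
#' its own segment's transform; columns in segments shorter than
#' \code{minSegLen} are excluded from candidacy.
#'
#' @param map an \linkS4class{AlignmentMap}.
#' @param mode \code{"global"} or \code{"partial"}.
#' @param cutoff Angstrom; default 1.
#' @param minSegLen minimum aligned pairs per segment in partial mode.
#' @return data.frame with columns \code{column} (0-based), \code{qIdx},
#'   \code{sIdx}, \code{caDistance}, \code{transform} (name of the governing
#'   superposition); attribute \code{"superpositions"} holds the fits.
#' @export
findFusionPoints <- function(map, mode = c("global", "partial"),
                             cutoff = 1.0, minSegLen = 3L) {
  mode <- match.arg(mode)
  sups <- superposeFragment(map, mode, minSegLen)
  p <- map@pairs
  dist <- rep(NA_real_, nrow(p))
  governs <- rep(NA_character_, nrow(p))
  for (nm in names(sups)) {
    d <- sups[[nm]]@pairDistances
    take <- !is.na(d) & is.na(dist)
    dist[take] <- d[take]; governs[take] <- nm
  }
  sel <- which(!is.na(dist) & dist < cutoff)
  out <- data.frame(column = p$column[sel], qIdx = p$qIdx[sel],
                    sIdx = p$sIdx[sel], caDistance = dist[sel],
                    transform = governs[sel], stringsAsFactors = FALSE)
  attr(out, "superpositions") <- sups
  out
}

#' Assemble one chimera at a fusion point
#'
#' Combination 1 takes the query residues up to and including the fusion
#' column's query residue, followed by the subject residues after the fusion
#' column's subject residue; combination 2 is the mirror image (subject
#' N-terminus). Subject coordinates are always transformed into the query
#' frame by the governing superposition. The result is renumbered 1..L on
#' chain A with per-residue provenance recorded.
#'
#' @param map an \linkS4class{AlignmentMap}.
#' @param fusionPoint one row of [findFusionPoints()] output.
#' @param combination 1 or 2.
#' @param superpositions the fits attached to the fusion-point table
#'   (defaults to its \code{"superpositions"} attribute).
#' @return a \linkS4class{Chimera}.
#' @export
assembleChimera <- function(map, fusionPoint, combination,
                            superpositions = attr(fusionPoint, "superpositions")) {
  stopifnot(methods::is(map, "AlignmentMap"), combination %in% 1:2)
  fp <- as.list(fusionPoint[1L, ])
  sup <- superpositions[[fp$transform]]
  if (is.null(sup)) .stopf("unknown governing transform '%s'", fp$transform)
  qa <- map@qStruct@atoms
  sa <- map@sStruct@atoms
  xyz <- .applyRigid(as.matrix(sa[, c("x", "y", "z")]),
                     sup@rotation, sup@translation)
  sa$x <- xyz[, 1L]; sa$y <- xyz[, 2L]; sa$z <- xyz[, 3L]
  Lq <- max(qa$resindex); Ls <- max(sa$resindex)
  if (combination == 1L) {
    nPart <- qa[qa$resindex <= fp$qIdx, , drop = FALSE]
    cPart <- sa[sa$resindex > fp$sIdx, , drop = FALSE]
    nLen <- fp$qIdx; cLen <- Ls - fp$sIdx
    prov <- c(rep("query", nLen), rep("subject", cLen))
  } else {
    nPart <- sa[sa$resindex <= fp$sIdx, , drop = FALSE]
    cPart <- qa[qa$resindex > fp$qIdx, , drop = FALSE]
    nLen <- fp$sIdx; cLen <- Lq - fp$qIdx
    prov <- c(rep("subject", nLen), rep("query", cLen))
  }
  if (nLen == 0L || cLen == 0L)
    .stopf("degenerate chimera: fusion at column %d leaves an empty %s side",
           fp$column, if (nLen == 0L) "N-terminal" else "C-terminal")
  cPart$resindex <- cPart$resindex - min(cPart$resindex) + nLen + 1L
  a <- rbind(nPart, cPart)
  a$resid <- a$resindex
  a$chain <- "A"; a$icode <- ""
  a$serial <- seq_len(nrow(a))
  rownames(a) <- NULL
  methods::new("Chimera",
               id = sprintf("comb%d_%d", combination, fp$column),
               atoms = a, combination = as.integer(combination),
               fusionColumn = as.integer(fp$column),
               qResIdx = as.integer(fp$qIdx), sResIdx = as.integer(fp$sIdx),
               caDistance = fp$caDistance, provenance = prov)
}

#' Backbone clash test for a chimera
#'
#' \code{TRUE} iff any backbone heavy-atom pair (N, CA, C, O) between a
#' query-tagged and a subject-tagged residue lies closer than \code{dClash},
#' excluding the two residues joined by the new peptide bond at the junction
#' (whose backbone atoms are covalently closer than any non-bonded contact
#' could be). Intra-parent geometry is taken as valid and not rescanned.
#'
#' @param chimera a \linkS4class{Chimera}.
#' @param dClash Angstrom; default 2.5.
#' @return logical: \code{TRUE} when the model clashes.
#' @export
clashCheck <- function(chimera, dClash = 2.5) {
  stopifnot(methods::is(chimera, "Chimera"))
  a <- chimera@atoms
  bb <- a[a$name %in% .backboneNames, , drop = FALSE]
  prov <- chimera@provenance[bb$resindex]
  junction <- sum(chimera@provenance == chimera@provenance[1L])
  skip <- bb$resindex %in% c(junction, junction + 1L)
  gN <- which(prov == prov[1L])
  gC <- which(prov != prov[1L])
  if (!length(gN) || !length(gC)) return(FALSE)
  use_N <- gN[!skip[gN]]; use_C <- gC[!skip[gC]]
  ## the junction residues still clash-test against non-adjacent residues
  ## of the other half, just not against each other
  jN <- gN[skip[gN]]; jC <- gC[skip[gC]]
  xyz <- as.matrix(bb[, c("x", "y", "z")])
  pairsBelow <- function(i, j) {
    if (!length(i) || !length(j)) return(FALSE)
    any(.crossDist(xyz[i, , drop = FALSE], xyz[j, , drop = FALSE]) < dClash)
  }
  pairsBelow(use_N, use_C) || pairsBelow(jN, use_C) || pairsBelow(use_N, jC)
}

#' Build every viable chimera for a hit
#'
#' Runs the full pipeline: find fusion points at the cutoff, attempt both
#' combinations at each point, drop degenerate junctions and models with
#' backbone clashes. Candidate count before the clash filter is twice the
#' number of fusion points; the ceiling over all cutoffs is
#' [theoreticalMaxChimeras()].
#'
#' @param map an \linkS4class{AlignmentMap}.
#' @param mode \code{"global"} or \code{"partial"}.
#' @param cutoff fusion-distance cutoff, Angstrom.
#' @param dClash backbone-clash threshold, Angstrom.
#' @param minSegLen minimum segment length for partial mode.
#' @return list with elements \code{chimeras} (named list of
#'   \linkS4class{Chimera}, names \code{comb\{1|2\}_\{column\}}) and
#'   \code{manifest} (one row per attempted candidate: name, column, parent
#'   residues, Ca distance, status \code{kept}/\code{clash}/\code{degenerate}).
#' @export
buildAllChimeras <- function(map, mode = c("global", "partial"),
                             cutoff = 1.0, dClash = 2.5, minSegLen = 3L) {
  mode <- match.arg(mode)
  fps <- findFusionPoints(map, mode, cutoff, minSegLen)
  sups <- attr(fps, "superpositions")
  chimeras <- list()
  rows <- list()
  if (nrow(fps) == 0L)
    message("no fusion points below ", cutoff, " Angstrom; nothing to build")
  for (i in seq_len(nrow(fps))) {
    for (comb in 1:2) {
      nm <- sprintf("comb%d_%d", comb, fps$column[i])
      ch <- tryCatch(assembleChimera(map, fps[i, ], comb, sups),
                     error = function(e) e)
      if (inherits(ch, "error")) {
        status <- "degenerate"
      } else if (clashCheck(ch, dClash)) {
        status <- "clash"
      } else {
        status <- "kept"
        chimeras[[nm]] <- ch
      }
      rows[[length(rows) + 1L]] <-
        data.frame(name = nm, column = fps$column[i], qIdx = fps$qIdx[i],
                   sIdx = fps$sIdx[i], caDistance = fps$caDistance[i],
                   status = status, stringsAsFactors = FALSE)
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(), column = integer(), qIdx = integer(),
               sIdx = integer(), caDistance = numeric(), status = character())
  list(chimeras = chimeras, manifest = manifest)
}
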