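#' @import methods
NULL

#' ProteinStructure: ordered residues with typed atoms and coordinates
#'
#' The universal 3-D object of the package: a flat atom table grouped into an
#' ordered residue list. Residue order is file order; every algorithm addresses
#' residues through the internal sequential index (column \code{resindex},
#' \code{1..L}), never through author numbering.
#'
#' @slot id character(1). PDB/SCOPe-style identifier.
#' @slot atoms data.frame with columns \code{serial} (integer), \code{name}
#'   (PDB atom name, e.g. \code{"CA"}), \code{element}, \code{resname}
#'   (3-letter code), \code{chain}, \code{resid} (author residue number),
#'   \code{icode} (insertion code, \code{""} when absent), \code{resindex}
#'   (internal 1-based residue index) and Cartesian \code{x}, \code{y},
#'   \code{z} in Angstrom.
#'
#' @section Validity:
#' Coordinates are finite; each residue has at most one atom per atom name;
#' \code{(chain, resid, icode)} is unique across residues; \code{resindex} is
#' a contiguous run \code{1..L} with \code{L >= 1}.
#'
#' @aliases ProteinStructure
#' @exportClass ProteinStructure
setClass("ProteinStructure",
         representation(id = "character", atoms = "data.frame"))

.atomCols <- c("serial", "name", "element", "resname", "chain", "resid",
               "icode", "resindex", "x", "y", "z")

setValidity("ProteinStructure", function(object) {
  a <- object@atoms
  if (length(object@id) != 1L) return("'id' must be a single string")
  miss <- setdiff(.atomCols, names(a))
  if (length(miss)) return(paste("atom table lacks columns:",
                                 paste(miss, collapse = ", ")))
  if (nrow(a) == 0L) return("structure must contain at least one residue")
  if (!all(is.finite(c(a$x, a$y, a$z)))) return("non-finite coordinates")
  ri <- a$resindex
  if (!all(diff(ri) %in% c(0L, 1L)) || ri[1L] != 1L)
    return("resindex must be contiguous 1..L in atom order")
  key <- tapply(paste(a$chain, a$resid, a$icode), ri, `[`, 1L)
  if (anyDuplicated(key)) return("(chain, resid, icode) not unique across residues")
  dupAtom <- stats::aggregate(seq_len(nrow(a)),
                              by = list(ri = ri, nm = a$name), FUN = length)
  if (any(dupAtom$x > 1L)) return("duplicate atom name within a residue")
  TRUE
})

#' HitSet: a validated table of fragment-homology hits
#'
#' One row per hit: two domains (query and subject) sharing a fragment, with
#' fragment bounds, gapped alignment strings, HHsearch-style probability,
#' RMSD, TM-score, sequence identity and dotted SCOPe lineage codes.
#' Fragment bounds are 0-based half-open on the internal residue index of the
#' corresponding structure.
#'
#' @slot hits data.frame with columns \code{query_id}, \code{subject_id},
#'   \code{q_cluster}, \code{s_cluster}, \code{q_start}, \code{q_end},
#'   \code{s_start}, \code{s_end}, \code{q_aln}, \code{s_aln},
#'   \code{probability}, \code{rmsd}, \code{tm_score}, \code{identity},
#'   \code{q_scop}, \code{s_scop}.
#'
#' @aliases HitSet
#' @exportClass HitSet
setClass("HitSet", representation(hits = "data.frame"))

.hitCols <- c("query_id", "subject_id", "q_cluster", "s_cluster",
              "q_start", "q_end", "s_start", "s_end", "q_aln", "s_aln",
              "probability", "rmsd", "tm_score", "identity",
              "q_scop", "s_scop")

## Per-row invariant check; returns character() when clean, else messages.
.hitRowProblems <- function(h) {
  msgs <- character()
  ungap <- function(s) nchar(gsub("-", "", s, fixed = TRUE))
  for (i in seq_len(nrow(h))) {
    r <- h[i, ]
    who <- sprintf("row %d (%s/%s)", i, r$query_id, r$subject_id)
    if (nchar(r$q_aln) != nchar(r$s_aln))
      msgs <- c(msgs, paste0(who, ": q_aln and s_aln lengths differ"))
    if (ungap(r$q_aln) != r$q_end - r$q_start)
      msgs <- c(msgs, paste0(who, ": ungapped q_aln length != q_end - q_start"))
    if (ungap(r$s_aln) != r$s_end - r$s_start)
      msgs <- c(msgs, paste0(who, ": ungapped s_aln length != s_end - s_start"))
    if (is.na(r$probability) || r$probability < 0 || r$probability > 100)
      msgs <- c(msgs, paste0(who, ": probability outside [0, 100]"))
    if (is.na(r$rmsd) || r$rmsd < 0)
      msgs <- c(msgs, paste0(who, ": negative rmsd"))
  }
  msgs
}

setValidity("HitSet", function(object) {
  h <- object@hits
  miss <- setdiff(.hitCols, names(h))
  if (length(miss)) return(paste("missing column(s):", paste(miss, collapse = ", ")))
  p <- .hitRowProblems(h)
  if (length(p)) return(paste(p, collapse = "; "))
  TRUE
})

#' SegmentPartition: gap-delimited alignment segments
#'
#' Maximal runs of alignment columns where both strings are non-gap, as
#' 0-based half-open \code{[start, end)} column ranges in ascending order.
#'
#' @slot segments data.frame with integer columns \code{start}, \code{end}.
#' @aliases SegmentPartition
#' @exportClass SegmentPartition
setClass("SegmentPartition", representation(segments = "data.frame"))

setValidity("SegmentPartition", function(object) {
  s <- object@segments
  if (!all(c("start", "end") %in% names(s))) return("need columns start, end")
  if (nrow(s) == 0L) return(TRUE)
  if (any(s$end <= s$start)) return("empty segment")
  if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)]))
    return("segments overlap or are not ascending")
  TRUE
})

#' Superposition: an optimal rigid-body fit and its residuals
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation numeric(3), Angstrom. The fit maps a mobile point b to
#'   \code{rotation \%*\% b + translation}.
#' @slot rmsd numeric(1), Angstrom, over the positions used in the fit.
#' @slot pairDistances per-aligned-position Ca-Ca distances (Angstrom) after
#'   the transform; \code{NA} for positions not governed by any fit.
#' @slot fitted logical, same length: whether each position entered the fit.
#' @aliases Superposition
#' @exportClass Superposition
setClass("Superposition",
         representation(rotation = "matrix", translation = "numeric",
                        rmsd = "numeric", pairDistances = "numeric",
                        fitted = "logical"))

setValidity("Superposition", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (abs(det(R) - 1) > 1e-6) return("rotation determinant must be +1")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6) return("rotation not orthonormal")
  if (length(object@translation) != 3L) return("translation must be length 3")
  d <- object@pairDistances[object@fitted]
  if (length(d) && abs(object@rmsd^2 - mean(d^2)) > 1e-6)
    return("rmsd inconsistent with fitted pair distances")
  TRUE
})

#' AlignmentMap: alignment columns mapped onto two structures
#'
#' Per-position pairing of query and subject residues for the gap-free columns
#' of a hit's alignment, together with the gap-delimited segment partition.
#'
#' @slot pairs data.frame with columns \code{column} (0-based alignment
#'   column), \code{qIdx}, \code{sIdx} (1-based internal residue indices).
#' @slot qStruct,sStruct the two parent \linkS4class{ProteinStructure}s.
#' @slot partition \linkS4class{SegmentPartition} of the alignment.
#' @slot hit one-row data.frame: the originating hit record.
#' @aliases AlignmentMap
#' @exportClass AlignmentMap
setClass("AlignmentMap",
         representation(pairs = "data.frame",
                        qStruct = "ProteinStructure",
                        sStruct = "ProteinStructure",
                        partition = "SegmentPartition",
                        hit = "data.frame"))

setValidity("AlignmentMap", function(object) {
  p <- object@pairs
  if (!all(c("column", "qIdx", "sIdx") %in% names(p)))
    return("pairs needs columns column, qIdx, sIdx")
  if (nrow(p) > 1L && (any(diff(p$qIdx) <= 0) || any(diff(p$sIdx) <= 0)))
    return("residue indices must be strictly increasing")
  TRUE
})

#' Chimera: a single-crossover fusion of two parents
#'
#' Extends \linkS4class{ProteinStructure} with the fusion point and
#' per-residue parent provenance. Combination 1 takes its N-terminus from the
#' query parent, combination 2 from the subject parent.
#'
#' @slot combination integer(1), 1 or 2.
#' @slot fusionColumn integer(1), 0-based alignment column of the crossover.
#' @slot qResIdx,sResIdx 1-based parent residue indices at the crossover.
#' @slot caDistance numeric(1), post-superposition Ca-Ca distance (Angstrom).
#' @slot provenance character vector, one of \code{"query"}/\code{"subject"}
#'   per residue.
#' @aliases Chimera
#' @exportClass Chimera
setClass("Chimera", contains = "ProteinStructure",
         representation(combination = "integer", fusionColumn = "integer",
                        qResIdx = "integer", sResIdx = "integer",
                        caDistance = "numeric", provenance = "character"))

setValidity("Chimera", function(object) {
  L <- max(object@atoms$resindex)
  if (length(object@provenance) != L) return("provenance must cover every residue")
  if (!all(object@provenance %in% c("query", "subject")))
    return("provenance tags must be 'query' or 'subject'")
  first <- object@provenance[1L]
  want <- if (object@combination == 1L) "query" else "subject"
  if (first != want)
    return("N-terminal provenance inconsistent with combination")
  if (is.unsorted(match(object@provenance, c(first, setdiff(c("query","subject"), first)))))
    return("provenance must switch parent exactly once")
  TRUE
})

#' SimilarityNetwork: domains sharing fragments, as a graph
#'
#' Nodes are domain-fragment clusters (\code{<domain>_<cluster>}); an edge
#' joins two nodes when at least one hit links them, with the number of
#' collapsed parallel hits stored as edge attribute \code{multiplicity}.
#'
#' @slot graph an \pkg{igraph} graph with vertex attributes \code{domain},
#'   \code{cluster}, \code{scop}, \code{fold}.
#' @slot collapsed logical(1): whether cluster tags were collapsed to bare
#'   domain ids at build time.
#' @aliases SimilarityNetwork
#' @exportClass SimilarityNetwork
setClass("SimilarityNetwork",
         representation(graph = "ANY", collapsed = "logical"))

setValidity("SimilarityNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph slot must hold an igraph object")
  if (igraph::gsize(g) && igraph::any_loop(g)) return("self-loops are not allowed")
  if (igraph::any_multiple(g)) return("parallel edges must be collapsed")
  TRUE
})
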