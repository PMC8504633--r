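#' Construct a ProteinStructure from an atom table
#'
#' Low-level constructor used by the readers and fixture generators; fills in
#' \code{resindex}, \code{element} and \code{icode} when absent and validates
#' the result.
#'
#' @param atoms data.frame with at least \code{name}, \code{resname},
#'   \code{chain}, \code{resid}, \code{x}, \code{y}, \code{z}. Optional
#'   \code{serial}, \code{element}, \code{icode}, \code{resindex}.
#' @param id identifier string.
#' @return a \linkS4class{ProteinStructure}.
#' @examples
#' a <- data.frame(name = "CA", resname = "GLY", chain = "A", resid = 1,
#'                 x = 0, y = 0, z = 0)
#' ProteinStructure(a, id = "toy")
#' @export
ProteinStructure <- function(atoms, id = "structure") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$icode)) atoms$icode <- ""
  atoms$icode[is.na(atoms$icode)] <- ""
  if (is.null(atoms$element))
    atoms$element <- substr(gsub("[^A-Za-z].*$", "", atoms$name), 1L, 1L)
  if (is.null(atoms$resindex)) {
    ## residue index increments whenever the (chain, resid, icode) key changes
    key <- paste(atoms$chain, atoms$resid, atoms$icode, sep = "\r")
    atoms$resindex <- cumsum(c(TRUE, key[-1L] != key[-length(key)]))
  }
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  atoms$resindex <- as.integer(atoms$resindex)
  atoms$serial <- as.integer(atoms$serial)
  atoms$resid <- as.integer(atoms$resid)
  rownames(atoms) <- NULL
  methods::new("ProteinStructure", id = id, atoms = atoms[, .atomCols])
}

#' @rdname ProteinStructure-accessors
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))

#' @rdname ProteinStructure-accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname ProteinStructure-accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname ProteinStructure-accessors
#' @export
setGeneric("caCoords", function(x, which = NULL) standardGeneric("caCoords"))

#' @rdname ProteinStructure-accessors
#' @export
setGeneric("sequence3", function(x) standardGeneric("sequence3"))

#' @rdname ProteinStructure-accessors
#' @export
setGeneric("sequence1", function(x) standardGeneric("sequence1"))

#' Accessors for ProteinStructure
#'
#' @param x a \linkS4class{ProteinStructure}.
#' @param which optional integer vector of 1-based residue indices.
#' @return \code{structureId}: the identifier. \code{atomTable}: the atom
#'   data.frame. \code{nResidues}: residue count L. \code{caCoords}: L x 3
#'   matrix of Ca coordinates (rows named by resindex; an error names any
#'   residue lacking a Ca). \code{sequence3}/\code{sequence1}: per-residue
#'   3-letter / 1-letter codes (\code{"X"} for non-standard).
#' @name ProteinStructure-accessors
NULL

#' @rdname ProteinStructure-accessors
setMethod("structureId", "ProteinStructure", function(x) x@id)

#' @rdname ProteinStructure-accessors
setMethod("atomTable", "ProteinStructure", function(x) x@atoms)

#' @rdname ProteinStructure-accessors
setMethod("nResidues", "ProteinStructure", function(x) max(x@atoms$resindex))

#' @rdname ProteinStructure-accessors
setMethod("caCoords", "ProteinStructure", function(x, which = NULL) {
  a <- x@atoms
  if (is.null(which)) which <- seq_len(max(a$resindex))
  ca <- a[a$name == "CA", , drop = FALSE]
  idx <- match(which, ca$resindex)
  if (anyNA(idx))
    .stopf("residue(s) without CA atom: %s",
           paste(which[is.na(idx)], collapse = ", "))
  m <- as.matrix(ca[idx, c("x", "y", "z")])
  rownames(m) <- which
  m
})

#' @rdname ProteinStructure-accessors
setMethod("sequence3", "ProteinStructure", function(x) {
  a <- x@atoms
  as.character(tapply(a$resname, a$resindex, `[`, 1L))
})

#' @rdname ProteinStructure-accessors
setMethod("sequence1", "ProteinStructure", function(x) {
  s <- .aa3to1[sequence3(x)]
  s[is.na(s)] <- "X"
  unname(s)
})

setMethod("show", "ProteinStructure", function(object) {
  L <- nResidues(object)
  cat(sprintf("ProteinStructure '%s': %d residues, %d atoms\n",
              object@id, L, nrow(object@atoms)))
  s <- paste(sequence1(object), collapse = "")
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat("  sequence: ", s, "\n", sep = "")
})

setMethod("show", "Chimera", function(object) {
  cat(sprintf("Chimera '%s' (combination %d, fusion column %d, Ca dist %.2f A)\n",
              object@id, object@combination, object@fusionColumn,
              object@caDistance))
  tab <- table(object@provenance)
  cat(sprintf("  %d residues: %d query + %d subject\n",
              nResidues(object), tab[["query"]], tab[["subject"]]))
})

#' Per-residue parent provenance of a chimera
#' @param x a \linkS4class{Chimera}.
#' @return character vector (\code{"query"}/\code{"subject"}), one per residue.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname provenance
setMethod("provenance", "Chimera", function(x) x@provenance)

setMethod("show", "Superposition", function(object) {
  cat(sprintf("Superposition: rmsd %.3f A over %d fitted positions (%d total)\n",
              object@rmsd, sum(object@fitted), length(object@fitted)))
})

setMethod("show", "HitSet", function(object) {
  h <- object@hits
  cat(sprintf("HitSet: %d hits, %d distinct domains\n", nrow(h),
              length(unique(c(h$query_id, h$subject_id)))))
  if (nrow(h))
    print(utils::head(h[, c("query_id", "subject_id", "probability",
                            "rmsd", "tm_score")], 5L))
})

#' Number of hits in a HitSet
#' @param x a \linkS4class{HitSet}.
#' @export
setMethod("length", "HitSet", function(x) nrow(x@hits))

#' Underlying hit table
#' @param x a \linkS4class{HitSet}.
#' @return the hit data.frame.
#' @export
setGeneric("hitTable", function(x) standardGeneric("hitTable"))

#' @rdname hitTable
setMethod("hitTable", "HitSet", function(x) x@hits)

#' Subset a HitSet by row
#' @param x a \linkS4class{HitSet}.
#' @param i row indices.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "HitSet", function(x, i, j, ..., drop = FALSE) {
  methods::new("HitSet", hits = x@hits[i, , drop = FALSE])
})

setMethod("show", "SimilarityNetwork", function(object) {
  g <- object@graph
  cat(sprintf("SimilarityNetwork: %d nodes, %d edges%s\n",
              igraph::gorder(g), igraph::gsize(g),
              if (object@collapsed) " (clusters collapsed)" else ""))
})

setMethod("show", "AlignmentMap", function(object) {
  cat(sprintf("AlignmentMap: %d aligned pairs (%s vs %s), %d segment(s)\n",
              nrow(object@pairs), object@qStruct@id, object@sStruct@id,
              nrow(object@partition@segments)))
})
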