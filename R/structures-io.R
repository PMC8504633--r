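## PDB reading/writing. Parsing of the fixed-column format is delegated to
## bio3d; this layer enforces the package's dialect: single conformer
## (altloc blank or 'A'), first MODEL only, HETATM/waters/hydrogens dropped.

.waterNames <- c("HOH", "WAT", "DOD", "SOL")

## Pre-scan for malformed ATOM/HETATM records so errors can name the line.
.scanPDBLines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  coordRec <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in coordRec) {
    ln <- lines[i]
    if (nchar(ln) < 54L)
      .stopf("format error at line %d: coordinate record shorter than 54 columns", i)
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz))
      .stopf("format error at line %d: unparseable coordinate field", i)
  }
  invisible(length(coordRec))
}

#' Read a PDB file into a ProteinStructure
#'
#' Reads ATOM records of the first model only. HETATM records, waters,
#' hydrogens and alternate locations other than blank/'A' are dropped, so the
#' result is a single-conformer heavy-atom model.
#'
#' @param path path to a PDB-format file.
#' @param id identifier for the structure; defaults to the file base name.
#' @return a \linkS4class{ProteinStructure}.
#' @seealso [writePDB()], [buildIdealSS()]
#' @examples
#' h <- buildIdealSS("helix:8", id = "h8")
#' f <- tempfile(fileext = ".pdb")
#' writePDB(h, f)
#' readPDB(f)
#' @export
readPDB <- function(path, id = sub("\\.(pdb|ent)$", "", basename(path))) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (.scanPDBLines(path) == 0L)
    .stopf("empty-structure error: no coordinate records in %s", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) .stopf("format error reading %s: %s", path,
                               conditionMessage(e)))
  a <- pdb$atom
  keep <- a$type == "ATOM" &
    (is.na(a$alt) | a$alt %in% c("", "A")) &
    !(a$resid %in% .waterNames) &
    !(toupper(a$elesy) %in% "H")
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0L)
    .stopf("empty-structure error: %s contains no standard residues", path)
  atoms <- data.frame(serial = a$eleno, name = a$elety,
                      element = toupper(a$elesy), resname = a$resid,
                      chain = ifelse(is.na(a$chain), "A", a$chain),
                      resid = a$resno,
                      icode = ifelse(is.na(a$insert), "", a$insert),
                      x = a$x, y = a$y, z = a$z,
                      stringsAsFactors = FALSE)
  ProteinStructure(atoms, id = id)
}

#' Write a ProteinStructure to a PDB file
#'
#' Atom serials are renumbered sequentially from 1. For a
#' \linkS4class{Chimera} the B-factor column carries parent provenance
#' (query = 1.0, subject = 2.0), so downstream viewers can colour by origin.
#' Round-trip with [readPDB()] preserves residue/atom names, ordering and
#' coordinates to 3 decimals.
#'
#' @param x a \linkS4class{ProteinStructure}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writePDB <- function(x, path) {
  stopifnot(methods::is(x, "ProteinStructure"))
  a <- x@atoms
  if (nrow(a) == 0L) .stopf("refusing to write a structure with no residues")
  b <- rep(0, nrow(a))
  if (methods::is(x, "Chimera"))
    b <- ifelse(x@provenance[a$resindex] == "query", 1, 2)
  ok <- tryCatch({
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     type = rep("ATOM", nrow(a)),
                     resno = a$resid, resid = a$resname,
                     eleno = seq_len(nrow(a)), elety = a$name,
                     chain = a$chain, insert = ifelse(a$icode == "", NA, a$icode),
                     o = rep(1, nrow(a)), b = b, elesy = a$element)
    TRUE
  }, error = function(e) .stopf("I/O error writing %s: %s", path,
                                conditionMessage(e)))
  invisible(path)
}
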