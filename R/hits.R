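## Hit-table loading (TSV / single-table SQLite) and the fetch/filter
## query semantics.

.requiredHitCols <- function(h, where) {
  miss <- setdiff(.hitCols, names(h))
  if (length(miss))
    .stopf("schema error in %s: missing column(s) %s", where,
           paste(miss, collapse = ", "))
}

## The image ships no R SQLite driver, so the single-table SQLite dialect is
## read through the Python interpreter's stdlib sqlite3 module: the `hits`
## table is dumped to a temporary TSV, which then takes the TSV path.
.sqliteToTSV <- function(path) {
  out <- tempfile(fileext = ".tsv")
  code <- paste(
    "import sqlite3, csv, sys",
    "con = sqlite3.connect(sys.argv[1])",
    "cur = con.execute('SELECT * FROM hits')",
    "w = csv.writer(open(sys.argv[2], 'w', newline=''), delimiter='\\t')",
    "w.writerow([c[0] for c in cur.description])",
    "w.writerows(cur)",
    sep = "; ")
  status <- system2("python", c("-c", shQuote(code), shQuote(path), shQuote(out)),
                    stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status")) || !file.exists(out))
    .stopf("schema error: could not read a 'hits' table from %s", path)
  out
}

#' Load a hit table
#'
#' Reads fragment-homology hits from a TSV file with header, or from a
#' single-table SQLite file whose \code{hits} table carries the same columns.
#' Every row is validated against the hit invariants (equal-length alignment
#' strings, ungapped alignment length equal to the fragment bounds,
#' probability in [0, 100], non-negative RMSD); violations raise an error
#' naming the row number and both domain ids.
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"sqlite"}.
#' @return a \linkS4class{HitSet}.
#' @examples
#' tsv <- system.file("extdata", "toy_hits.tsv", package = "chimeraforge")
#' loadHits(tsv)
#' @export
loadHits <- function(path, format = c("tsv", "sqlite")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (format == "sqlite") path <- .sqliteToTSV(path)
  h <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  .requiredHitCols(h, path)
  for (col in c("q_cluster", "s_cluster", "q_start", "q_end",
                "s_start", "s_end"))
    h[[col]] <- as.integer(h[[col]])
  for (col in c("probability", "rmsd", "tm_score", "identity"))
    h[[col]] <- as.numeric(h[[col]])
  probs <- .hitRowProblems(h)
  if (length(probs))
    .stopf("validation error in %s:\n  %s", path,
           paste(probs, collapse = "\n  "))
  methods::new("HitSet", hits = h)
}

#' Filter criteria for hit tables
#'
#' Default thresholds: probability > 70 percent, RMSD < 3 Angstrom, query
#' fragment length between 10 and 200 residues (inclusive), TM-score < 0.3.
#' Probability and TM-score bounds are strict, length bounds inclusive. Any
#' criterion can be disabled by setting it to \code{NA}.
#'
#' @param minProbability percent; hits must exceed it strictly.
#' @param maxRmsd Angstrom; hits must fall below it strictly.
#' @param minLen,maxLen residues; inclusive bounds on the query fragment
#'   length \code{q_end - q_start}.
#' @param maxTm unitless; hits must fall below it strictly.
#' @return a list of class \code{"FilterCriteria"}.
#' @export
filterCriteria <- function(minProbability = 70, maxRmsd = 3.0,
                           minLen = 10, maxLen = 200, maxTm = 0.3) {
  if (!is.na(minLen) && !is.na(maxLen) && minLen > maxLen)
    .stopf("minLen must be <= maxLen")
  structure(list(minProbability = minProbability, maxRmsd = maxRmsd,
                 minLen = minLen, maxLen = maxLen, maxTm = maxTm),
            class = "FilterCriteria")
}

#' Filter hits by probability, RMSD, fragment length and TM-score
#'
#' Order-preserving subset of the hits satisfying all enabled criteria:
#' \code{probability > minProbability}, \code{rmsd < maxRmsd},
#' \code{minLen <= q_end - q_start <= maxLen}, \code{tm_score < maxTm}.
#' Fragment length is measured on the query fragment.
#'
#' @param hits a \linkS4class{HitSet}.
#' @param criteria a [filterCriteria()] list.
#' @return the filtered \linkS4class{HitSet} (possibly empty).
#' @export
filterHits <- function(hits, criteria = filterCriteria()) {
  stopifnot(methods::is(hits, "HitSet"), inherits(criteria, "FilterCriteria"))
  h <- hits@hits
  keep <- rep(TRUE, nrow(h))
  len <- h$q_end - h$q_start
  if (!is.na(criteria$minProbability))
    keep <- keep & h$probability > criteria$minProbability
  if (!is.na(criteria$maxRmsd)) keep <- keep & h$rmsd < criteria$maxRmsd
  if (!is.na(criteria$minLen)) keep <- keep & len >= criteria$minLen
  if (!is.na(criteria$maxLen)) keep <- keep & len <= criteria$maxLen
  if (!is.na(criteria$maxTm)) keep <- keep & h$tm_score < criteria$maxTm
  hits[which(keep)]
}

.scopPrefixRegex <- function(scopQuery) {
  if (!grepl("^[a-l](\\.[0-9]+){0,3}$", scopQuery))
    .stopf("malformed SCOPe prefix: '%s'", scopQuery)
  paste0("^", gsub(".", "\\.", scopQuery, fixed = TRUE), "(\\.|$)")
}

#' Fetch hits belonging to a SCOPe group
#'
#' Selects hits whose lineage code begins with a dotted prefix on whole-field
#' boundaries: \code{"c.2"} matches \code{"c.2.1.2"} but not
#' \code{"c.21.1.1"}. The prefix may name a class, fold, superfamily or
#' family (1-4 dotted fields).
#'
#' @param hits a \linkS4class{HitSet}.
#' @param scopQuery dotted lineage prefix, e.g. \code{"c.37"}.
#' @param side which side(s) must match: \code{"either"} (default),
#'   \code{"query"}, \code{"subject"} or \code{"both"}.
#' @return the matching \linkS4class{HitSet}.
#' @export
fetchGroup <- function(hits, scopQuery,
                       side = c("either", "query", "subject", "both")) {
  stopifnot(methods::is(hits, "HitSet"))
  side <- match.arg(side)
  re <- .scopPrefixRegex(scopQuery)
  h <- hits@hits
  q <- grepl(re, h$q_scop); s <- grepl(re, h$s_scop)
  keep <- switch(side, either = q | s, query = q, subject = s, both = q & s)
  hits[which(keep)]
}

#' Remove every hit touching a domain
#'
#' Drops all hits whose query or subject is the given domain, matching on the
#' bare domain id: a node-style id with a trailing cluster tag
#' (\code{"d2g0ta1_2"}) is accepted and stripped, so all cluster variants of
#' the domain are removed.
#'
#' @param hits a \linkS4class{HitSet}.
#' @param domainId domain identifier.
#' @return the reduced \linkS4class{HitSet}.
#' @export
excludeDomain <- function(hits, domainId) {
  stopifnot(methods::is(hits, "HitSet"))
  h <- hits@hits
  if (!domainId %in% c(h$query_id, h$subject_id))
    domainId <- sub("_[0-9]+$", "", domainId)
  hits[which(h$query_id != domainId & h$subject_id != domainId)]
}
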