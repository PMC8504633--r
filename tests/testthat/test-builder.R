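test_that("alignment mapping pairs gap-free columns and flags bad input", {
  toy <- makeToyPair(20, 5, seed = 3)
  map <- mapAlignment(toy$hit, toy$query, toy$subject)
  expect_equal(nrow(map@pairs), 20L)

  ## gap exclusion: "AA--AA"/"AAAAAA" maps 4 pairs at columns 0,1,4,5
  q <- buildIdealSS("strand:4", id = "gq")
  s <- buildIdealSS("strand:6", id = "gs")
  hit <- methods::new("HitSet", hits = data.frame(
    query_id = "gq", subject_id = "gs", q_cluster = 1L, s_cluster = 1L,
    q_start = 0L, q_end = 4L, s_start = 0L, s_end = 6L,
    q_aln = "AA--AA", s_aln = "AAAAAA", probability = 99, rmsd = 1,
    tm_score = 0.2, identity = 100, q_scop = "c.1.1.1", s_scop = "c.1.1.1"))
  map2 <- mapAlignment(hit, q, s)
  expect_equal(map2@pairs$column, c(0L, 1L, 4L, 5L))
  expect_equal(map2@pairs$qIdx, 1:4)
  expect_equal(map2@pairs$sIdx, c(1L, 2L, 5L, 6L))

  ## bound overflow names the domain
  badHit <- hit
  badHit@hits$s_end <- 99L
  badHit@hits$s_aln <- strrep("A", 99)
  badHit@hits$q_aln <- paste0("AAAA", strrep("-", 95))
  expect_error(mapAlignment(badHit, q, s), "mapping error.*gs")

  ## sequence mismatch above tolerance gives column diagnostics
  wrong <- hit
  wrong@hits$q_aln <- "GG--GG"
  expect_error(mapAlignment(wrong, q, s), "mapping error.*column")
})

test_that("fusion points are exactly the engineered sub-cutoff columns", {
  toy <- makeToyPair(20, 5, seed = 1)
  map <- mapAlignment(toy$hit, toy$query, toy$subject)
  fps <- findFusionPoints(map)
  expect_equal(nrow(fps), 5L)
  expect_true(all(fps$caDistance < 1.0))
  ## cutoff 0 -> empty; generous cutoff -> every aligned column
  expect_equal(nrow(findFusionPoints(map, cutoff = 0)), 0L)
  expect_equal(nrow(findFusionPoints(map, cutoff = 1e6)), 20L)
  ## identical structures: every aligned column is a fusion point
  h <- buildIdealSS("helix:10", id = "p")
  mapSelf <- mapAlignment(selfHit(h), h, h)
  expect_equal(nrow(findFusionPoints(mapSelf)), 10L)
})

test_that("assembly splits at the fusion column with complementary provenance", {
  toy <- makeToyPair(20, 5, seed = 1)
  map <- mapAlignment(toy$hit, toy$query, toy$subject)
  fps <- findFusionPoints(map)
  sups <- attr(fps, "superpositions")
  Lq <- nResidues(toy$query); Ls <- nResidues(toy$subject)
  for (i in seq_len(nrow(fps))) {
    c1 <- assembleChimera(map, fps[i, ], 1, sups)
    c2 <- assembleChimera(map, fps[i, ], 2, sups)
    expect_equal(nResidues(c1), fps$qIdx[i] + (Ls - fps$sIdx[i]))
    expect_equal(nResidues(c2), fps$sIdx[i] + (Lq - fps$qIdx[i]))
    ## complementary provenance totals
    expect_equal(sum(provenance(c1) == "query"), fps$qIdx[i])
    expect_equal(sum(provenance(c2) == "subject"), fps$sIdx[i])
    ## renumbered 1..L on chain A
    a <- atomTable(c1)
    expect_equal(unique(a$chain), "A")
    expect_equal(a$resid, a$resindex)
  }
  expect_equal(structureId(assembleChimera(map, fps[1, ], 1, sups)),
               sprintf("comb1_%d", fps$column[1]))
})

test_that("self-chimeras reproduce the parent and never clash", {
  h <- buildIdealSS("helix:10", id = "p")
  map <- mapAlignment(selfHit(h), h, h)
  res <- buildAllChimeras(map)
  expect_equal(table(res$manifest$status)[["degenerate"]], 2L)
  expect_false(any(res$manifest$status == "clash"))
  pxyz <- as.matrix(atomTable(h)[, c("x", "y", "z")])
  for (ch in res$chimeras) {
    expect_equal(nResidues(ch), 10L)
    cxyz <- as.matrix(atomTable(ch)[, c("x", "y", "z")])
    expect_lt(sqrt(mean((pxyz - cxyz)^2)), 1e-6)
    expect_false(clashCheck(ch))
  }
})

test_that("clash detection equals the brute-force scan and finds real overlap", {
  ## engineered overlap: subject-tagged half translated onto the query half
  set.seed(21)
  nClash <- 0L
  for (seed in 1:50) {
    toy <- makeToyPair(10, 3, seed = seed)
    map <- mapAlignment(toy$hit, toy$query, toy$subject)
    res <- buildAllChimeras(map)
    if (!length(res$chimeras)) next
    ch <- res$chimeras[[sample(length(res$chimeras), 1)]]
    ## random rigid shove of the subject-tagged residues
    a <- atomTable(ch)
    shift <- runif(3, -1, 1) * sample(c(0.5, 2, 6), 1)
    sel <- provenance(ch)[a$resindex] == "subject"
    a[sel, c("x", "y", "z")] <- sweep(as.matrix(a[sel, c("x", "y", "z")]),
                                      2, shift, "+")
    shoved <- ch; shoved@atoms <- a
    got <- clashCheck(shoved)
    expect_identical(got, bruteClash(shoved))
    nClash <- nClash + got
  }
  expect_gt(nClash, 0)   # the fixture family exercises both outcomes

  ## direct overlap fixture: two helices on top of each other
  h <- buildIdealSS("helix:10", id = "p")
  map <- mapAlignment(selfHit(h), h, h)
  fps <- findFusionPoints(map)
  ch <- assembleChimera(map, fps[5, ], 1, attr(fps, "superpositions"))
  a <- atomTable(ch)
  sel <- provenance(ch)[a$resindex] == "subject"
  ## put the subject half exactly onto the query half
  a[sel, c("x", "y", "z")] <- a[!sel, c("x", "y", "z")][seq_len(sum(sel)), ]
  overlapped <- ch; overlapped@atoms <- a
  expect_true(clashCheck(overlapped))
})

test_that("buildAllChimeras enumerates, names and filters candidates", {
  toy <- makeToyPair(20, 5, seed = 1)
  map <- mapAlignment(toy$hit, toy$query, toy$subject)
  res <- buildAllChimeras(map)
  expect_equal(nrow(res$manifest), 10L)            # 2 per fusion point
  expect_lte(nrow(res$manifest), theoreticalMaxChimeras(map))
  expect_equal(length(res$chimeras), 10L)          # fixture is clash-free
  expect_match(names(res$chimeras), "^comb[12]_[0-9]+$")
  ## every kept model passes the clash filter by construction
  for (ch in res$chimeras) expect_false(clashCheck(ch))
  ## chimera length arithmetic, always >= 2
  expect_true(all(vapply(res$chimeras, nResidues, 0L) >= 2L))
  ## zero fusion points -> empty list with informational message
  toy0 <- makeToyPair(20, 0, seed = 1)
  map0 <- mapAlignment(toy0$hit, toy0$query, toy0$subject)
  expect_message(res0 <- buildAllChimeras(map0), "no fusion points")
  expect_length(res0$chimeras, 0L)
})

test_that("chimera PDB output carries provenance in the B-factor column", {
  toy <- makeToyPair(12, 3, seed = 4)
  map <- mapAlignment(toy$hit, toy$query, toy$subject)
  res <- buildAllChimeras(map)
  ch <- res$chimeras[[1]]
  f <- tempfile(fileext = ".pdb")
  writePDB(ch, f)
  lines <- grep("^ATOM", readLines(f), value = TRUE)
  b <- as.numeric(substr(lines, 61, 66))
  expect_setequal(unique(b), c(1, 2))
  resno <- as.integer(substr(lines, 23, 26))
  expect_equal(sort(unique(b[resno <= sum(provenance(ch) == provenance(ch)[1])])),
               if (ch@combination == 1L) 1 else 2)
})
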