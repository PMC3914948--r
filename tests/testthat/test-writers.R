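duplex_record <- function(sequence = "GCGCGCGC") {
  fx <- make_ideal_duplex(sequence, dir = withr::local_tempdir(),
                          name = "w")
  s <- read_structure(fx$path)
  p <- detect_base_pairs(s)
  st <- detect_stacking(s)
  h <- enforce_unique_membership(
    assemble_helices(p, st, n_residues(s)))$helices
  cl <- classify_pair_roles(h, p)
  ann <- classify_nesting(h)
  pt <- decompose_triples(cl, n_residues(s))
  build_record(s$residues$base, pt, h, ann, cl, title = "duplex")
}

test_that("CT output carries the slot-0 pairing and round-trips exactly", {
  dir <- withr::local_tempdir()
  rec <- duplex_record()
  out <- write_ct(rec, file.path(dir, "d.ct"))
  expect_equal(out$n_omitted, 0)
  lines <- readLines(out$path)
  expect_length(lines, 17)
  f1 <- strsplit(lines[2], " ")[[1]]
  expect_equal(as.integer(f1[5]), 16)   # residue 1 pairs residue 16
  rt <- read_ct(out$path)
  expect_equal(rt$sequence, rec$sequence)
  expect_equal(vapply(rt$partners, function(v) if (length(v)) v else 0L, 0L),
               rss3d:::.slot0_mutual(rec))
})

test_that("unpaired record writes all-zero partner columns", {
  rec <- build_record(rep("U", 5), rep(list(integer(0)), 5), list(),
                      classify_nesting(list()),
                      data.frame(i = integer(0), j = integer(0),
                                 role = character(0),
                                 helix_id = integer(0)))
  dir <- withr::local_tempdir()
  ct <- write_ct(rec, file.path(dir, "u.ct"))
  f <- read_ct(ct$path)
  expect_true(all(lengths(f$partners) == 0))
  bp <- write_bpseq_extended(rec, file.path(dir, "u.bpseq"))
  body <- readLines(bp$path)
  expect_true(all(grepl(" 0$", body)))
  db <- write_dotbracket(rec, file.path(dir, "u.dbn"))
  expect_equal(readLines(db$path)[2], ".....")
})

test_that("CT format errors name the offending line", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "bad.ct")
  writeLines(c("3 t", "1 G 0 2 3 1", "2 C 1 3 0 2", "3 G 2 0 2 3"), p)
  expect_error(read_ct(p), "line 2")          # 1 -> 3 but 3 -> 2
  writeLines(c("4 t", "1 G 0 2 0 1", "2 C 1 3 0 2", "3 G 2 0 0 3"), p)
  expect_error(read_ct(p), "3 data lines")
})

test_that("triple fixture: CT omits one pair, BPSEQ keeps it as a TRIPLE line", {
  dir <- withr::local_tempdir()
  out <- topology_record(make_topology("triple_a915"))
  rec <- out$record
  expect_message(ct <- write_ct(rec, file.path(dir, "t.ct")), "1 triple")
  expect_equal(ct$n_omitted, 1)
  rt <- read_ct(ct$path)
  expect_equal(rt$partners[[15]], 915L)
  expect_length(rt$partners[[20]], 0)
  bp <- write_bpseq_extended(rec, file.path(dir, "t.bpseq"))
  expect_equal(bp$n_triples, 1)
  lines <- readLines(bp$path)
  expect_equal(lines[15], "15 A 915")
  expect_equal(lines[length(lines)], "# TRIPLE 15 20")
  # no pairing lost across formats: omitted + serialized = total
  n_serialized <- sum(rss3d:::.slot0_mutual(rec) > 0) / 2
  expect_equal(n_serialized + ct$n_omitted, nrow(rec$pairs))
})

test_that("dot-bracket uses one alphabet per layer and balances brackets", {
  dir <- withr::local_tempdir()
  rec <- topology_record(make_topology("figure2"))$record
  db <- write_dotbracket(rec, file.path(dir, "f2.dbn"))
  struct <- readLines(db$path)[2]
  ch <- strsplit(struct, "")[[1]]
  expect_equal(sum(ch == "("), sum(ch == ")"))
  expect_equal(sum(ch == "["), sum(ch == "]"))
  expect_equal(sum(ch == "["), 3)   # the non-nested helix has 3 pairs
  # layer-0 brackets nest properly
  depth <- cumsum((ch == "(") - (ch == ")"))
  expect_true(all(depth >= 0))
  expect_equal(depth[length(depth)], 0)

  hp <- duplex_record("GGCAAGCC")
  db2 <- write_dotbracket(hp, file.path(dir, "h.dbn"))
  expect_false(grepl("\\[", readLines(db2$path)[2]))
})

test_that("JSON dump is lossless and byte-stable across runs", {
  dir <- withr::local_tempdir()
  rec <- topology_record(make_topology("triple_a915"))$record
  p1 <- file.path(dir, "a.json"); p2 <- file.path(dir, "b.json")
  write_json_record(rec, p1)
  write_json_record(rec, p2)
  expect_identical(readLines(p1), readLines(p2))
  rec2 <- read_json_record(p1)
  expect_identical(rec2$partners, rec$partners)
  expect_identical(rec2$sequence, rec$sequence)
  expect_identical(rec2$layer, rec$layer)
  expect_identical(rec2$helix_class, rec$helix_class)
  expect_equal(rec2$pairs$i, rec$pairs$i)
  expect_equal(rec2$pairs$role, rec$pairs$role)
  expect_identical(rec2$domain_of, rec$domain_of)
  # residue 15 has two pairs in the dump
  expect_length(rec2$partners[[15]], 2)
})

test_that("CT, BPSEQ and JSON slot-0 columns agree", {
  dir <- withr::local_tempdir()
  for (fixture in c("figure2", "triple_a915", "central_pseudoknot")) {
    rec <- topology_record(make_topology(fixture))$record
    ct <- suppressMessages(write_ct(rec, file.path(dir, paste0(fixture, ".ct"))))
    bp <- write_bpseq_extended(rec, file.path(dir, paste0(fixture, ".bpseq")))
    ctp <- vapply(read_ct(ct$path)$partners,
                  function(v) if (length(v)) v else 0L, 0L)
    bpl <- readLines(bp$path)
    bpl <- bpl[!startsWith(bpl, "#")]
    bpp <- as.integer(vapply(strsplit(bpl, " "), `[`, "", 3))
    expect_equal(ctp, bpp)
    js <- file.path(dir, paste0(fixture, ".json"))
    write_json_record(rec, js)
    expect_equal(rss3d:::.slot0_mutual(read_json_record(js)), ctp)
  }
})

test_that("empty structure serializes to valid dots-only output", {
  rec <- build_record(character(0), list(), list(), classify_nesting(list()),
                      data.frame(i = integer(0), j = integer(0),
                                 role = character(0), helix_id = integer(0)))
  dir <- withr::local_tempdir()
  db <- write_dotbracket(rec, file.path(dir, "e.dbn"))
  expect_equal(readLines(db$path), c("", ""))
  js <- file.path(dir, "e.json")
  write_json_record(rec, js)
  x <- jsonlite::read_json(js)
  expect_equal(x$n_residues, 0)
  expect_length(x$pairs, 0)
})
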