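test_that("the four-helix topology assembles into 4 helices with one non-nested", {
  tp <- make_topology("figure2")
  h <- assemble_helices(tp$pairs, NULL, tp$n_residues)
  expect_length(h, 4)
  ann <- classify_nesting(h)
  expect_equal(sum(ann$layer > 0), 1)
  blue <- h[[which(ann$layer > 0)]]
  expect_equal(blue$strand5_range[1], tp$expected$nonnested_start)
  expect_equal(ann$helix_class[[as.character(blue$helix_id)]],
               "non_nested_tertiary")
  expect_true(all(ann$helix_class[names(ann$layer)[ann$layer == 0]] ==
                    "nested_secondary"))
})

test_that("empty pair list gives empty helix list; bad indices error", {
  expect_length(assemble_helices(data.frame(i = integer(0), j = integer(0)),
                                 NULL, 10), 0)
  expect_error(assemble_helices(data.frame(i = 1L, j = 99L), NULL, 10),
               "exceeds n_residues")
})

test_that("bulge chaining follows the stack: bridged = one helix, unbridged = two", {
  # duplex pairing with a 2-nt bulge on strand 5' between pairs 4 and 5
  pairs <- data.frame(i = c(1:4, 7:10), j = c(20:17, 16:13))
  adj <- data.frame(i = c(1L, 2L, 3L, 7L, 8L, 9L), j = c(2L, 3L, 4L, 8L, 9L, 10L))
  bridged <- rbind(adj, data.frame(i = 4L, j = 7L))  # stack across the bulge
  h1 <- assemble_helices(pairs, bridged, 20)
  expect_length(h1, 1)
  expect_true(h1[[1]]$has_defect)
  # no stacks at all is pairing-list-only mode (adjacency, g = 0): splits
  h0 <- assemble_helices(pairs, NULL, 20)
  expect_length(h0, 2)
  # stacks supplied but none bridging the bulge junction: splits in two
  h2 <- assemble_helices(pairs, adj, 20)
  expect_length(h2, 2)
  expect_false(any(vapply(h2, `[[`, TRUE, "has_defect")))
})

test_that("strand connectivity within helices always holds", {
  tp <- make_topology("random", n_helices = 7, seed = 11)
  h <- assemble_helices(tp$pairs, NULL, tp$n_residues)
  for (hx in h) {
    p <- hx$pairs
    if (nrow(p) > 1) {
      expect_true(all(diff(p$i) > 0))
      expect_true(all(diff(p$j) < 0))
    }
    expect_false(anyDuplicated(c(p$i, p$j)) > 0)
  }
})

test_that("unique membership keeps the pair in the larger helix, demotes the other", {
  # two helices sharing residue 15 via a triple; helix A has 3 pairs,
  # helix B (containing the duplicate pair) has 2
  pairs <- rbind(
    data.frame(i = c(14L, 15L, 16L), j = c(916L, 915L, 914L)),
    data.frame(i = c(15L, 16L), j = c(21L, 20L)))
  h <- assemble_helices(pairs, NULL, 920)
  expect_length(h, 2)
  uq <- enforce_unique_membership(h)
  # both pairs of the smaller helix touch conflicted residues 15 and 16
  expect_equal(nrow(uq$demoted), 2)
  expect_length(uq$helices, 1)
  expect_equal(uq$helices[[1]]$pairs$j, c(916L, 915L, 914L))
  # idempotence
  uq2 <- enforce_unique_membership(uq$helices)
  expect_equal(uq2$helices, uq$helices)
  expect_equal(nrow(uq2$demoted), 0)
})

test_that("equal-size membership conflicts resolve to the earlier-starting helix", {
  pairs <- rbind(
    data.frame(i = c(10L, 11L), j = c(40L, 39L)),
    data.frame(i = c(11L, 12L), j = c(60L, 59L)))
  h <- assemble_helices(pairs, NULL, 60)
  uq <- enforce_unique_membership(h)
  # helix starting at 10 wins residue 11; (11, 60) demoted
  expect_true(any(uq$demoted$i == 11 & uq$demoted$j == 60))
  starts <- vapply(uq$helices, function(x) x$strand5_range[1], numeric(1))
  expect_true(10 %in% starts)
})

test_that("disjoint helices pass unique membership unchanged", {
  tp <- make_topology("figure2")
  h <- assemble_helices(tp$pairs, NULL, tp$n_residues)
  uq <- enforce_unique_membership(h)
  expect_equal(nrow(uq$demoted), 0)
  expect_length(uq$helices, 4)
})

test_that("pair roles: helix members secondary, lone and demoted pairs tertiary", {
  tr <- make_topology("triple_a915")
  h <- assemble_helices(tr$pairs, NULL, tr$n_residues)
  uq <- enforce_unique_membership(h)
  cl <- classify_pair_roles(uq$helices, tr$pairs)
  expect_equal(sum(cl$role == "secondary"), 3)
  expect_equal(sum(cl$role == "tertiary"), 1)
  expect_equal(cl$role[cl$i == 15 & cl$j == 20], "tertiary")
  # conservation
  expect_equal(nrow(cl), nrow(tr$pairs))
  # a non-canonical pair extending a helix is secondary
  pairs <- data.frame(i = 1:4, j = 30:27, canonical = c(TRUE, TRUE, TRUE, FALSE))
  h2 <- assemble_helices(pairs, NULL, 30)
  cl2 <- classify_pair_roles(h2, pairs)
  expect_length(h2, 1)
  expect_equal(cl2$role[!cl2$canonical], "secondary")
})

test_that("single helix is nested layer 0; forced-secondary flips the selection", {
  one <- assemble_helices(data.frame(i = 1:3, j = 20:18), NULL, 20)
  ann <- classify_nesting(one)
  expect_equal(unname(ann$layer), 0L)
  expect_equal(unname(ann$helix_class), "nested_secondary")

  cp <- make_topology("central_pseudoknot")
  h <- label_helices(assemble_helices(cp$pairs, NULL, cp$n_residues), cp$labels)
  free <- classify_nesting(h)
  # unforced: maximum-weight crossing-free set (the 4-pair helix)
  w0 <- sum(vapply(h[free$layer == 0], function(x) nrow(x$pairs), integer(1)))
  expect_equal(w0, cp$expected$unforced_layer0_weight)
  forced <- classify_nesting(h, forced_secondary = "Helix 2")
  lab2 <- which(vapply(h, function(x) identical(x$label, "Helix 2"), logical(1)))
  id2 <- as.character(h[[lab2]]$helix_id)
  expect_equal(forced$layer[[id2]], 0L)
  expect_equal(forced$helix_class[[id2]], "forced_secondary")
  expect_true(all(forced$layer[names(forced$layer) != id2] > 0))
})

test_that("mutually crossing forced helices raise an infeasible-constraint error", {
  pairs <- rbind(data.frame(i = 1:2, j = 30:29),
                 data.frame(i = 10:11, j = 45:44))
  h <- assemble_helices(pairs, NULL, 45)
  h <- label_helices(h, list(H1 = c(1, 2), H2 = c(10, 11)))
  expect_error(classify_nesting(h, forced_secondary = c("H1", "H2")),
               "infeasible")
})

test_that("exact nested-set weight matches exhaustive enumeration on random topologies", {
  for (seed in 1:25) {
    tp <- make_topology("random", n_helices = 6, seed = seed)
    h <- assemble_helices(tp$pairs, NULL, tp$n_residues)
    ann <- classify_nesting(h)
    w <- sum(vapply(h[ann$layer == 0], function(x) nrow(x$pairs), integer(1)))
    expect_equal(w, brute_force_layer0_weight(h), label = paste("seed", seed))
    # layer-0 helices pairwise non-crossing
    l0 <- h[ann$layer == 0]
    if (length(l0) > 1)
      for (a in seq_along(l0)) for (b in seq_along(l0)) if (a < b)
        expect_false(rss3d:::helices_cross(l0[[a]], l0[[b]]))
    # within every layer, no two helices cross
    for (l in unique(ann$layer)) {
      hl <- h[ann$layer == l]
      if (length(hl) > 1)
        for (a in seq_along(hl)) for (b in seq_along(hl)) if (a < b)
          expect_false(rss3d:::helices_cross(hl[[a]], hl[[b]]))
    }
  }
})

test_that("adding a non-crossing helix never shrinks layer 0", {
  tp <- make_topology("figure2")
  h <- assemble_helices(tp$pairs, NULL, tp$n_residues)
  ann <- classify_nesting(h)
  ids0 <- names(ann$layer)[ann$layer == 0]
  extra <- rbind(tp$pairs, data.frame(i = 75:76, j = 80:79, canonical = TRUE))
  h2 <- assemble_helices(extra, NULL, 80)
  ann2 <- classify_nesting(h2)
  starts0 <- vapply(h[as.integer(ids0)], function(x) x$strand5_range[1], numeric(1))
  starts2 <- vapply(h2[ann2$layer == 0], function(x) x$strand5_range[1], numeric(1))
  expect_true(all(starts0 %in% starts2))
})

test_that("triple decomposition keeps both pairs and orders the hub's partners", {
  tr <- make_topology("triple_a915")
  out <- topology_record(tr)
  expect_equal(out$partners[[15]], c(915L, 20L))
  expect_equal(out$partners[[915]], 15L)
  expect_equal(out$partners[[20]], 15L)
  # conservation: pair multiset unchanged (4 pairs in, 4 pairs represented)
  total <- sum(lengths(out$partners)) / 2
  expect_equal(total, nrow(tr$pairs))
  expect_equal(sum(out$classified$role == "secondary") +
                 sum(out$classified$role == "tertiary"), nrow(tr$pairs))
})

test_that("two separate triples entered as two pairs each survive decomposition", {
  # conserved triplets around the central pseudoknot: hubs unspecified in
  # the source scheme, here U12/U13 hold both partners
  pairs <- data.frame(i = c(12L, 12L, 13L, 13L),
                      j = c(22L, 912L, 20L, 914L))
  h <- enforce_unique_membership(assemble_helices(pairs, NULL, 920))$helices
  cl <- classify_pair_roles(h, pairs)
  pt <- decompose_triples(cl, 920)
  expect_equal(sum(lengths(pt)) / 2, 4)
  expect_setequal(pt[[12]], c(22L, 912L))
  expect_setequal(pt[[13]], c(20L, 914L))
})

test_that("a residue with more than three partners triggers the anomaly warning", {
  pairs <- data.frame(i = rep(5L, 4), j = c(10L, 20L, 30L, 40L))
  h <- enforce_unique_membership(assemble_helices(pairs, NULL, 40))$helices
  cl <- classify_pair_roles(h, pairs)
  expect_warning(pt <- decompose_triples(cl, 40), "anomaly")
  expect_length(pt[[5]], 4)
})

test_that("domain assignment labels ranges and rejects overlaps", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "dom.yaml")
  writeLines(c("domains:",
               "  - name: A", "    ranges: [[1, 10]]",
               "  - name: B", "    ranges: [[11, 20]]"), p)
  sc <- read_domain_scheme(p)
  d <- assign_domains(20, sc)
  expect_equal(d, rep(c("A", "B"), each = 10))
  expect_equal(assign_domains(5, NULL), rep("unassigned", 5))
  writeLines(c("domains:",
               "  - name: A", "    ranges: [[1, 10]]",
               "  - name: B", "    ranges: [[5, 20]]"), p)
  expect_error(assign_domains(20, read_domain_scheme(p)), "overlapping")
})
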