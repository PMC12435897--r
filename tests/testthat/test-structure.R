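two_res_complex <- function(gap) {
  lig <- data.frame(resno = 1L, resid = "ALA", elety = "CA",
                    x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  rec <- data.frame(resno = 1L, resid = "GLY", elety = "CA",
                    x = gap, y = 0, z = 0, stringsAsFactors = FALSE)
  complex_structure("pairX", lig, rec, c("1" = "NTc.Cm1"),
                    c("1" = "1x22"))
}

test_that("contact detection applies the heavy-atom distance cutoff", {
  cx <- two_res_complex(4.0)
  expect_equal(nrow(detect_contacts(cx, 5.0)), 1L)
  expect_equal(nrow(detect_contacts(cx, 3.0)), 0L)
  ct <- detect_contacts(cx, 5.0)
  expect_equal(ct$min_dist, 4.0)
  expect_identical(ct$ccn, "NTc.Cm1")
  expect_identical(ct$crn, "1x22")
})

test_that("contact sets equal the brute-force all-pairs scan", {
  set.seed(77)
  for (i in 1:12) {
    cx <- random_complex()
    got <- detect_contacts(cx, 5.0)
    want <- brute_force_contacts(cx, 5.0)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got[, c("ccn", "crn", "n_atom_pairs")],
                   want[, c("ccn", "crn", "n_atom_pairs")],
                   ignore_attr = TRUE)
      expect_equal(got$min_dist, want$min_dist, tolerance = 1e-9)
    }
  }
})

test_that("structures load protein-only and hydrogen-free from PDB", {
  spec <- generator_spec(seed = 5)
  cx <- make_toy_complex(spec)$cx
  path <- tempfile(fileext = ".pdb")
  write_complex_pdb(cx, path)
  # splice in a water record
  lines <- readLines(path)
  wat <- "HETATM 9999  O   HOH A 900      99.000  99.000  99.000  1.00  0.00           O"
  writeLines(append(lines, wat, after = length(lines) - 2L), path)
  back <- load_complex(path, chains = c(ligand = "A", receptor = "B"),
                       cx$ligand_labels, cx$receptor_labels)
  expect_equal(nrow(back$ligand), nrow(cx$ligand))
  expect_equal(nrow(back$receptor), nrow(cx$receptor))
  expect_false(any(back$ligand$resid == "HOH"))
  expect_error(load_complex(path, chains = c(ligand = "A",
                                             receptor = "Z"),
                            cx$ligand_labels, cx$receptor_labels),
               "chain Z")
})

test_that("fingerprints hold unique pairs with composite OR columns", {
  c1 <- data.frame(complex_id = "a", ccn = c("B1.1", "B1.2"),
                   crn = c("1x22", "1x23"), min_dist = 4,
                   n_atom_pairs = 1L, stringsAsFactors = FALSE)
  c2 <- data.frame(complex_id = "b", ccn = "B1.1", crn = "1x22",
                   min_dist = 4, n_atom_pairs = 1L,
                   stringsAsFactors = FALSE)
  c3 <- data.frame(complex_id = "c", ccn = "B1.3", crn = "1x24",
                   min_dist = 4, n_atom_pairs = 1L,
                   stringsAsFactors = FALSE)
  fp <- build_fingerprint(list(a = c1, b = c2, c = c3))
  expect_equal(nrow(fp$pairs), 3L)
  expect_equal(sum(fp$presence[, "a"] & fp$presence[, "b"]), 1L)
  expect_error(build_fingerprint(list(a = c1, a = c2)), "duplicate")

  # composite: pair present in any member is present in the group
  fpc <- build_fingerprint(list(a = c1, b = c2, c = c3),
                           composites = list(ab = c("a", "b")))
  expect_identical(colnames(fpc$presence), c("c", "ab"))
  expect_true(fpc$presence["B1.2|1x23", "ab"])
  expect_true(fpc$presence["B1.1|1x22", "ab"])
})

test_that("fingerprint algebra holds on randomized fixtures", {
  set.seed(31)
  lig_pool <- paste0("B3.", 1:8)
  rec_pool <- paste0("2x", 40:49)
  for (i in 1:10) {
    sets <- lapply(1:5, function(k) {
      random_contact_set(paste0("c", k), sample(3:10, 1), lig_pool,
                         rec_pool)
    })
    names(sets) <- paste0("c", 1:5)
    fp <- build_fingerprint(sets)
    union_keys <- unique(unlist(lapply(sets, function(d) {
      paste(d$ccn, d$crn, sep = "|")
    })))
    # row count equals the union of unique pairs
    expect_equal(nrow(fp$pairs), length(union_keys))
    # conserved + complement partition all rows
    scores_l <- stats::setNames(runif(length(lig_pool)), lig_pool)
    scores_r <- stats::setNames(runif(length(rec_pool)), rec_pool)
    cc <- conserved_contacts(fp, scores_l, scores_r, 0.5)
    expect_equal(nrow(cc$conserved) + nrow(cc$complement),
                 nrow(fp$pairs))
    expect_equal(cc$pct_instances + cc$pct_instances_complement, 100)
    # composite column is the OR of its members
    fpc <- build_fingerprint(sets, composites = list(g = c("c1", "c2")))
    expect_identical(
      unname(fpc$presence[, "g"]),
      unname(fp$presence[, "c1"] | fp$presence[, "c2"]))
  }
})

test_that("conserved-contact filter demands both sides at threshold", {
  c1 <- data.frame(complex_id = "a", ccn = c("B1.1", "B1.2", "B1.3"),
                   crn = c("1x22", "1x23", "1x24"), min_dist = 4,
                   n_atom_pairs = 1L, stringsAsFactors = FALSE)
  fp <- build_fingerprint(list(a = c1))
  lig <- c(B1.1 = 0.9, B1.2 = 0.49, B1.3 = 0.9)
  rec <- c(`1x22` = 0.9, `1x23` = 0.9, `1x24` = 0.50)
  out <- conserved_contacts(fp, lig, rec, 0.5)
  expect_identical(out$conserved$ccn, c("B1.1", "B1.3"))
  # one side at 0.49 is excluded: the rule is strict on both sides
  expect_true("B1.2" %in% out$complement$ccn)
  expect_equal(out$pct_unique, 100 * 2 / 3)
})

test_that("consensus rules separate CC and CXC contact sets", {
  lig_pool <- paste0("B3.", 1:6)
  rec_pool <- paste0("2x", 40:45)
  mk <- function(id, rows) {
    data.frame(complex_id = id, ccn = lig_pool[rows],
               crn = rec_pool[rows], min_dist = 4, n_atom_pairs = 1L,
               stringsAsFactors = FALSE)
  }
  # pair 1: 3/5 CC + 0/3 CXC -> CC consensus
  # pair 2: 3/5 CC + 1/3 CXC -> neither
  # pair 3: 0/5 CC + 2/3 CXC -> CXC consensus
  sets <- list(cc1 = mk("cc1", c(1, 2)), cc2 = mk("cc2", c(1, 2)),
               cc3 = mk("cc3", c(1, 2)), cc4 = mk("cc4", 4),
               cc5 = mk("cc5", 4),
               xc1 = mk("xc1", c(2, 3)), xc2 = mk("xc2", 3),
               xc3 = mk("xc3", 5))
  tags <- c(cc1 = "CC", cc2 = "CC", cc3 = "CC", cc4 = "CC", cc5 = "CC",
            xc1 = "CXC", xc2 = "CXC", xc3 = "CXC")
  fp <- build_fingerprint(sets, subfamilies = tags)
  out <- consensus_subfamily_contacts(fp)
  expect_equal(out$min_cc, 3L)
  expect_equal(out$min_cxc, 2L)
  expect_identical(out$cc$ccn, "B3.1")
  expect_identical(out$cxc$ccn, "B3.3")
  # exclusivity: sets are disjoint
  expect_length(intersect(paste(out$cc$ccn, out$cc$crn),
                          paste(out$cxc$ccn, out$cxc$crn)), 0)
  fp_untagged <- build_fingerprint(sets)
  expect_error(consensus_subfamily_contacts(fp_untagged), "untagged")
})

test_that("preserved-variable filter uses strict presence and one low side", {
  lig_pool <- paste0("B3.", 1:3)
  rec_pool <- paste0("2x", 40:42)
  sets <- lapply(1:16, function(k) {
    rows <- if (k <= 9) 1L else if (k <= 12) 2L else 3L
    # pair1 in 9 complexes, pair2 in 3, pair3 in 4... plus pair3 in all
    data.frame(complex_id = paste0("c", k),
               ccn = c(lig_pool[rows], "B3.3"),
               crn = c(rec_pool[rows], "2x42"), min_dist = 4,
               n_atom_pairs = 1L, stringsAsFactors = FALSE)
  })
  names(sets) <- paste0("c", 1:16)
  fp <- build_fingerprint(sets)
  lig <- c(B3.1 = 0.3, B3.2 = 0.3, B3.3 = 0.9)
  rec <- c(`2x40` = 0.9, `2x41` = 0.9, `2x42` = 0.9)
  out <- preserved_variable_contacts(fp, lig, rec, min_complexes = 8)
  # pair1: 9/16 with one side 0.3 -> retained
  expect_true("B3.1" %in% out$ccn)
  # pair2: 3/16 (not > 8) -> excluded despite low conservation
  expect_false("B3.2" %in% out$ccn)
  # pair3: 16/16 but both sides 0.9 -> excluded
  expect_false("B3.3" %in% out$ccn)

  # boundary: exactly 8 of 16 fails the strict inequality
  fp8 <- build_fingerprint(sets[1:8])
  out8 <- preserved_variable_contacts(fp8, lig, rec, min_complexes = 8)
  expect_equal(nrow(out8), 0L)
})

test_that("diversification fractions normalize over filtered contacts", {
  sets <- list(
    a = data.frame(complex_id = "a",
                   ccn = c("NTc.Cm1", "NTc.Cm2", "B3.1"),
                   crn = c("1x22", "1x23", "2x40"), min_dist = 4,
                   n_atom_pairs = 1L, stringsAsFactors = FALSE),
    b = data.frame(complex_id = "b", ccn = "B3.1", crn = "2x40",
                   min_dist = 4, n_atom_pairs = 1L,
                   stringsAsFactors = FALSE))
  fp <- build_fingerprint(sets)
  lig <- c(NTc.Cm1 = 0.1, NTc.Cm2 = 0.1, B3.1 = 0.1)
  rec <- c(`1x22` = 0.1, `1x23` = 0.1, `2x40` = 0.1)
  out <- diversification_by_region(fp, lig, rec,
                                   presence_max_fraction = 0.75)
  # B3.1|2x40 is in 2/2 complexes -> filtered out; the rest are NTc
  expect_equal(out$n_filtered, 2L)
  expect_equal(out$ligand_sse$fraction[out$ligand_sse$sse == "NTc"], 1)
  expect_equal(sum(out$sse_pair$fraction), 1)
  expect_equal(sum(out$ligand_sse$fraction), 1)
})

test_that("pairwise comparison reports shared percentage and identity", {
  lig_pool <- paste0("B3.", 1:70)
  rec_pool <- paste0("2x", 40:99)
  mk <- function(id, rows) {
    data.frame(complex_id = id, ccn = lig_pool[rows],
               crn = rec_pool[rows], min_dist = 4, n_atom_pairs = 1L,
               stringsAsFactors = FALSE)
  }
  # 11 shared contacts of 61 in the union (36 + 36 - 11)
  a <- mk("cxA", 1:36)
  b <- mk("cxB", c(1:11, 37:61))
  fp <- build_fingerprint(list(cxA = a, cxB = b))
  out <- pairwise_complex_comparison(fp)
  expect_equal(out$n_shared, 11L)
  expect_equal(out$n_union, 61L)
  expect_equal(out$pct_shared, 18)  # round(100 * 11/61) half-up

  # identical sets share 100%, disjoint sets 0%
  fp_same <- build_fingerprint(list(x = mk("x", 1:5), y = mk("y", 1:5)))
  expect_equal(pairwise_complex_comparison(fp_same)$pct_shared, 100)
  fp_disj <- build_fingerprint(list(x = mk("x", 1:5), y = mk("y", 6:9)))
  expect_equal(pairwise_complex_comparison(fp_disj)$pct_shared, 0)

  # interface identity averages ligand and receptor identities over
  # interface positions, gaps counting as mismatches
  labs <- c("B3.1", "B3.2", "B3.3")
  ligaln <- tiny_alignment(c(L1 = "ACD", L2 = "AC-"), labels = labs)
  recaln <- tiny_alignment(c(R1 = "KKK", R2 = "KQW"),
                           labels = c("2x40", "2x41", "2x42"),
                           role = "receptor")
  sets <- list(p = mk("p", 1:3), q = mk("q", 1:2))
  fp2 <- build_fingerprint(
    sets,
    paralogs = data.frame(column = c("p", "q"),
                          ligand = c("L1", "L2"),
                          receptor = c("R1", "R2"),
                          stringsAsFactors = FALSE))
  out2 <- pairwise_complex_comparison(fp2, ligaln, recaln)
  # ligand identity 2/3; receptor identity 1/3 -> mean 50
  expect_equal(out2$pct_identity, 50)
})

test_that("anchored superposition is exact under rigid motion", {
  spec <- generator_spec(seed = 9)
  a <- make_toy_complex(spec, "A")$cx
  # B = copy of A: all deviations zero
  r0 <- anchored_rmsd(a, a)
  expect_equal(max(r0$per_position$deviation), 0, tolerance = 1e-9)

  # B = rigidly moved copy: superposition removes the motion entirely
  b <- rigid_transform(a, angles = c(0.4, -1.1, 0.7),
                       translation = c(12, -5, 30))
  r1 <- anchored_rmsd(a, b)
  expect_equal(r1$anchor_rmsd, 0, tolerance = 1e-8)
  expect_equal(r1$mean_deviation, 0, tolerance = 1e-8)

  # planted displacement: one ligand Calpha moved 2 A, anchors untouched
  b2 <- a
  b2$ligand$z[4] <- b2$ligand$z[4] + 2
  moved_label <- unname(a$ligand_labels[as.character(a$ligand$resno[4])])
  r2 <- anchored_rmsd(a, b2)
  dev <- r2$per_position$deviation
  names(dev) <- r2$per_position$label
  expect_equal(unname(dev[moved_label]), 2, tolerance = 1e-6)
  expect_true(all(dev[setdiff(names(dev), moved_label)] < 1e-6))

  # fewer than three shared anchors is an error
  tiny <- a
  tiny$receptor <- tiny$receptor[1:2, ]
  expect_error(anchored_rmsd(tiny, tiny), "at least 3")
})

test_that("anchor fit is optimal against random rigid placements", {
  spec <- generator_spec(seed = 13)
  a <- make_toy_complex(spec, "A")$cx
  # noisy copy in the same frame: identity is a near-optimal placement,
  # and the least-squares fit must beat every random rigid placement
  set.seed(99)
  b <- a
  for (ch in c("ligand", "receptor")) {
    b[[ch]]$x <- b[[ch]]$x + rnorm(nrow(b[[ch]]), 0, 0.4)
    b[[ch]]$y <- b[[ch]]$y + rnorm(nrow(b[[ch]]), 0, 0.4)
    b[[ch]]$z <- b[[ch]]$z + rnorm(nrow(b[[ch]]), 0, 0.4)
  }
  fit <- anchored_rmsd(a, b)
  anchor_rmsd_of <- function(cx) {
    ca_a <- a$receptor[a$receptor$elety == "CA", c("x", "y", "z")]
    ca_b <- cx$receptor[cx$receptor$elety == "CA", c("x", "y", "z")]
    sqrt(mean(rowSums((as.matrix(ca_a) - as.matrix(ca_b))^2)))
  }
  for (i in 1:100) {
    jig <- rigid_transform(b, angles = rnorm(3, 0, 0.05),
                           translation = rnorm(3, 0, 0.5))
    expect_gte(anchor_rmsd_of(jig) + 1e-9, fit$anchor_rmsd)
  }
})

test_that("B-factor annotation writes absolute values that reread", {
  spec <- generator_spec(seed = 21)
  cx <- make_toy_complex(spec)$cx
  lab <- unname(cx$receptor_labels[1])
  path <- tempfile(fileext = ".pdb")
  annotate_bfactor(cx, stats::setNames(-1.5, lab), path,
                   transform = "abs")
  pdb <- bio3d::read.pdb(path)
  b_by_res <- tapply(pdb$atom$b, paste(pdb$atom$chain, pdb$atom$resno),
                     unique)
  expect_equal(unname(b_by_res[["B 1"]]), 1.5)
  # unmapped residues carry zero
  expect_equal(unname(b_by_res[["A 1"]]), 0)
})
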