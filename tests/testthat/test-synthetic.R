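test_that("generation is bit-identical under one seed", {
  spec <- generator_spec(seed = 6,
                         family = list(n_paralogs = c(CC = 4, CXC = 3),
                                       n_orthologs = 3))
  expect_identical(make_family_alignment(spec),
                   make_family_alignment(spec))
  expect_identical(make_motif_regions(spec), make_motif_regions(spec))
  expect_identical(make_toy_complex(spec), make_toy_complex(spec))
  expect_identical(make_tables(spec), make_tables(spec))
  # and differs under another seed
  spec2 <- generator_spec(seed = 7,
                          family = list(n_paralogs = c(CC = 4, CXC = 3),
                                        n_orthologs = 3))
  expect_false(identical(make_family_alignment(spec)$aln$seqs,
                         make_family_alignment(spec2)$aln$seqs))
})

test_that("family truth tables describe the generated columns", {
  spec <- generator_spec(
    seed = 8, family = list(n_paralogs = c(CC = 8, CXC = 6),
                            n_orthologs = 30,
                            discriminability = c(1, 0)))
  fam <- make_family_alignment(spec)
  m <- aln_matrix(fam$aln)
  tags <- fam$aln$records$subfamily
  # conserved columns carry a single residue; anchor is cysteine
  cons <- fam$truth$column[fam$truth$type == "conserved"]
  for (j in cons) expect_equal(length(unique(m[, j])), 1L)
  anchor_col <- which(fam$aln$labels == "CX.1")
  expect_true(all(m[, anchor_col] == "C"))
  # d = 1: perfectly separable marker residues
  j1 <- fam$truth$column[which(fam$truth$divergence == 1)]
  expect_equal(length(unique(m[tags == "CC", j1])), 1L)
  expect_length(intersect(unique(m[tags == "CC", j1]),
                          unique(m[tags == "CXC", j1])), 0)
  # d = 0: exchangeable, class frequencies converge (law of large numbers)
  j0 <- fam$truth$column[which(fam$truth$divergence == 0)]
  r1 <- fam$truth$r1[j0]
  f_cc <- mean(m[tags == "CC", j0] == r1)
  f_cxc <- mean(m[tags == "CXC", j0] == r1)
  expect_equal(f_cc, 0.5, tolerance = 0.12)
  expect_equal(f_cxc, 0.5, tolerance = 0.12)
})

test_that("planted motif counts are exact and backgrounds are clean", {
  spec <- generator_spec(seed = 10,
                         regions = list(presence_rates = c(0.6, 0.0),
                                        n_paralogs = 4,
                                        n_orthologs = 10))
  mr <- make_motif_regions(spec)
  expect_equal(mr$truth$n_planted,
               as.integer(ceiling(mr$truth$rate * 10)))
  for (i in seq_len(nrow(mr$truth))) {
    tr <- mr$truth[i, ]
    hits <- match_fragment(tr$motif, mr$regions[[tr$paralog]])
    expect_equal(sum(hits), tr$n_planted)
    if (tr$rate == 0) expect_false(any(hits))
  }
})

test_that("planted SLiM sets are recovered end-to-end over many specs", {
  for (s in 1:25) {
    spec <- generator_spec(
      seed = 1000 + s,
      regions = list(
        n_paralogs = 5, n_orthologs = sample(4:12, 1),
        presence_rates = round(runif(5), 2)))
    mr <- make_motif_regions(spec)
    fc <- fragment_conservation(mr$regions)
    for (i in seq_len(nrow(mr$truth))) {
      tr <- mr$truth[i, ]
      realized <- tr$n_planted / tr$n_orthologs
      row <- fc[fc$pattern == tr$motif & fc$paralog == tr$paralog, ]
      if (realized >= 0.5) {
        expect_true(row$putative_slim,
                    label = paste("seed", 1000 + s, tr$motif))
      } else if (nrow(row)) {
        expect_false(row$putative_slim,
                     label = paste("seed", 1000 + s, tr$motif))
      }
    }
  }
})

test_that("toy complexes realize exactly the planted contacts", {
  for (s in 1:10) {
    spec <- generator_spec(seed = 500 + s,
                           complex = list(n_contacts = 3L))
    tc <- make_toy_complex(spec)
    got <- detect_contacts(tc$cx, spec$complex$cutoff)
    expect_identical(got[, c("ccn", "crn")], tc$truth,
                     ignore_attr = TRUE)
    # planted pairs sit 1 A inside the cutoff, everything else beyond
    expect_true(all(got$min_dist <= spec$complex$cutoff - 1 + 1e-9))
  }
  # empty plant gives zero contacts
  spec0 <- generator_spec(seed = 1, complex = list(n_contacts = 0L))
  expect_equal(nrow(detect_contacts(make_toy_complex(spec0)$cx, 5)), 0L)
})

test_that("generated tables carry their planned summaries", {
  spec <- generator_spec(seed = 12)
  tabs <- make_tables(spec)

  mapped <- map_variants(tabs$variants$data, tabs$variants$label_maps)
  got <- interface_variant_summary(mapped, tabs$variants$interface)
  for (g in tabs$variants$truth$gene) {
    want <- tabs$variants$truth$interface_total[
      tabs$variants$truth$gene == g]
    have <- got$total[got$gene == g]
    if (length(have)) expect_equal(have, want) else expect_equal(want, 0)
  }

  ms <- mutscan_position_summary(tabs$mutscan$data)
  expect_equal(ms$substitutions$mean_enrichment,
               tabs$mutscan$truth$substitutions$mean_enrichment)
  expect_equal(ms$positions$abs_mean_log2,
               unname(tabs$mutscan$truth$positions$abs_mean_log2),
               tolerance = 1e-12)

  m <- filter_network(tabs$network$data)
  truth_m <- tabs$network$truth$matrix
  expect_identical(m[rownames(truth_m), colnames(truth_m)], truth_m)
  coup <- subfamily_coupling_test(m, tabs$network$subfamilies)
  expect_identical(coup$table + 0, tabs$network$truth$table + 0)
})
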