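edge <- function(l, r, s, e, ref) {
  data.frame(ligand = l, receptor = r, strength = as.integer(s),
             evidence = e, reference = ref, stringsAsFactors = FALSE)
}

test_that("strength and evidence filters gate the interaction matrix", {
  edges <- rbind(edge("L1", "R1", 3, "A", "p1"),
                 edge("L1", "R2", 1, "A", "p2"),
                 edge("L2", "R1", 2, "D", "p3"),
                 edge("L2", "R2", 2, "C", "p4"))
  m <- filter_network(edges)
  expect_true(m["L1", "R1"])    # strong + quantitative
  expect_false(m["L1", "R2"])   # strength 1 fails even at grade A
  expect_false(m["L2", "R1"])   # grade D fails
  expect_true(m["L2", "R2"])    # boundary: strength 2, grade C passes

  # exact-grade mode keeps only the stated grade
  m2 <- filter_network(edges, evidence = "C", evidence_mode = "exact")
  expect_false(m2["L1", "R1"])
  expect_true(m2["L2", "R2"])

  # raising min_strength never adds edges
  m3 <- filter_network(edges, min_strength = 3)
  expect_true(all(m >= m3))
})

test_that("the matrix equals a brute-force per-pair evaluation", {
  set.seed(41)
  for (i in 1:10) {
    n <- 25
    edges <- data.frame(
      ligand = sample(paste0("L", 1:5), n, replace = TRUE),
      receptor = sample(paste0("R", 1:4), n, replace = TRUE),
      strength = sample(0:3, n, replace = TRUE),
      evidence = sample(c("A", "B", "C", "D"), n, replace = TRUE),
      reference = paste0("p", 1:n), stringsAsFactors = FALSE)
    m <- filter_network(edges)
    for (l in rownames(m)) {
      for (r in colnames(m)) {
        sub <- edges[edges$ligand == l & edges$receptor == r, ]
        want <- any(sub$strength >= 2 & sub$evidence %in% c("A", "B", "C"))
        expect_identical(unname(m[l, r]), want)
      }
    }
  }
})

test_that("pair grouping follows subfamily identity then network overlap", {
  edges <- rbind(edge("CCL3", "CCR5", 3, "A", "p1"),
                 edge("CCL3", "CCR3", 3, "A", "p2"),
                 edge("CCL15", "CCR1", 3, "A", "p3"),
                 edge("CCL15", "CCR3", 3, "A", "p4"),
                 edge("CCL20", "CCR6", 3, "A", "p5"),
                 edge("CXCL8", "CXCR2", 3, "A", "p6"))
  m <- filter_network(edges)
  subf <- c(CCL3 = "CC", CCL15 = "CC", CCL20 = "CC", CXCL8 = "CXC",
            CCR5 = "CC", CCR3 = "CC", CCR1 = "CC", CCR6 = "CC",
            CXCR2 = "CXC")
  # different subfamilies -> group 1
  expect_equal(as.integer(partner_overlap_group(
    c("CCL3", "CCR5"), c("CXCL8", "CXCR2"), m, subf)), 1L)
  # same subfamily, ligands share CCR3 -> group 3
  expect_equal(as.integer(partner_overlap_group(
    c("CCL3", "CCR5"), c("CCL15", "CCR1"), m, subf)), 3L)
  # same subfamily, no shared partners -> group 2
  expect_equal(as.integer(partner_overlap_group(
    c("CCL15", "CCR1"), c("CCL20", "CCR6"), m, subf)), 2L)
  # symmetric in pair order
  expect_equal(as.integer(partner_overlap_group(
    c("CCL15", "CCR1"), c("CCL3", "CCR5"), m, subf)), 3L)
  expect_error(partner_overlap_group(
    c("CCL3", "CCR5"), c("XXX", "CCR5"), m, subf), "unknown")
})

test_that("subfamily coupling chi-squared matches the closed form", {
  # contrived matrix reproducing a 2x2 of (10, 2, 3, 9)
  tab <- rbind(like = c(interacting = 10, not = 2),
               unlike = c(interacting = 3, not = 9))
  a <- 10; b <- 2; cc <- 3; d <- 9
  n <- a + b + cc + d
  chi_closed <- n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  ct <- stats::chisq.test(tab, correct = FALSE)
  expect_equal(unname(ct$statistic), chi_closed, tolerance = 1e-10)

  # block-diagonal interaction (like pairs only) gives extreme coupling
  ligs <- c(paste0("sCCL", 1:4), paste0("sCXCL", 1:4))
  recs <- c(paste0("sCCR", 1:4), paste0("sCXCR", 1:4))
  tags <- setNames(rep(c("CC", "CXC", "CC", "CXC"), each = 4),
                   c(ligs, recs))
  m <- outer(tags[ligs], tags[recs], "==")
  dimnames(m) <- list(ligs, recs)
  out <- subfamily_coupling_test(m, tags)
  expect_lt(out$p_value, 1e-10)
  expect_equal(out$table["like", "not"], 0)
  expect_equal(out$table["unlike", "interacting"], 0)

  # empty margin flagged with undefined p
  m0 <- m; m0[] <- FALSE
  out0 <- subfamily_coupling_test(m0, tags)
  expect_identical(out0$flag, "empty_margin")
  expect_true(is.na(out0$p_value))
})

test_that("independence-sampled networks give roughly uniform p-values", {
  set.seed(53)
  ligs <- paste0("L", 1:12)
  recs <- paste0("R", 1:10)
  tags <- setNames(c(rep(c("CC", "CXC"), 6), rep(c("CC", "CXC"), 5)),
                   c(ligs, recs))
  ps <- replicate(60, {
    m <- matrix(runif(120) < 0.4, 12, 10, dimnames = list(ligs, recs))
    subfamily_coupling_test(m, tags)$p_value
  })
  ps <- ps[!is.na(ps)]
  # no systematic inflation under the null
  expect_gt(mean(ps > 0.05), 0.75)
  expect_gt(min(ps), 0)
})

test_that("edge lists round-trip through TSV with uniqueness checks", {
  edges <- rbind(edge("L1", "R1", 3, "A", "p1"),
                 edge("L1", "R1", 2, "B", "p2"))
  path <- tempfile(fileext = ".tsv")
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  back <- read_network_edges(path)
  expect_identical(back, edges)
  dup <- rbind(edges, edges[1, ])
  utils::write.table(dup, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_network_edges(path), "duplicate")
})
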