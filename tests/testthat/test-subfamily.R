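balanced_tags <- function(n_cc, n_cxc) {
  stats::setNames(c(rep("CC", n_cc), rep("CXC", n_cxc)),
                  paste0("s", seq_len(n_cc + n_cxc)))
}

test_that("down-sampling balances classes and splits by floor(fraction)", {
  part <- downsample_and_split(balanced_tags(421, 421), 0.8, seed = 1)
  expect_equal(part$per_class, 421L)
  expect_equal(length(part$train), 672L)
  expect_equal(length(part$test), 170L)

  part2 <- downsample_and_split(balanced_tags(226, 226), 0.8, seed = 1)
  expect_equal(length(part2$train), 360L)
  expect_equal(length(part2$test), 92L)

  # majority class is reduced to the minority count
  part3 <- downsample_and_split(balanced_tags(600, 421), 0.8, seed = 2)
  expect_equal(part3$per_class, 421L)
  expect_equal(length(part3$train) + length(part3$test), 842L)

  expect_error(downsample_and_split(balanced_tags(10, 10), 1.0),
               "degenerate")
  expect_error(
    downsample_and_split(stats::setNames(c("CC", "CXC"), c("a", "b")),
                         0.8), "at least 2")
  # reproducible from the seed
  expect_identical(downsample_and_split(balanced_tags(50, 40), 0.8, 9),
                   downsample_and_split(balanced_tags(50, 40), 0.8, 9))
})

test_that("coverage adjustment retries seeds until test residues are seen", {
  tags <- balanced_tags(10, 10)
  # two sequences carry W; some partitions put both in test
  column <- stats::setNames(c("W", "W", rep("A", 8), rep("G", 10)),
                            names(tags))
  part <- ensure_residue_coverage(column, tags, 0.8, seed = 1)
  expect_false(is.null(part))
  expect_true(all(unique(column[part$test]) %in%
                    unique(column[part$train])))

  # one shared residue: first partition already covers
  flat <- stats::setNames(rep("A", 20), names(tags))
  p0 <- ensure_residue_coverage(flat, tags, 0.8, seed = 5)
  expect_equal(p0$seed_used, 5L)

  # pairwise-distinct residues: any non-empty test set contains unseen
  # symbols, so no partition can cover
  distinct <- stats::setNames(AA_ALPHABET20, names(tags))
  expect_null(ensure_residue_coverage(distinct, tags, 0.8, seed = 1,
                                      max_attempts = 20))
})

test_that("a perfectly separable column scores 1 and a constant one 0.5", {
  ids <- paste0("s", 1:40)
  records <- data.frame(seq_id = ids, paralog = ids, species = "human",
                        subfamily = rep(c("CC", "CXC"), each = 20),
                        role = "ligand", stringsAsFactors = FALSE)
  seqs <- stats::setNames(
    paste0(rep(c("P", "E"), each = 20), rep("A", 40)), ids)
  aln <- labeled_alignment(records, seqs, c("CX.4", "B1.1"))
  sc <- subfamily_scores(aln, seeds = 1:3)
  expect_equal(sc$mean_accuracy[sc$label == "CX.4"], 1.0)
  expect_true(sc$predictive[sc$label == "CX.4"])
  # single-symbol column: degenerate, majority-class accuracy on a
  # balanced test set is 0.5
  expect_equal(sc$mean_accuracy[sc$label == "B1.1"], 0.5)
  expect_identical(sc$flag[sc$label == "B1.1"], "degenerate")
  # split arithmetic recorded: train + test = 2 x per-class size
  expect_equal(attr(sc, "n_train") + attr(sc, "n_test"),
               2L * attr(sc, "per_class"))
})

test_that("null columns calibrate near 0.5 and planted columns are found", {
  # exchangeable columns: big enough family for a test set of >= 80
  spec <- generator_spec(
    seed = 101,
    family = list(n_paralogs = c(CC = 11, CXC = 10), n_orthologs = 19,
                  discriminability = c(1.0, 0.6), gap_rate = 0))
  fam <- make_family_alignment(spec)
  sc <- subfamily_scores(fam$aln, seeds = 1:3)
  expect_gte(attr(sc, "n_test"), 80L)

  neutral <- fam$truth$label[fam$truth$type == "neutral"]
  null_mean <- mean(sc$mean_accuracy[sc$label %in% neutral])
  expect_gte(null_mean, 0.45)
  expect_lte(null_mean, 0.55)

  # the planted fully-divergent column ranks first, like the
  # subfamily-defining "X" residue between the N-terminal cysteines
  planted <- fam$truth$label[which(fam$truth$divergence == 1.0)]
  expect_identical(sc$label[which.max(sc$mean_accuracy)], planted)
  expect_gte(sc$mean_accuracy[sc$label == planted], 0.95)

  # determinism: same seeds give identical scores
  sc2 <- subfamily_scores(fam$aln, seeds = 1:3)
  expect_identical(sc, sc2)
})

test_that("divergent columns are recovered as predictive across seeds", {
  # class-conditional total variation 0.6 should clear the 0.75 flag in
  # nearly every regenerated family
  hits <- vapply(1:15, function(s) {
    spec <- generator_spec(
      seed = 300 + s,
      family = list(n_paralogs = c(CC = 11, CXC = 10),
                    n_orthologs = 19, discriminability = 0.6,
                    gap_rate = 0))
    fam <- make_family_alignment(spec)
    lab <- fam$truth$label[!is.na(fam$truth$divergence)]
    sc <- subfamily_scores(fam$aln, positions = lab, seeds = 1:3)
    sc$mean_accuracy >= 0.75
  }, NA)
  expect_gte(mean(hits), 0.95)
})

test_that("prediction probabilities track the training classes", {
  ids <- paste0("s", 1:40)
  records <- data.frame(seq_id = ids, paralog = ids, species = "human",
                        subfamily = rep(c("CC", "CXC"), each = 20),
                        role = "ligand", stringsAsFactors = FALSE)
  seqs <- stats::setNames(
    paste0(rep(c("P", "E"), each = 20), rep("A", 40)), ids)
  aln <- labeled_alignment(records, seqs, c("CX.4", "B1.1"))

  # query carrying the CC-exclusive residue at the separable column
  pp <- prediction_probabilities(c("CX.4" = "P", "B1.1" = "A"), aln,
                                 seeds = 1:3)
  expect_lt(pp$probability[pp$label == "CX.4"], 0.05)
  # query residue absent from both classes is flagged, not imputed
  pp2 <- prediction_probabilities(c("CX.4" = "W"), aln, seeds = 1:3)
  expect_true(is.na(pp2$probability))
  expect_identical(pp2$flag, "unseen")

  # replicate mean equals the hand-average of per-replicate values
  singles <- vapply(1:3, function(s) {
    prediction_probabilities(c("CX.4" = "P"), aln, n_replicates = 1L,
                             seeds = s)$probability
  }, 0)
  expect_equal(pp$probability[pp$label == "CX.4"], mean(singles))
})

test_that("interface character percentages count qualifying contacts", {
  probs <- data.frame(label = paste0("B1.", 1:6),
                      probability = c(0.9, 0.8, 0.95, 0.2, 0.5, 0.7),
                      stringsAsFactors = FALSE)
  scores <- data.frame(label = paste0("B1.", 1:6),
                       mean_accuracy = c(0.9, 0.8, 0.9, 0.9, 0.9, 0.5),
                       stringsAsFactors = FALSE)
  # contacts at B1.1-5; B1.6 not a contact; B1.5 tied; B1.4 CC-like
  out <- classify_interface_character(probs, paste0("B1.", 1:5), scores)
  expect_equal(out$n_qualifying, 4L)
  expect_equal(out$n_tied, 1L)
  expect_equal(out$pct_cxc, 75)
  expect_equal(out$pct_cc, 25)
  expect_warning(
    classify_interface_character(probs, "B9.1", scores),
    "no qualifying")
})

test_that("engineered interfaces look more CXC-like than the whole chain", {
  # a synthetic viral-mimic query: CXC-typical residues only at its
  # contact positions, CC-typical elsewhere
  n <- 30
  ids <- paste0("s", seq_len(2 * n))
  records <- data.frame(seq_id = ids, paralog = ids, species = "human",
                        subfamily = rep(c("CC", "CXC"), each = n),
                        role = "ligand", stringsAsFactors = FALSE)
  n_pos <- 8
  labs <- paste0("H.", seq_len(n_pos))
  cc_res <- rep("P", n_pos)
  cxc_res <- rep("E", n_pos)
  seqs <- stats::setNames(c(
    replicate(n, paste(cc_res, collapse = "")),
    replicate(n, paste(cxc_res, collapse = ""))), ids)
  aln <- labeled_alignment(records, seqs, labs)
  contact_pos <- labs[1:3]
  query <- stats::setNames(ifelse(labs %in% contact_pos, "E", "P"), labs)
  pp <- prediction_probabilities(query, aln, seeds = 1:3)
  sc <- subfamily_scores(aln, seeds = 1:3)
  iface <- classify_interface_character(pp, contact_pos, sc)
  whole <- classify_interface_character(pp, labs, sc)
  expect_gt(iface$pct_cxc, whole$pct_cxc)
  expect_equal(iface$pct_cxc, 100)
})
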