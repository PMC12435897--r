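# small in-code fixtures shared across test files

tiny_records <- function(ids, subfamily = "CC", role = "ligand",
                         paralog = ids, species = "human") {
  data.frame(seq_id = ids, paralog = paralog,
             species = rep_len(species, length(ids)),
             subfamily = rep_len(subfamily, length(ids)),
             role = rep_len(role, length(ids)), stringsAsFactors = FALSE)
}

tiny_alignment <- function(seqs, labels = NULL, subfamily = "CC",
                           role = "ligand", reference_id = NULL) {
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  labeled_alignment(tiny_records(names(seqs), subfamily, role), seqs,
                    labels = labels, reference_id = reference_id)
}

# a random two-chain complex with several heavy atoms per residue,
# for brute-force contact comparisons
random_complex <- function(n_lig = 8, n_rec = 10, atoms_per_res = 3,
                           spread = 18) {
  mk <- function(n, offset) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      center <- stats::runif(3, 0, spread) + offset
      data.frame(resno = i, resid = "ALA",
                 elety = c("N", "CA", "C")[seq_len(atoms_per_res)],
                 x = center[1] + stats::rnorm(atoms_per_res, 0, 1),
                 y = center[2] + stats::rnorm(atoms_per_res, 0, 1),
                 z = center[3] + stats::rnorm(atoms_per_res, 0, 1),
                 stringsAsFactors = FALSE)
    }))
  }
  lig <- mk(n_lig, 0)
  rec <- mk(n_rec, 4)
  complex_structure("rand", lig, rec,
                    setNames(paste0("B3.", seq_len(n_lig)),
                             seq_len(n_lig)),
                    setNames(paste0("1x", 21 + seq_len(n_rec)),
                             seq_len(n_rec)))
}

# O(n_lig * n_rec * atoms^2) reference contact scan
brute_force_contacts <- function(cx, cutoff) {
  out <- list()
  for (i in unique(cx$ligand$resno)) {
    la <- cx$ligand[cx$ligand$resno == i, ]
    for (j in unique(cx$receptor$resno)) {
      ra <- cx$receptor[cx$receptor$resno == j, ]
      dmin <- Inf
      npair <- 0L
      for (a in seq_len(nrow(la))) {
        for (b in seq_len(nrow(ra))) {
          d <- sqrt(sum((unlist(la[a, c("x", "y", "z")]) -
                           unlist(ra[b, c("x", "y", "z")]))^2))
          if (d <= cutoff) npair <- npair + 1L
          dmin <- min(dmin, d)
        }
      }
      if (npair > 0L) {
        out[[length(out) + 1L]] <- data.frame(
          ccn = unname(cx$ligand_labels[as.character(i)]),
          crn = unname(cx$receptor_labels[as.character(j)]),
          min_dist = dmin, n_atom_pairs = npair,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) return(out)
  out <- out[order(out$ccn, out$crn), ]
  rownames(out) <- NULL
  out
}

# random contact sets over a fixed label pool, for fingerprint algebra
random_contact_set <- function(id, n, lig_pool, rec_pool) {
  pairs <- unique(data.frame(
    ccn = sample(lig_pool, n, replace = TRUE),
    crn = sample(rec_pool, n, replace = TRUE),
    stringsAsFactors = FALSE))
  cbind(complex_id = id, pairs, min_dist = 4.0,
        n_atom_pairs = 1L, stringsAsFactors = FALSE)
}
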