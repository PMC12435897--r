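#' Construct a two-chain complex structure
#'
#' Holds the protein-only, hydrogen-free atoms of a ligand (chemokine) and
#' receptor chain together with residue-to-label maps (CCN for the ligand,
#' CRN for the receptor) and subfamily tags. Toy complexes may be
#' Calpha-only; the contact engine treats any non-hydrogen atom record as
#' a heavy atom.
#'
#' @param complex_id identifier.
#' @param ligand,receptor data.frames with columns \code{resno},
#'   \code{resid} (residue name), \code{elety} (atom name), \code{x},
#'   \code{y}, \code{z} (coordinates in Angstrom).
#' @param ligand_labels,receptor_labels named character vectors mapping
#'   residue number (as character) to position label; must be injective.
#' @param subfamily named character vector
#'   \code{c(ligand = ..., receptor = ...)}.
#' @param composite_group optional group id for composite treatment.
#' @param modified_mask optional character vector of ligand labels whose
#'   residues are engineered (e.g. variant N-termini); consumers may skip
#'   these in ortholog-conservation annotation.
#' @return object of class \code{complex_structure}.
#' @export
complex_structure <- function(complex_id, ligand, receptor,
                              ligand_labels, receptor_labels,
                              subfamily = c(ligand = NA_character_,
                                            receptor = NA_character_),
                              composite_group = NA_character_,
                              modified_mask = character(0)) {
  chk <- function(df, what) {
    need <- c("resno", "resid", "elety", "x", "y", "z")
    if (!all(need %in% names(df))) {
      stop(what, " chain needs columns: ", paste(need, collapse = ", "))
    }
    if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
      stop("non-finite coordinates in ", what, " chain")
    }
    df
  }
  ligand <- chk(ligand, "ligand")
  receptor <- chk(receptor, "receptor")
  for (lm in list(ligand_labels, receptor_labels)) {
    if (anyDuplicated(lm[!is.na(lm)])) stop("label map not injective")
  }
  structure(list(complex_id = complex_id, ligand = ligand,
                 receptor = receptor, ligand_labels = ligand_labels,
                 receptor_labels = receptor_labels,
                 subfamily = subfamily, composite_group = composite_group,
                 modified_mask = modified_mask),
            class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  cat("complex_structure ", x$complex_id, ": ligand ",
      length(unique(x$ligand$resno)), " res / receptor ",
      length(unique(x$receptor$resno)), " res\n", sep = "")
  invisible(x)
}

#' Load a two-chain complex from a PDB file
#'
#' Reads the file with bio3d, trims to protein atoms (dropping waters,
#' cofactors and other heteroatoms) and removes hydrogens. Residues
#' without a label-map entry are retained in the chains but excluded from
#' labeled analyses; their count is recorded in attribute
#' \code{n_unmapped}.
#'
#' @param path PDB file.
#' @param chains named character vector \code{c(ligand = chainID,
#'   receptor = chainID)}.
#' @param ligand_labels,receptor_labels residue-number-to-label maps as in
#'   [complex_structure()].
#' @param complex_id identifier (defaults to the file stem).
#' @inheritParams complex_structure
#' @return a \code{complex_structure}.
#' @export
load_complex <- function(path, chains, ligand_labels, receptor_labels,
                         complex_id = sub("\\.pdb$", "", basename(path)),
                         subfamily = c(ligand = NA_character_,
                                       receptor = NA_character_),
                         composite_group = NA_character_) {
  pdb <- bio3d::read.pdb(path)
  prot <- bio3d::trim.pdb(pdb, bio3d::atom.select(pdb, "protein",
                                                  verbose = FALSE))
  atoms <- prot$atom
  atoms <- atoms[!grepl("^H", trimws(atoms$elety)) &
                   !(!is.na(atoms$elesy) & trimws(atoms$elesy) == "H"), ,
                 drop = FALSE]
  pull <- function(ch) {
    sel <- atoms$chain == ch
    if (!any(sel)) stop("chain ", ch, " absent from ", path)
    data.frame(resno = atoms$resno[sel], resid = atoms$resid[sel],
               elety = trimws(atoms$elety[sel]), x = atoms$x[sel],
               y = atoms$y[sel], z = atoms$z[sel],
               stringsAsFactors = FALSE)
  }
  lig <- pull(chains[["ligand"]])
  rec <- pull(chains[["receptor"]])
  cx <- complex_structure(complex_id, lig, rec, ligand_labels,
                          receptor_labels, subfamily, composite_group)
  n_unmapped <- sum(!as.character(unique(lig$resno)) %in%
                      names(ligand_labels)) +
    sum(!as.character(unique(rec$resno)) %in% names(receptor_labels))
  attr(cx, "n_unmapped") <- n_unmapped
  cx
}

cross_chain_distances <- function(a, b) {
  A <- as.matrix(a[, c("x", "y", "z")])
  B <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

#' Detect intermolecular residue-residue contacts
#'
#' A ligand residue and a receptor residue are in contact iff any pair of
#' their heavy atoms lies within the cutoff. Only residues with a label
#' map entry are reported; the number of dropped (unlabeled) residue
#' pairs is recorded in attribute \code{n_unlabeled_pairs}.
#'
#' @param cx a \code{complex_structure}.
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 5.0).
#' @return data.frame sorted by (ccn, crn) with columns
#'   \code{complex_id}, \code{ccn}, \code{crn}, \code{min_dist},
#'   \code{n_atom_pairs}.
#' @export
detect_contacts <- function(cx, cutoff = 5.0) {
  stopifnot(cutoff > 0)
  D <- cross_chain_distances(cx$ligand, cx$receptor)
  hit <- which(D <= cutoff, arr.ind = TRUE)
  if (!nrow(hit)) {
    out <- data.frame(complex_id = character(0), ccn = character(0),
                      crn = character(0), min_dist = numeric(0),
                      n_atom_pairs = integer(0))
    attr(out, "n_unlabeled_pairs") <- 0L
    return(out)
  }
  lr <- cx$ligand$resno[hit[, 1]]
  rr <- cx$receptor$resno[hit[, 2]]
  key <- paste(lr, rr, sep = "|")
  min_d <- tapply(D[hit], key, min)
  n_at <- tapply(D[hit], key, length)
  parts <- strsplit(names(min_d), "|", fixed = TRUE)
  lres <- vapply(parts, `[`, "", 1L)
  rres <- vapply(parts, `[`, "", 2L)
  ccn <- unname(cx$ligand_labels[lres])
  crn <- unname(cx$receptor_labels[rres])
  keep <- !is.na(ccn) & !is.na(crn)
  out <- data.frame(complex_id = cx$complex_id, ccn = ccn[keep],
                    crn = crn[keep], min_dist = as.numeric(min_d)[keep],
                    n_atom_pairs = as.integer(n_at)[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$ccn, out$crn), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unlabeled_pairs") <- sum(!keep)
  out
}

#' Build a contact fingerprint across complexes
#'
#' Rows are the unique (CCN, CRN) contact pairs observed in any complex;
#' columns are complexes (or composite groups of near-redundant complexes
#' of the same ligand-receptor pair, whose column is the OR of its
#' members and which counts once in consensus analyses).
#'
#' @param contacts named list of contact data.frames (from
#'   [detect_contacts()]); names are complex ids, or taken from the
#'   \code{complex_id} column.
#' @param composites optional named list: group id -> character vector of
#'   member complex ids.
#' @param subfamilies optional named character vector complex/group id ->
#'   subfamily tag (\code{"CC"} / \code{"CXC"} / other).
#' @param paralogs optional data.frame (\code{column}, \code{ligand},
#'   \code{receptor}) naming the paralogs of each column, used by
#'   [pairwise_complex_comparison()].
#' @return object of class \code{contact_fingerprint}: list with
#'   \code{pairs} (data.frame ccn, crn), \code{presence} (logical matrix
#'   pairs x columns), \code{subfamilies}, \code{paralogs},
#'   \code{instances} (total contact instances before compositing).
#' @export
build_fingerprint <- function(contacts, composites = NULL,
                              subfamilies = NULL, paralogs = NULL) {
  stopifnot(length(contacts) >= 1L)
  if (is.null(names(contacts))) {
    names(contacts) <- vapply(contacts, function(d) d$complex_id[1], "")
  }
  if (anyDuplicated(names(contacts))) {
    stop("duplicate complex_id in contact sets")
  }
  allp <- unique(do.call(rbind, lapply(contacts, function(d) {
    d[, c("ccn", "crn"), drop = FALSE]
  })))
  allp <- allp[order(allp$ccn, allp$crn), , drop = FALSE]
  rownames(allp) <- NULL
  key <- paste(allp$ccn, allp$crn, sep = "|")
  pres <- vapply(contacts, function(d) {
    key %in% paste(d$ccn, d$crn, sep = "|")
  }, logical(length(key)))
  pres <- matrix(pres, nrow = length(key),
                 dimnames = list(key, names(contacts)))
  instances <- sum(pres)
  if (!is.null(composites)) {
    members <- unlist(composites)
    bad <- setdiff(members, colnames(pres))
    if (length(bad)) stop("composite member(s) not present: ",
                          paste(bad, collapse = ", "))
    keep <- setdiff(colnames(pres), members)
    comp <- vapply(composites, function(ms) {
      rowSums(pres[, ms, drop = FALSE]) > 0
    }, logical(length(key)))
    pres <- cbind(pres[, keep, drop = FALSE],
                  matrix(comp, nrow = length(key),
                         dimnames = list(key, names(composites))))
  }
  structure(list(pairs = allp, presence = pres,
                 subfamilies = subfamilies, paralogs = paralogs,
                 instances = instances),
            class = "contact_fingerprint")
}

#' @export
print.contact_fingerprint <- function(x, ...) {
  cat("contact_fingerprint: ", nrow(x$pairs), " unique pairs x ",
      ncol(x$presence), " complexes (", x$instances,
      " contact instances)\n", sep = "")
  invisible(x)
}

#' Number of complexes each contact pair appears in
#' @param fp a \code{contact_fingerprint}.
#' @export
pair_counts <- function(fp) rowSums(fp$presence)

# round half-up to integer percentages, matching printed report style
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

lookup_scores <- function(labels, scores) {
  if (is.data.frame(scores)) scores <- profile_lookup(scores)
  out <- scores[labels]
  names(out) <- labels
  out
}

#' Contacts between conserved positions (and their complement)
#'
#' Retains fingerprint rows whose ligand AND receptor positions both have
#' paralog conservation at or above the threshold; the complement is the
#' set with at least one poorly conserved side. Positions missing from a
#' profile are treated as non-conserved (logged in attribute
#' \code{n_missing_scores}). Percentages are reported against both the
#' unique-pair count and the total contact-instance count.
#'
#' @param fp a \code{contact_fingerprint}.
#' @param ligand_scores,receptor_scores conservation profiles (data.frame
#'   or named numeric).
#' @param threshold conservation threshold (default 0.50, both sides).
#' @return list with \code{conserved}, \code{complement} (pair
#'   data.frames), \code{pct_unique}, \code{pct_instances} and the
#'   complement percentages.
#' @export
conserved_contacts <- function(fp, ligand_scores, receptor_scores,
                               threshold = 0.50) {
  ls <- lookup_scores(fp$pairs$ccn, ligand_scores)
  rs <- lookup_scores(fp$pairs$crn, receptor_scores)
  n_missing <- sum(is.na(ls)) + sum(is.na(rs))
  ls[is.na(ls)] <- -Inf
  rs[is.na(rs)] <- -Inf
  sel <- ls >= threshold & rs >= threshold
  inst <- rowSums(fp$presence)
  out <- list(conserved = fp$pairs[sel, , drop = FALSE],
              complement = fp$pairs[!sel, , drop = FALSE],
              pct_unique = 100 * mean(sel),
              pct_instances = 100 * sum(inst[sel]) / sum(inst),
              pct_unique_complement = 100 * mean(!sel),
              pct_instances_complement =
                100 * sum(inst[!sel]) / sum(inst))
  attr(out, "n_missing_scores") <- n_missing
  out
}

#' Consensus subfamily-specific contacts
#'
#' A contact is CC-consensus when present in at least a majority of CC
#' complexes and in no CXC complex; CXC-consensus symmetrically. With the
#' study's five CC and three CXC columns the default majorities are 3/5
#' and 2/3. The two sets are disjoint by construction.
#'
#' @param fp a \code{contact_fingerprint} whose columns are all tagged CC
#'   or CXC via its \code{subfamilies}.
#' @param min_cc,min_cxc majority thresholds; default
#'   \code{floor(n/2) + 1} of the respective column counts.
#' @return list with \code{cc} and \code{cxc} pair data.frames and the
#'   thresholds used.
#' @export
consensus_subfamily_contacts <- function(fp, min_cc = NULL,
                                         min_cxc = NULL) {
  if (is.null(fp$subfamilies)) {
    stop("untagged fingerprint columns: no subfamilies recorded")
  }
  tags <- fp$subfamilies[colnames(fp$presence)]
  if (any(is.na(tags))) {
    stop("untagged fingerprint column(s): ",
         paste(colnames(fp$presence)[is.na(tags)], collapse = ", "))
  }
  cc_cols <- which(tags == "CC")
  cxc_cols <- which(tags == "CXC")
  if (is.null(min_cc)) min_cc <- floor(length(cc_cols) / 2) + 1L
  if (is.null(min_cxc)) min_cxc <- floor(length(cxc_cols) / 2) + 1L
  n_cc <- rowSums(fp$presence[, cc_cols, drop = FALSE])
  n_cxc <- rowSums(fp$presence[, cxc_cols, drop = FALSE])
  list(cc = fp$pairs[n_cc >= min_cc & n_cxc == 0L, , drop = FALSE],
       cxc = fp$pairs[n_cxc >= min_cxc & n_cc == 0L, , drop = FALSE],
       min_cc = as.integer(min_cc), min_cxc = as.integer(min_cxc))
}

#' Structurally preserved contacts among poorly conserved residues
#'
#' Rows present in strictly more than \code{min_complexes} columns where
#' at least one contacting side has paralog conservation at or below
#' \code{conservation_max} — recurring structural contacts whose sequence
#' identity varies across paralogs.
#'
#' @inheritParams conserved_contacts
#' @param min_complexes strict lower bound on the presence count
#'   (default 8, i.e. > 8 of 16).
#' @param conservation_max conservation ceiling (default 0.5).
#' @return pair data.frame of retained rows with presence counts.
#' @export
preserved_variable_contacts <- function(fp, ligand_scores,
                                        receptor_scores,
                                        min_complexes = 8L,
                                        conservation_max = 0.5) {
  ls <- lookup_scores(fp$pairs$ccn, ligand_scores)
  rs <- lookup_scores(fp$pairs$crn, receptor_scores)
  ls[is.na(ls)] <- -Inf  # unknown conservation counts as poorly conserved
  rs[is.na(rs)] <- -Inf
  cnt <- rowSums(fp$presence)
  sel <- cnt > min_complexes &
    (ls <= conservation_max | rs <= conservation_max)
  out <- fp$pairs[sel, , drop = FALSE]
  out$n_complexes <- cnt[sel]
  out
}

#' Regions of sequence- and structure-level diversification
#'
#' Filters the fingerprint for rarely preserved contacts (present in
#' fewer than \code{presence_max_fraction} of the columns) between poorly
#' conserved positions, then tabulates what fraction of the filtered
#' contacts falls in each ligand SSE, receptor region, and SSE pair.
#'
#' @inheritParams conserved_contacts
#' @param presence_max_fraction strict presence-fraction ceiling
#'   (default 0.5, i.e. < 5/10).
#' @param conservation_max conservation ceiling (default 0.5, strict).
#' @param sides \code{"both"} (default): both positions must be poorly
#'   conserved; \code{"either"}: one suffices.
#' @return list of data.frames \code{ligand_sse}, \code{receptor_sse},
#'   \code{sse_pair}, each with a \code{fraction} column summing to 1,
#'   plus \code{n_filtered}.
#' @export
diversification_by_region <- function(fp, ligand_scores, receptor_scores,
                                      presence_max_fraction = 0.5,
                                      conservation_max = 0.5,
                                      sides = c("both", "either")) {
  sides <- match.arg(sides)
  ls <- lookup_scores(fp$pairs$ccn, ligand_scores)
  rs <- lookup_scores(fp$pairs$crn, receptor_scores)
  ls[is.na(ls)] <- -Inf
  rs[is.na(rs)] <- -Inf
  frac <- rowSums(fp$presence) / ncol(fp$presence)
  low <- if (sides == "both") {
    ls < conservation_max & rs < conservation_max
  } else {
    ls < conservation_max | rs < conservation_max
  }
  sel <- frac < presence_max_fraction & low
  n <- sum(sel)
  if (!n) {
    return(list(ligand_sse = data.frame(), receptor_sse = data.frame(),
                sse_pair = data.frame(), n_filtered = 0L))
  }
  lsse <- label_region(fp$pairs$ccn[sel])
  rsse <- label_region(fp$pairs$crn[sel])
  tab <- function(x) {
    t <- table(x)
    data.frame(sse = names(t), n = as.integer(t),
               fraction = as.numeric(t) / n, stringsAsFactors = FALSE)
  }
  pair <- tab(paste(lsse, rsse, sep = ":"))
  names(pair)[1] <- "sse_pair"
  list(ligand_sse = tab(lsse), receptor_sse = tab(rsse),
       sse_pair = pair, n_filtered = as.integer(n))
}

#' Pairwise contact sharing and interface sequence identity
#'
#' For every pair of fingerprint columns: the percentage of contacts
#' shared by both complexes relative to their union of unique pairs
#' (rounded half-up to integers for report parity), and the mean of the
#' ligand and receptor percent identities computed over interface
#' positions — any position contacting in ANY loaded complex. Gapped
#' positions count as mismatches.
#'
#' @param fp a \code{contact_fingerprint} carrying a \code{paralogs}
#'   table.
#' @param ligand_aln,receptor_aln labeled alignments containing the
#'   paralogs (matched on the \code{paralog} metadata column; the first
#'   matching row is used).
#' @return data.frame with \code{complex_a}, \code{complex_b},
#'   \code{n_shared}, \code{n_union}, \code{pct_shared},
#'   \code{pct_identity}.
#' @export
pairwise_complex_comparison <- function(fp, ligand_aln = NULL,
                                        receptor_aln = NULL) {
  cols <- colnames(fp$presence)
  lig_iface <- unique(fp$pairs$ccn)
  rec_iface <- unique(fp$pairs$crn)
  row_for <- function(aln, paralog) {
    i <- which(aln$records$paralog == paralog)[1]
    if (is.na(i)) return(NULL)
    chars <- strsplit(aln$seqs[[i]], "")[[1]]
    stats::setNames(chars, aln$labels)
  }
  ident <- function(a, b, labs) {
    x <- a[labs]
    y <- b[labs]
    100 * mean(!is.na(x) & !is.na(y) & x != GAP & y != GAP & x == y)
  }
  out <- list()
  for (i in seq_along(cols)) {
    for (j in seq_along(cols)) {
      if (j <= i) next
      A <- fp$presence[, i]
      B <- fp$presence[, j]
      n_shared <- sum(A & B)
      n_union <- sum(A | B)
      pct_shared <- round_half_up(100 * n_shared / n_union)
      pct_id <- NA_real_
      if (!is.null(fp$paralogs) && !is.null(ligand_aln) &&
          !is.null(receptor_aln)) {
        pa <- fp$paralogs[match(cols[i], fp$paralogs$column), ]
        pb <- fp$paralogs[match(cols[j], fp$paralogs$column), ]
        la <- row_for(ligand_aln, pa$ligand)
        lb <- row_for(ligand_aln, pb$ligand)
        ra <- row_for(receptor_aln, pa$receptor)
        rb <- row_for(receptor_aln, pb$receptor)
        if (is.null(la) || is.null(lb) || is.null(ra) || is.null(rb)) {
          warning("missing sequence for pair ", cols[i], " / ", cols[j],
                  "; identity skipped")
        } else {
          pct_id <- mean(c(ident(la, lb, lig_iface),
                           ident(ra, rb, rec_iface)))
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        complex_a = cols[i], complex_b = cols[j],
        n_shared = n_shared, n_union = n_union,
        pct_shared = pct_shared, pct_identity = pct_id,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

ca_coords_by_label <- function(cx, chain = c("ligand", "receptor")) {
  chain <- match.arg(chain)
  atoms <- cx[[chain]]
  labs <- cx[[paste0(chain, "_labels")]]
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  lab <- labs[as.character(ca$resno)]
  keep <- !is.na(lab)
  m <- as.matrix(ca[keep, c("x", "y", "z")])
  rownames(m) <- lab[keep]
  m
}

#' Anchored superposition and per-position Calpha deviations
#'
#' Superposes complex B onto complex A by least squares over the Calpha
#' atoms of their shared anchor-chain positions (receptor CRN positions by
#' default; ligand-anchored mode measures receptor variability), then
#' reports the Calpha deviation at every shared position of the other
#' chain and their mean. Superposition uses bio3d's fit.xyz.
#'
#' @param cxa,cxb \code{complex_structure} objects.
#' @param anchor \code{"receptor"} (default) or \code{"ligand"}.
#' @return list with \code{per_position} (data.frame label, deviation),
#'   \code{mean_deviation}, \code{anchor_rmsd}, \code{n_anchor}.
#' @export
anchored_rmsd <- function(cxa, cxb, anchor = c("receptor", "ligand")) {
  anchor <- match.arg(anchor)
  other <- if (anchor == "receptor") "ligand" else "receptor"
  Aa <- ca_coords_by_label(cxa, anchor)
  Ab <- ca_coords_by_label(cxb, anchor)
  shared_anchor <- intersect(rownames(Aa), rownames(Ab))
  if (length(shared_anchor) < 3L) {
    stop("need at least 3 shared anchor positions, have ",
         length(shared_anchor))
  }
  Oa <- ca_coords_by_label(cxa, other)
  Ob <- ca_coords_by_label(cxb, other)
  shared_other <- intersect(rownames(Oa), rownames(Ob))
  fixed <- as.vector(t(Aa[shared_anchor, , drop = FALSE]))
  mobile_mat <- rbind(Ab[shared_anchor, , drop = FALSE],
                      Ob[shared_other, , drop = FALSE])
  mobile <- as.vector(t(mobile_mat))
  nA <- length(shared_anchor)
  fitted <- bio3d::fit.xyz(fixed, mobile,
                           fixed.inds = seq_len(3L * nA),
                           mobile.inds = seq_len(3L * nA))
  fitm <- matrix(fitted, ncol = 3L, byrow = TRUE)
  anchor_dev <- sqrt(rowSums((fitm[seq_len(nA), , drop = FALSE] -
                                Aa[shared_anchor, , drop = FALSE])^2))
  odev <- if (length(shared_other)) {
    sqrt(rowSums((fitm[nA + seq_along(shared_other), , drop = FALSE] -
                    Oa[shared_other, , drop = FALSE])^2))
  } else {
    numeric(0)
  }
  list(per_position = data.frame(label = shared_other,
                                 deviation = as.numeric(odev),
                                 stringsAsFactors = FALSE),
       mean_deviation = if (length(odev)) mean(odev) else NA_real_,
       anchor_rmsd = sqrt(mean(anchor_dev^2)),
       n_anchor = as.integer(nA))
}

#' Write per-position values into the B-factor column of a PDB file
#'
#' Every atom of a residue whose label has a value carries the
#' (optionally absolute) value; atoms of unmapped residues carry 0. Used
#' to paint mutational-scan enrichment onto structures.
#'
#' @param cx a \code{complex_structure}.
#' @param values named numeric vector label -> value (either chain).
#' @param path output PDB path.
#' @param transform \code{"abs"} (default) or \code{"identity"}.
#' @return the path, invisibly.
#' @export
annotate_bfactor <- function(cx, values, path,
                             transform = c("abs", "identity")) {
  transform <- match.arg(transform)
  f <- if (transform == "abs") abs else identity
  rows <- rbind(cbind(cx$ligand, chain = "A",
                      label = unname(cx$ligand_labels[
                        as.character(cx$ligand$resno)])),
                cbind(cx$receptor, chain = "B",
                      label = unname(cx$receptor_labels[
                        as.character(cx$receptor$resno)])))
  b <- ifelse(!is.na(rows$label) & rows$label %in% names(values),
              f(values[rows$label]), 0)
  xyz <- as.vector(t(as.matrix(rows[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = rows$resno,
                   resid = rows$resid, elety = rows$elety,
                   chain = rows$chain, b = round(b, 2))
  invisible(path)
}

#' Write a complex structure to a PDB file
#'
#' Ligand atoms on chain A, receptor atoms on chain B.
#' @param cx a \code{complex_structure}.
#' @param path output path.
#' @export
write_complex_pdb <- function(cx, path) {
  rows <- rbind(cbind(cx$ligand, chain = "A"),
                cbind(cx$receptor, chain = "B"))
  xyz <- as.vector(t(as.matrix(rows[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = rows$resno,
                   resid = rows$resid, elety = rows$elety,
                   chain = rows$chain)
  invisible(path)
}
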