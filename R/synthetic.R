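with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Specification for the synthetic-data generators
#'
#' Bundles the plans from which all synthetic fixtures are generated with
#' known ground truth. Defaults mirror the scale of the real study
#' system: 26 CC and 17 CXC chemokine paralogs with ~22 orthologs each
#' (a master alignment of about a thousand sequences), short unstructured
#' N-termini with planted motifs, Calpha-only toy complexes with planted
#' cross-chain contacts realizable at the 5 Angstrom cutoff, and
#' variant/mutational-scan/network tables with planned summaries.
#'
#' @param seed master seed; every generator derives its RNG state from
#'   it, so regeneration is bit-identical.
#' @param family family-alignment plan: paralog counts per subfamily,
#'   orthologs per paralog, discriminative-column divergences in [0, 1]
#'   (at divergence d the CC class draws its marker residue with
#'   probability (1+d)/2), number of conserved and neutral columns and
#'   the per-cell gap rate of neutral columns.
#' @param regions motif-region plan: paralog/ortholog counts, N-terminus
#'   length and target motif presence rates (motifs are planted
#'   deterministically into exactly ceiling(rate * n) sequences, so
#'   realized rates equal targets).
#' @param complex toy-complex plan: chain lengths, number of planted
#'   contacts and the contact cutoff.
#' @param tables variant/mutscan/network plan.
#' @return object of class \code{generator_spec}.
#' @export
generator_spec <- function(seed = 1L,
                           family = list(),
                           regions = list(),
                           complex = list(),
                           tables = list()) {
  fam <- utils::modifyList(list(
    n_paralogs = c(CC = 26L, CXC = 17L), n_orthologs = 22L,
    discriminability = c(1.0, 0.8, 0.7, 0.6, 0.5, 0.4),
    n_conserved = 8L, gap_rate = 0.02), family)
  reg <- utils::modifyList(list(
    n_paralogs = 10L, n_orthologs = 10L, nterm_length = 12L,
    presence_rates = c(0.8, 0.6, 0.5, 0.4, 0.2)), regions)
  cx <- utils::modifyList(list(
    n_ligand = 12L, n_receptor = 15L, n_contacts = 4L, cutoff = 5.0),
    complex)
  tab <- utils::modifyList(list(
    n_genes = 4L, n_variants_per_gene = 10L, n_interface = 6L,
    mutscan_positions = 5L, n_cc_ligands = 6L, n_cxc_ligands = 4L,
    n_cc_receptors = 4L, n_cxc_receptors = 3L), tables)
  stopifnot(all(fam$n_paralogs >= 1L), fam$n_orthologs >= 1L,
            all(fam$discriminability >= 0 & fam$discriminability <= 1),
            all(reg$presence_rates >= 0 & reg$presence_rates <= 1),
            cx$cutoff > 3)  # planted geometry needs cutoff - 1 > separation floor
  structure(list(seed = as.integer(seed), family = fam, regions = reg,
                 complex = cx, tables = tab),
            class = "generator_spec")
}

# fixed chemokine-like column layout: NTc stacking region, anchor
# cysteine at CX.1, then the structured SSEs
family_column_plan <- function() {
  spans <- data.frame(
    sse = c("NTc", "CX", "cxb1", "B1", "b1b2", "B2", "b2b3", "B3",
            "b3h", "H", "CT"),
    start = c(1L, 6L, 10L, 16L, 20L, 24L, 28L, 32L, 36L, 40L, 48L),
    end = c(5L, 9L, 15L, 19L, 23L, 27L, 31L, 35L, 39L, 47L, 51L),
    kind = c("Cm", rep("plain", 10)),
    start_index = 1L,
    stringsAsFactors = FALSE)
  list(spans = spans, anchor = 6L, width = 51L)
}

#' Generate a labeled family alignment with planted column structure
#'
#' Builds a CC/CXC chemokine-like master alignment: per-column residue
#' draws follow the column plan (conserved: one residue family-wide;
#' discriminative: residue r1 versus r2 with class-conditional
#' probability (1+d)/2; neutral: class-independent draws from a small
#' pool, with gaps at the configured rate), with the anchor cysteine
#' conserved at CX.1 and labels assigned through [assign_labels()].
#'
#' @param spec a [generator_spec()].
#' @return list with \code{aln} (a \code{labeled_alignment}),
#'   \code{config} (the \code{numbering_config}) and \code{truth}
#'   (data.frame column, label, type, r1, r2, divergence).
#' @export
make_family_alignment <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  fam <- spec$family
  plan <- family_column_plan()
  with_seed(spec$seed, {
    width <- plan$width
    anchor <- plan$anchor
    body <- setdiff(seq_len(width), c(seq_len(5L), anchor))
    n_disc <- length(fam$discriminability)
    stopifnot(fam$n_conserved - 1L + n_disc <= length(body))
    cons_cols <- body[seq_len(fam$n_conserved - 1L)]
    disc_cols <- body[fam$n_conserved - 1L + seq_len(n_disc)]
    type <- rep("neutral", width)
    type[c(anchor, cons_cols)] <- "conserved"
    type[disc_cols] <- "discriminative"
    cons_res <- stats::setNames(
      c("C", sample(setdiff(AA_ALPHABET20, "C"), fam$n_conserved - 1L,
                    replace = TRUE)),
      c(anchor, cons_cols))
    pool <- c("A", "G", "S", "T", "N", "D", "E", "K")
    marker <- lapply(seq_len(n_disc), function(i) {
      sample(AA_ALPHABET20, 2L)
    })
    r1 <- rep(NA_character_, width)
    r2 <- rep(NA_character_, width)
    d <- rep(NA_real_, width)
    r1[disc_cols] <- vapply(marker, `[`, "", 1L)
    r2[disc_cols] <- vapply(marker, `[`, "", 2L)
    d[disc_cols] <- fam$discriminability
    paralogs <- c(paste0("sCCL", seq_len(fam$n_paralogs[["CC"]])),
                  paste0("sCXCL", seq_len(fam$n_paralogs[["CXC"]])))
    subfam <- c(rep("CC", fam$n_paralogs[["CC"]]),
                rep("CXC", fam$n_paralogs[["CXC"]]))
    n_per <- 1L + fam$n_orthologs  # human + orthologs
    records <- data.frame(
      seq_id = paste0(rep(paralogs, each = n_per), "_",
                      rep(c("human", paste0("sp", seq_len(fam$n_orthologs))),
                          times = length(paralogs))),
      paralog = rep(paralogs, each = n_per),
      species = rep(c("human", paste0("sp", seq_len(fam$n_orthologs))),
                    times = length(paralogs)),
      subfamily = rep(subfam, each = n_per),
      role = "ligand", stringsAsFactors = FALSE)
    n <- nrow(records)
    m <- matrix("", n, width)
    for (j in seq_len(width)) {
      m[, j] <- switch(
        type[j],
        conserved = rep(cons_res[[as.character(j)]], n),
        discriminative = {
          p <- (1 + d[j]) / 2
          pick1 <- stats::runif(n) < p
          cc <- records$subfamily == "CC"
          ifelse(cc == pick1, r1[j], r2[j])
        },
        neutral = {
          res <- sample(pool, n, replace = TRUE)
          res[stats::runif(n) < fam$gap_rate] <- GAP
          res
        })
    }
    seqs <- stats::setNames(apply(m, 1L, paste, collapse = ""),
                            records$seq_id)
    cfg <- numbering_config("CCN", plan$spans, anchor = plan$anchor)
    aln <- assign_labels(labeled_alignment(records, seqs), cfg)
    truth <- data.frame(column = seq_len(width), label = aln$labels,
                        type = type, r1 = r1, r2 = r2, divergence = d,
                        stringsAsFactors = FALSE)
    list(aln = aln, config = cfg, truth = truth)
  })
}

#' Generate ortholog N-terminal region sets with planted motifs
#'
#' Each synthetic paralog gets one 3-mer motif planted into exactly
#' ceiling(rate * n) of its ortholog N-termini, so realized presence
#' rates equal the targets exactly. Motif letters and background letters
#' are drawn from disjoint alphabets, which rules out accidental motif
#' matches by construction.
#'
#' @param spec a [generator_spec()].
#' @return list with \code{regions} (named list paralog -> character
#'   vector of ortholog N-terminal strings), \code{reference} (named
#'   character: the first ortholog per paralog, by convention the human
#'   sequence) and \code{truth} (data.frame paralog, motif, rate,
#'   n_orthologs, n_planted).
#' @export
make_motif_regions <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  reg <- spec$regions
  motif_alpha <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
  backg_alpha <- c("M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  with_seed(spec$seed + 1L, {
    paralogs <- paste0("sCK", seq_len(reg$n_paralogs))
    rates <- rep_len(reg$presence_rates, reg$n_paralogs)
    out <- list()
    truth <- list()
    for (i in seq_along(paralogs)) {
      motif <- paste(sample(motif_alpha, 3L, replace = TRUE),
                     collapse = "")
      n <- reg$n_orthologs
      n_plant <- as.integer(ceiling(rates[i] * n))
      seqs <- vapply(seq_len(n), function(k) {
        paste(sample(backg_alpha, reg$nterm_length, replace = TRUE),
              collapse = "")
      }, "")
      if (n_plant > 0L) {
        pos <- sample(seq_len(reg$nterm_length - 2L), 1L)
        for (k in seq_len(n_plant)) {
          substr(seqs[k], pos, pos + 2L) <- motif
        }
      }
      out[[paralogs[i]]] <- seqs
      truth[[i]] <- data.frame(paralog = paralogs[i], motif = motif,
                               rate = rates[i], n_orthologs = n,
                               n_planted = n_plant,
                               stringsAsFactors = FALSE)
    }
    list(regions = out,
         reference = vapply(out, `[`, "", 1L),
         truth = do.call(rbind, truth))
  })
}

default_ccn_labels <- function(n) {
  pool <- c(paste0("NTc.Cm", 3:1), paste0("CX.", 1:3),
            paste0("cxb1.", 1:3), paste0("B1.", 1:3),
            paste0("b1b2.", 1:3), paste0("B2.", 1:3),
            paste0("b2b3.", 1:3), paste0("B3.", 1:3),
            paste0("b3h.", 1:3), paste0("H.", 1:4), paste0("CT.", 1:3))
  stopifnot(n <= length(pool))
  pool[seq_len(n)]
}

default_crn_labels <- function(n) {
  pool <- c(paste0("NTr.Cm", 3:1), paste0("1x", 22:31),
            paste0("ECL2.", 1:5), paste0("45x", 50:52),
            paste0("ECL2.Cp", 3:7), paste0("7x", 24:33))
  stopifnot(n <= length(pool))
  pool[seq_len(n)]
}

#' Generate a Calpha-only toy complex with planted contacts
#'
#' Chains are laid out on parallel lines 40 Angstrom apart with 10
#' Angstrom residue spacing; each planted (ligand, receptor) pair moves
#' the receptor residue to cutoff - 1 Angstrom of its ligand partner,
#' leaving every other cross-chain atom pair beyond cutoff + 2.
#'
#' @param spec a [generator_spec()].
#' @param complex_id identifier.
#' @param subfamily subfamily tags \code{c(ligand = , receptor = )}.
#' @param seed_offset increment on the master seed, letting callers
#'   derive several independent complexes from one spec.
#' @return list with \code{cx} (a \code{complex_structure}) and
#'   \code{truth} (data.frame ccn, crn of planted contacts).
#' @export
make_toy_complex <- function(spec, complex_id = "toy1",
                             subfamily = c(ligand = "CC",
                                           receptor = "CC"),
                             seed_offset = 2L) {
  stopifnot(inherits(spec, "generator_spec"))
  cp <- spec$complex
  stopifnot(cp$n_contacts <= min(cp$n_ligand, cp$n_receptor))
  with_seed(spec$seed + seed_offset, {
    lig <- data.frame(resno = seq_len(cp$n_ligand), resid = "ALA",
                      elety = "CA",
                      x = 10 * seq_len(cp$n_ligand), y = 0, z = 0,
                      stringsAsFactors = FALSE)
    rec <- data.frame(resno = seq_len(cp$n_receptor), resid = "ALA",
                      elety = "CA",
                      x = 10 * seq_len(cp$n_receptor), y = 40, z = 0,
                      stringsAsFactors = FALSE)
    li <- sample(cp$n_ligand, cp$n_contacts)
    rj <- sample(cp$n_receptor, cp$n_contacts)
    for (k in seq_len(cp$n_contacts)) {
      rec$x[rj[k]] <- lig$x[li[k]]
      rec$y[rj[k]] <- cp$cutoff - 1
      rec$z[rj[k]] <- 0
    }
    lig_labels <- stats::setNames(default_ccn_labels(cp$n_ligand),
                                  lig$resno)
    rec_labels <- stats::setNames(default_crn_labels(cp$n_receptor),
                                  rec$resno)
    cx <- complex_structure(complex_id, lig, rec, lig_labels,
                            rec_labels, subfamily = subfamily)
    truth <- data.frame(ccn = unname(lig_labels[as.character(li)]),
                        crn = unname(rec_labels[as.character(rj)]),
                        stringsAsFactors = FALSE)
    truth <- truth[order(truth$ccn, truth$crn), , drop = FALSE]
    rownames(truth) <- NULL
    list(cx = cx, truth = truth)
  })
}

#' Apply a rigid-body transform to a chain's coordinates
#'
#' Helper for superposition tests: rotates (Euler angles, radians) and
#' translates the coordinates of one or both chains.
#'
#' @param cx a \code{complex_structure}.
#' @param angles numeric(3) rotation angles about x, y, z.
#' @param translation numeric(3).
#' @param chains which chains to move (default both).
#' @return the transformed \code{complex_structure}.
#' @export
rigid_transform <- function(cx, angles = c(0, 0, 0),
                            translation = c(0, 0, 0),
                            chains = c("ligand", "receptor")) {
  cs <- cos(angles)
  sn <- sin(angles)
  Rx <- rbind(c(1, 0, 0), c(0, cs[1], -sn[1]), c(0, sn[1], cs[1]))
  Ry <- rbind(c(cs[2], 0, sn[2]), c(0, 1, 0), c(-sn[2], 0, cs[2]))
  Rz <- rbind(c(cs[3], -sn[3], 0), c(sn[3], cs[3], 0), c(0, 0, 1))
  R <- Rz %*% Ry %*% Rx
  for (ch in chains) {
    xyz <- as.matrix(cx[[ch]][, c("x", "y", "z")])
    moved <- xyz %*% t(R) + matrix(translation, nrow(xyz), 3L,
                                   byrow = TRUE)
    cx[[ch]]$x <- moved[, 1]
    cx[[ch]]$y <- moved[, 2]
    cx[[ch]]$z <- moved[, 3]
  }
  cx
}

#' Generate variant, mutational-scan and network tables with truth
#'
#' @param spec a [generator_spec()].
#' @return list of three elements, each \code{list(data, truth)}:
#'   \code{variants} (table + label map + interface set + planned
#'   per-gene interface sums), \code{mutscan} (replicate table + planned
#'   substitution and position means), \code{network} (edge list +
#'   subfamily tags + planned interaction matrix and contingency table).
#' @export
make_tables <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  tb <- spec$tables
  with_seed(spec$seed + 3L, {
    ## variants
    genes <- paste0("sGENE", seq_len(tb$n_genes))
    label_pool <- default_crn_labels(20L)
    label_maps <- lapply(genes, function(g) {
      stats::setNames(label_pool, seq_along(label_pool))
    })
    names(label_maps) <- genes
    interface <- sample(label_pool, tb$n_interface)
    vt <- do.call(rbind, lapply(genes, function(g) {
      idx <- sample(20L, tb$n_variants_per_gene)
      data.frame(gene = g, native_index = idx,
                 ref = sample(AA_ALPHABET20, tb$n_variants_per_gene,
                              replace = TRUE),
                 alt = sample(AA_ALPHABET20, tb$n_variants_per_gene,
                              replace = TRUE),
                 count = sample(0:50, tb$n_variants_per_gene,
                                replace = TRUE),
                 source = "population", stringsAsFactors = FALSE)
    }))
    vt_truth <- do.call(rbind, lapply(genes, function(g) {
      rows <- vt[vt$gene == g, ]
      labs <- label_maps[[g]][as.character(rows$native_index)]
      data.frame(gene = g,
                 interface_total = sum(rows$count[labs %in% interface]),
                 stringsAsFactors = FALSE)
    }))
    ## mutational scan
    pos <- paste0("1x", 23 + seq_len(tb$mutscan_positions))
    mu <- stats::rnorm(tb$mutscan_positions, 0, 1.5)
    ms <- do.call(rbind, lapply(seq_along(pos), function(i) {
      subs <- setdiff(AA_ALPHABET20, "A")
      base <- mu[i] + stats::rnorm(length(subs), 0, 0.3)
      data.frame(label = pos[i], substitution = subs,
                 rep1 = base + stats::rnorm(length(subs), 0, 0.1),
                 rep2 = base + stats::rnorm(length(subs), 0, 0.1),
                 stringsAsFactors = FALSE)
    }))
    ms_truth <- data.frame(
      label = ms$label, substitution = ms$substitution,
      mean_enrichment = (ms$rep1 + ms$rep2) / 2,
      stringsAsFactors = FALSE)
    ms_pos_truth <- data.frame(
      label = pos,
      abs_mean_log2 = abs(tapply(ms_truth$mean_enrichment,
                                 ms_truth$label, mean)[pos]),
      stringsAsFactors = FALSE)
    ## network
    ligs <- c(paste0("sCCL", seq_len(tb$n_cc_ligands)),
              paste0("sCXCL", seq_len(tb$n_cxc_ligands)))
    recs <- c(paste0("sCCR", seq_len(tb$n_cc_receptors)),
              paste0("sCXCR", seq_len(tb$n_cxc_receptors)))
    tags <- stats::setNames(
      c(rep("CC", tb$n_cc_ligands), rep("CXC", tb$n_cxc_ligands),
        rep("CC", tb$n_cc_receptors), rep("CXC", tb$n_cxc_receptors)),
      c(ligs, recs))
    edges <- list()
    planted <- matrix(FALSE, length(ligs), length(recs),
                      dimnames = list(ligs, recs))
    ref <- 0L
    for (l in ligs) {
      for (r in recs) {
        p <- if (tags[[l]] == tags[[r]]) 0.6 else 0.08
        if (stats::runif(1) < p) {
          planted[l, r] <- TRUE
          ref <- ref + 1L
          edges[[length(edges) + 1L]] <- data.frame(
            ligand = l, receptor = r,
            strength = sample(2:3, 1L),
            evidence = sample(c("A", "B", "C"), 1L),
            reference = paste0("ref", ref), stringsAsFactors = FALSE)
        } else if (stats::runif(1) < 0.2) {
          # below-threshold evidence the filter must drop
          ref <- ref + 1L
          edges[[length(edges) + 1L]] <- data.frame(
            ligand = l, receptor = r,
            strength = sample(0:1, 1L), evidence = "D",
            reference = paste0("ref", ref), stringsAsFactors = FALSE)
        }
      }
    }
    edges <- do.call(rbind, edges)
    like <- outer(tags[ligs], tags[recs], "==")
    planted_tab <- rbind(
      like = c(interacting = sum(planted & like),
               not = sum(!planted & like)),
      unlike = c(interacting = sum(planted & !like),
                 not = sum(!planted & !like)))
    list(
      variants = list(data = vt, label_maps = label_maps,
                      interface = interface, truth = vt_truth),
      mutscan = list(data = ms,
                     truth = list(substitutions = ms_truth,
                                  positions = ms_pos_truth)),
      network = list(data = edges, subfamilies = tags,
                     truth = list(matrix = planted,
                                  table = planted_tab)))
  })
}
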