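#' Filter a literature interaction network to a binary matrix
#'
#' Each edge is a (ligand, receptor, reference) record with an
#' interaction strength (0-3; 3 for sub-100 nM binding or signaling, 2
#' for 100-1000 nM, 1 weaker, 0 tested with no effect) and an evidence
#' grade (A quantitative dose-response, B semi-quantitative, C
#' qualitative, D indirect). A pair interacts when at least one of its
#' edges passes both filters. By default "at least grade C" evidence is
#' read inclusively (A, B or C qualify); set
#' \code{evidence_mode = "exact"} to require the stated grade itself.
#'
#' @param edges data.frame with columns \code{ligand}, \code{receptor},
#'   \code{strength} (0-3), \code{evidence} (A-D), optionally
#'   \code{reference}.
#' @param min_strength minimum interaction strength (default 2).
#' @param evidence evidence-grade cutoff (default \code{"C"}).
#' @param evidence_mode \code{"at_least"} (default) or \code{"exact"}.
#' @return logical matrix ligand x receptor covering every protein
#'   appearing in the edge list.
#' @export
filter_network <- function(edges, min_strength = 2L, evidence = "C",
                           evidence_mode = c("at_least", "exact")) {
  evidence_mode <- match.arg(evidence_mode)
  stopifnot(all(edges$strength %in% 0:3),
            all(edges$evidence %in% c("A", "B", "C", "D")))
  rank <- c(A = 1L, B = 2L, C = 3L, D = 4L)
  pass <- edges$strength >= min_strength &
    if (evidence_mode == "at_least") {
      rank[edges$evidence] <= rank[[evidence]]
    } else {
      edges$evidence == evidence
    }
  ligands <- sort(unique(edges$ligand))
  receptors <- sort(unique(edges$receptor))
  m <- matrix(FALSE, length(ligands), length(receptors),
              dimnames = list(ligands, receptors))
  hit <- unique(edges[pass, c("ligand", "receptor"), drop = FALSE])
  m[cbind(hit$ligand, hit$receptor)] <- TRUE
  m
}

#' Group two ligand-receptor pairs by subfamily and network overlap
#'
#' Group 1: the pairs belong to different subfamilies. Group 2: same
#' subfamily but non-overlapping interaction networks. Group 3: same
#' subfamily with overlapping networks — the two ligands share at least
#' one receptor or the two receptors share at least one ligand in the
#' filtered interaction matrix. Symmetric in pair order.
#'
#' @param pair_a,pair_b character vectors \code{c(ligand, receptor)}.
#' @param matrix filtered interaction matrix from [filter_network()].
#' @param subfamilies named character vector protein -> subfamily tag.
#' @return integer group (1, 2 or 3) with attribute \code{overlap}.
#' @export
partner_overlap_group <- function(pair_a, pair_b, matrix, subfamilies) {
  prots <- c(pair_a, pair_b)
  known <- c(rownames(matrix), colnames(matrix))
  if (!all(prots %in% known)) {
    stop("unknown protein(s): ",
         paste(setdiff(prots, known), collapse = ", "))
  }
  if (anyNA(subfamilies[prots])) {
    stop("missing subfamily tag for: ",
         paste(prots[is.na(subfamilies[prots])], collapse = ", "))
  }
  same <- subfamilies[[pair_a[1]]] == subfamilies[[pair_b[1]]] &&
    subfamilies[[pair_a[2]]] == subfamilies[[pair_b[2]]]
  partners_of_ligand <- function(l) colnames(matrix)[matrix[l, ]]
  partners_of_receptor <- function(r) rownames(matrix)[matrix[, r]]
  overlap <- length(intersect(partners_of_ligand(pair_a[1]),
                              partners_of_ligand(pair_b[1]))) > 0L ||
    length(intersect(partners_of_receptor(pair_a[2]),
                     partners_of_receptor(pair_b[2]))) > 0L
  g <- if (!same) 1L else if (overlap) 3L else 2L
  structure(g, overlap = overlap)
}

#' Test subfamily coupling of the interaction network
#'
#' Tabulates like-subfamily versus unlike-subfamily ligand-receptor
#' combinations against interacting/non-interacting status and applies a
#' Pearson chi-squared test (1 df, no continuity correction). Only CC-
#' and CXC-tagged proteins enter the table.
#'
#' @param matrix filtered interaction matrix from [filter_network()].
#' @param subfamilies named character vector protein -> subfamily.
#' @return list with \code{table} (2x2 counts), \code{statistic},
#'   \code{p_value} and \code{flag} (\code{"empty_margin"} when a row or
#'   column of the table is all zero, in which case the p-value is NA).
#' @export
subfamily_coupling_test <- function(matrix, subfamilies) {
  lig <- rownames(matrix)[subfamilies[rownames(matrix)] %in%
                            c("CC", "CXC")]
  rec <- colnames(matrix)[subfamilies[colnames(matrix)] %in%
                            c("CC", "CXC")]
  if (!length(lig) || !length(rec)) stop("no CC/CXC-tagged proteins")
  m <- matrix[lig, rec, drop = FALSE]
  like <- outer(subfamilies[lig], subfamilies[rec], "==")
  tab <- rbind(like = c(interacting = sum(m & like),
                        not = sum(!m & like)),
               unlike = c(interacting = sum(m & !like),
                          not = sum(!m & !like)))
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    return(list(table = tab, statistic = NA_real_, p_value = NA_real_,
                flag = "empty_margin"))
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(table = tab, statistic = unname(ct$statistic),
       p_value = ct$p.value, flag = "")
}

#' Read an interaction edge list from TSV
#'
#' Columns: ligand, receptor, strength, evidence, reference. The
#' (ligand, receptor, reference) triple must be unique.
#'
#' @param path TSV path.
#' @export
read_network_edges <- function(path) {
  edges <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("ligand", "receptor", "strength", "evidence")
  if (!all(need %in% names(edges))) {
    stop("edge list needs columns: ", paste(need, collapse = ", "))
  }
  if ("reference" %in% names(edges)) {
    key <- paste(edges$ligand, edges$receptor, edges$reference)
    if (anyDuplicated(key)) stop("duplicate (ligand, receptor, reference)")
  }
  edges
}
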