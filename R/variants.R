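#' Map a variant table to common-numbering labels
#'
#' Each missense-variant row is resolved through a gene's
#' residue-to-label map. Rows land in exactly one of three buckets:
#' \code{labeled}, \code{unlabeled} (position has no common-numbering
#' label) or \code{error} (unknown gene; row-level, never aborts).
#' When reference sequences are supplied, rows whose stated reference
#' residue disagrees with the sequence are flagged \code{ref_mismatch}
#' and retained, keeping the table's residue as consensus.
#'
#' @param variants data.frame with columns \code{gene},
#'   \code{native_index}, \code{ref}, \code{alt}, a value column
#'   (\code{count} or \code{frequency}), \code{source}; phenotype rows may
#'   add \code{phenotype} and \code{p}.
#' @param label_maps named list gene -> named character vector
#'   (native index as name -> label), e.g. from
#'   [label_map_from_alignment()], or a data.frame with \code{protein},
#'   \code{native_index}, \code{label}.
#' @param sequences optional named character vector of ungapped
#'   reference sequences per gene for ref-mismatch checking.
#' @return the input with added \code{label}, \code{status} and
#'   \code{ref_mismatch} columns.
#' @export
map_variants <- function(variants, label_maps, sequences = NULL) {
  if (is.data.frame(label_maps)) {
    label_maps <- split(
      stats::setNames(label_maps$label,
                      label_maps$native_index),
      label_maps$protein)
  }
  out <- variants
  out$label <- NA_character_
  out$status <- "error"
  out$ref_mismatch <- FALSE
  for (i in seq_len(nrow(out))) {
    g <- out$gene[i]
    if (!g %in% names(label_maps)) next
    lm <- label_maps[[g]]
    lab <- unname(lm[as.character(out$native_index[i])])
    if (length(lab) != 1L || is.na(lab)) {
      out$status[i] <- "unlabeled"
    } else {
      out$label[i] <- lab
      out$status[i] <- "labeled"
    }
    if (!is.null(sequences) && g %in% names(sequences)) {
      res <- substr(sequences[[g]], out$native_index[i],
                    out$native_index[i])
      if (nzchar(res) && res != out$ref[i]) out$ref_mismatch[i] <- TRUE
    }
  }
  out
}

#' Summarize interface variation per gene
#'
#' Sums the allele counts (or frequencies) of variants whose mapped label
#' lies in the interface-position set, per gene, and ranks genes by the
#' cumulative value. Homozygous carriers are assumed pre-counted twice in
#' the input allele counts.
#'
#' @param mapped result of [map_variants()].
#' @param interface_labels character vector of interface position labels
#'   (any position contacting in any loaded complex).
#' @param value_col which column to sum (default \code{"count"},
#'   falling back to \code{"frequency"}).
#' @return data.frame (\code{gene}, \code{total}, \code{n_variants})
#'   sorted decreasing by total; attribute \code{metric} records which
#'   column was summed.
#' @export
interface_variant_summary <- function(mapped, interface_labels,
                                      value_col = NULL) {
  if (is.null(value_col)) {
    value_col <- if ("count" %in% names(mapped)) "count" else "frequency"
  }
  sel <- mapped$status == "labeled" & mapped$label %in% interface_labels
  sub <- mapped[sel, , drop = FALSE]
  tot <- tapply(sub[[value_col]], sub$gene, sum)
  cnt <- tapply(sub[[value_col]], sub$gene, length)
  out <- data.frame(gene = names(tot), total = as.numeric(tot),
                    n_variants = as.integer(cnt),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$total), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "metric") <- value_col
  out
}

#' Summarize saturation-mutagenesis enrichment per position
#'
#' Each substitution's value is the mean of its replicate log2 enrichment
#' ratios; each position is summarized by the distribution of its
#' substitution values, their mean, and the absolute mean used for
#' structure mapping (functionally important positions are depleted, so
#' large absolute values mark importance).
#'
#' @param scan data.frame with \code{label}, \code{substitution} and one
#'   or more replicate columns (any column matching \code{"^rep"}).
#' @return list with \code{substitutions} (per-substitution means) and
#'   \code{positions} (\code{label}, \code{n_substitutions},
#'   \code{mean_log2}, \code{abs_mean_log2}).
#' @export
mutscan_position_summary <- function(scan) {
  repcols <- grep("^rep", names(scan), value = TRUE)
  if (!length(repcols)) stop("no replicate columns (rep1, rep2, ...)")
  vals <- as.matrix(scan[, repcols, drop = FALSE])
  if (!all(is.finite(vals))) stop("non-finite enrichment values")
  subs <- data.frame(label = scan$label,
                     substitution = scan$substitution,
                     mean_enrichment = rowMeans(vals),
                     stringsAsFactors = FALSE)
  pm <- tapply(subs$mean_enrichment, subs$label, mean)
  pn <- tapply(subs$mean_enrichment, subs$label, length)
  positions <- data.frame(label = names(pm),
                          n_substitutions = as.integer(pn),
                          mean_log2 = as.numeric(pm),
                          abs_mean_log2 = abs(as.numeric(pm)),
                          stringsAsFactors = FALSE)
  rownames(positions) <- NULL
  list(substitutions = subs, positions = positions)
}

#' Compare enrichment distributions across positions
#'
#' Omnibus tie-corrected Kruskal-Wallis test (chi-square p-value) across
#' the positions' substitution-value distributions, followed by pairwise
#' post-hoc Dunn z tests with Bonferroni correction over all tested
#' pairs.
#'
#' @param values numeric vector of substitution enrichment values.
#' @param groups position label per value.
#' @return list with \code{H}, \code{df}, \code{p_value}, \code{dunn}
#'   (data.frame group_a, group_b, z, p, p_adj) and \code{flag}
#'   (\code{"constant"} when all values are identical, in which case
#'   p = 1).
#' @export
mutscan_compare <- function(values, groups) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  if (length(unique(groups)) < 2L) stop("need at least 2 positions")
  if (any(table(groups) < 2L)) stop("need at least 2 values per position")
  if (length(unique(values)) == 1L) {
    gs <- sort(unique(groups))
    pairs <- utils::combn(gs, 2L)
    dunn <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                       z = 0, p = 1, p_adj = 1,
                       stringsAsFactors = FALSE)
    return(list(H = 0, df = length(gs) - 1L, p_value = 1, dunn = dunn,
                flag = "constant"))
  }
  kw <- stats::kruskal.test(values, factor(groups))
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  s2 <- (N * (N + 1) / 12) - tie_term / (12 * (N - 1))
  gs <- sort(unique(groups))
  rbar <- tapply(r, groups, mean)[gs]
  ns <- table(groups)[gs]
  pairs <- utils::combn(gs, 2L)
  z <- apply(pairs, 2L, function(pr) {
    (rbar[[pr[1]]] - rbar[[pr[2]]]) /
      sqrt(s2 * (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  dunn <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                     z = as.numeric(z), p = p,
                     p_adj = pmin(1, p * ncol(pairs)),
                     stringsAsFactors = FALSE)
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value, dunn = dunn, flag = "")
}
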