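#' Parameters for trident conservation scoring
#'
#' The trident score combines three per-column terms,
#' \deqn{score = (1 - t)^a (1 - r)^b (1 - g)^c,}
#' where \eqn{t} is the normalized symbol entropy (gaps excluded,
#' normalized by \eqn{\log \min(20, depth)}), \eqn{r} the normalized mean
#' stereochemical distance of the column's residues to its consensus
#' residue, and \eqn{g} the gap fraction. A perfectly conserved, gap-free
#' column scores 1; an all-gap column scores 0.
#'
#' The stereochemical distance derives from a substitution matrix
#' normalized to unit self-similarity,
#' \eqn{d(a,b) = 1 - B(a,b)/\sqrt{B(a,a) B(b,b)}}, clipped to [0, 1].
#'
#' @param a,b,c non-negative exponents for the entropy, stereochemistry and
#'   gap terms. Defaults (1, 0.5, 3) are pinned and recorded in output
#'   provenance.
#' @param matrix substitution matrix name, resolved from Biostrings
#'   (default \code{"BLOSUM62"}).
#' @return object of class \code{trident_params}.
#' @export
trident_params <- function(a = 1, b = 0.5, c = 3, matrix = "BLOSUM62") {
  stopifnot(a >= 0, b >= 0, c >= 0)
  B <- get_subst_matrix(matrix)
  B <- B[AA_ALPHABET20, AA_ALPHABET20]
  self <- sqrt(diag(B))
  D <- 1 - B / outer(self, self)
  D[D < 0] <- 0
  D[D > 1] <- 1
  stopifnot(isSymmetric(unname(D)), all(abs(diag(D)) < 1e-12))
  structure(list(a = a, b = b, c = c, matrix = matrix, dist = D),
            class = "trident_params")
}

get_subst_matrix <- function(name) {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  get(name, envir = env)
}

#' Trident conservation score of one alignment column
#'
#' @param column character vector of single residues (may contain the gap
#'   symbol \code{"-"}).
#' @param params a [trident_params()] object.
#' @return numeric score in [0, 1]; an all-gap column returns 0 with
#'   attribute \code{all_gap = TRUE}.
#' @export
trident_score <- function(column, params = trident_params()) {
  stopifnot(length(column) > 0)
  n <- length(column)
  res <- column[column != GAP]
  g <- 1 - length(res) / n
  if (!length(res)) {
    return(structure(0, all_gap = TRUE))
  }
  bad <- setdiff(unique(res), AA_ALPHABET20)
  if (length(bad)) {
    stop("non-standard residue(s) in column: ", paste(bad, collapse = ", "))
  }
  tab <- table(res)
  p <- as.numeric(tab) / length(res)
  hmax <- log(min(20L, length(res)))
  t <- if (hmax > 0) -sum(p * log(p)) / hmax else 0
  # consensus = most frequent residue, alphabetical tie-break
  consensus <- names(tab)[order(-as.numeric(tab), names(tab))][1L]
  r <- mean(params$dist[cbind(res, rep(consensus, length(res)))])
  (1 - t)^params$a * (1 - r)^params$b * (1 - g)^params$c
}

#' Per-position conservation profile over a sequence subset
#'
#' Applies [trident_score()] to every labeled column over the selected
#' sequences. Selectors mirror the scored sets of the source study: all
#' human paralogs, a subfamily, CC+CXC combined, ACKR-only or non-ACKR
#' receptors, or the ortholog set of a single paralog.
#'
#' @param aln a \code{labeled_alignment}.
#' @param subset one of: NULL (all sequences), a character vector of
#'   seq_ids, a logical vector, or a function taking the records
#'   data.frame and returning a logical vector.
#' @param params a [trident_params()] object.
#' @param set_descriptor free-text provenance of the subset; defaults to a
#'   deparse of the selector.
#' @return data.frame (\code{label}, \code{score}, \code{n_non_gap}) with
#'   attributes \code{set_descriptor}, \code{n_sequences}, \code{params}.
#'   Labeled columns that are all-gap within the subset are omitted.
#' @export
conservation_profile <- function(aln, subset = NULL,
                                 params = trident_params(),
                                 set_descriptor = NULL) {
  if (is.null(set_descriptor)) {
    set_descriptor <- if (is.null(subset)) "all sequences" else
      paste(deparse(substitute(subset)), collapse = "")
  }
  keep <- if (is.null(subset)) {
    rep(TRUE, length(aln$seqs))
  } else if (is.function(subset)) {
    subset(aln$records)
  } else if (is.character(subset)) {
    names(aln$seqs) %in% subset
  } else {
    as.logical(subset)
  }
  if (sum(keep) < 2L) stop("selector yields fewer than 2 sequences")
  m <- aln_matrix(aln)[keep, , drop = FALSE]
  cols <- which(!is.na(aln$labels))
  score <- vapply(cols, function(j) trident_score(m[, j], params), 0)
  nng <- vapply(cols, function(j) sum(m[, j] != GAP), 0L)
  out <- data.frame(label = aln$labels[cols], score = score,
                    n_non_gap = nng, stringsAsFactors = FALSE)
  out <- out[out$n_non_gap > 0L, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "set_descriptor") <- set_descriptor
  attr(out, "n_sequences") <- sum(keep)
  attr(out, "params") <- params[c("a", "b", "c", "matrix")]
  out
}

#' Write a conservation profile as TSV
#'
#' Columns: label, score, n_non_gap, set_descriptor, n_sequences.
#' @param profile result of [conservation_profile()].
#' @param path output path.
#' @export
write_conservation_profile <- function(profile, path) {
  out <- profile
  out$set_descriptor <- attr(profile, "set_descriptor")
  out$n_sequences <- attr(profile, "n_sequences")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(profile)
}

#' Turn a profile into a named score lookup
#' @param profile a conservation (or any label/score) data.frame.
#' @return named numeric vector score by label.
#' @export
profile_lookup <- function(profile) {
  stats::setNames(profile$score, profile$label)
}
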