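#' Enumerate 2-, 3- and 4-mer peptide fragments (with gapped variants)
#'
#' All contiguous 2/3/4-mers of an unstructured-region sequence, plus the
#' degenerate (gapped) variants obtained by placing the wildcard \code{x}
#' at the 2nd position of each 3-mer and at the 2nd, 3rd or both interior
#' positions of each 4-mer (shapes XxX, XxXX, XXxX, XxxX). Fragments
#' occurring multiple times in a sequence are reported once.
#'
#' @param seq ungapped string over the 20 standard amino acids;
#'   non-standard letters (B, J, O, U, X, Z) are rejected.
#' @return data.frame with \code{pattern}, \code{k} (window length) and
#'   \code{gapped}; empty for sequences shorter than 2.
#' @export
enumerate_fragments <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(seq, "")[[1]]
  bad <- setdiff(chars, AA_ALPHABET20)
  if (length(bad)) {
    stop("non-standard residue(s) in sequence: ",
         paste(unique(bad), collapse = ", "))
  }
  n <- length(chars)
  empty <- data.frame(pattern = character(0), k = integer(0),
                      gapped = logical(0))
  if (n < 2L) return(empty)
  win <- function(k) {
    if (n < k) return(character(0))
    starts <- seq_len(n - k + 1L)
    vapply(starts, function(i) paste(chars[i:(i + k - 1L)],
                                     collapse = ""), "")
  }
  w2 <- win(2L)
  w3 <- win(3L)
  w4 <- win(4L)
  gap_at <- function(w, pos) {
    vapply(w, function(s) {
      v <- strsplit(s, "")[[1]]
      v[pos] <- "x"
      paste(v, collapse = "")
    }, "", USE.NAMES = FALSE)
  }
  out <- rbind(
    if (length(w2)) data.frame(pattern = w2, k = 2L, gapped = FALSE),
    if (length(w3)) data.frame(pattern = w3, k = 3L, gapped = FALSE),
    if (length(w3)) data.frame(pattern = gap_at(w3, 2L), k = 3L,
                               gapped = TRUE),
    if (length(w4)) data.frame(pattern = w4, k = 4L, gapped = FALSE),
    if (length(w4)) data.frame(pattern = gap_at(w4, 2L), k = 4L,
                               gapped = TRUE),
    if (length(w4)) data.frame(pattern = gap_at(w4, 3L), k = 4L,
                               gapped = TRUE),
    if (length(w4)) data.frame(pattern = gap_at(w4, c(2L, 3L)), k = 4L,
                               gapped = TRUE)
  )
  out <- unique(out)
  rownames(out) <- NULL
  out
}

validate_pattern <- function(pattern) {
  ok <- grepl("^[A-WY]{2}$|^[A-WY]x?[A-WY]{1,2}$|^[A-WY]{2}x[A-WY]$|^[A-WY]xx[A-WY]$|^[A-WY]{3,4}$",
              pattern)
  chars <- strsplit(pattern, "")[[1]]
  legal <- all(chars %in% c(AA_ALPHABET20, "x"))
  nc <- nchar(pattern)
  if (!legal || nc < 2L || nc > 4L ||
      chars[1] == "x" || chars[nc] == "x") {
    stop("invalid fragment pattern: ", pattern)
  }
  invisible(pattern)
}

#' Test whether a (possibly gapped) fragment occurs in sequences
#'
#' The wildcard \code{x} matches any single residue; a pattern matches
#' when some window of the sequence matches it position-wise.
#'
#' @param pattern fragment pattern (2-4 residues, interior \code{x}
#'   wildcards allowed).
#' @param seqs character vector of ungapped sequences.
#' @return logical vector, one per sequence.
#' @export
match_fragment <- function(pattern, seqs) {
  validate_pattern(pattern)
  rx <- gsub("x", ".", pattern, fixed = TRUE)
  grepl(rx, seqs)
}

normalize_region_set <- function(x) {
  # each ortholog is a character vector of >=1 segments (ECL2: pre/post)
  if (is.character(x)) x <- as.list(x)
  lapply(x, function(s) s[nzchar(s)])
}

#' Fragment conservation among orthologs and paralogs
#'
#' For every fragment enumerated from any sequence, the ortholog fraction
#' of a paralog is the share of that paralog's ortholog sequences
#' containing the fragment (each sequence counted once; multi-segment
#' regions such as ECL2 pre/post are pooled per sequence before
#' counting). Fragments with ortholog fraction at or above the threshold
#' are flagged putative SLiMs for that paralog. The paralog fraction of a
#' fragment is the share of paralogs whose (reference) region contains
#' it.
#'
#' @param ortholog_regions named list: paralog -> list of ortholog region
#'   strings (each ortholog either a single string or a character vector
#'   of segments). Paralogs with an empty ortholog set are skipped with a
#'   message.
#' @param paralog_regions optional named list/character: the reference
#'   (human) region per paralog, used for paralog presence; defaults to
#'   "present in any ortholog".
#' @param threshold putative-SLiM ortholog-conservation threshold
#'   (default 0.5).
#' @return data.frame with \code{pattern}, \code{k}, \code{gapped},
#'   \code{paralog}, \code{ortholog_fraction}, \code{n_orthologs},
#'   \code{present_in_paralog}, \code{putative_slim}; attribute
#'   \code{paralog_fraction} holds the per-pattern data.frame.
#' @export
fragment_conservation <- function(ortholog_regions,
                                  paralog_regions = NULL,
                                  threshold = 0.5) {
  sets <- lapply(ortholog_regions, normalize_region_set)
  empty <- vapply(sets, function(s) length(s) == 0L, NA)
  if (any(empty)) {
    message("skipping paralog(s) without orthologs: ",
            paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  if (!length(sets)) stop("no paralogs with ortholog sequences")
  frag_tab <- unique(do.call(rbind, lapply(sets, function(orths) {
    do.call(rbind, lapply(orths, function(segs) {
      do.call(rbind, lapply(segs, enumerate_fragments))
    }))
  })))
  if (!is.null(paralog_regions)) {
    pr <- normalize_region_set(paralog_regions)
    frag_tab <- unique(rbind(frag_tab, do.call(rbind, lapply(pr, function(segs) {
      do.call(rbind, lapply(segs, enumerate_fragments))
    }))))
  }
  rownames(frag_tab) <- NULL
  patterns <- frag_tab$pattern
  rows <- lapply(names(sets), function(p) {
    orths <- sets[[p]]
    pooled <- vapply(orths, paste, "", collapse = "\n")  # segments pooled
    hits <- vapply(patterns, function(pt) {
      rx <- gsub("x", ".", pt, fixed = TRUE)
      sum(vapply(orths, function(segs) any(grepl(rx, segs)), NA))
    }, 0L)
    frac <- hits / length(orths)
    present <- if (!is.null(paralog_regions)) {
      segs <- normalize_region_set(paralog_regions)[[p]]
      vapply(patterns, function(pt) {
        any(grepl(gsub("x", ".", pt, fixed = TRUE), segs))
      }, NA)
    } else {
      frac > 0
    }
    data.frame(pattern = patterns, k = frag_tab$k,
               gapped = frag_tab$gapped, paralog = p,
               ortholog_fraction = frac,
               n_orthologs = length(orths),
               present_in_paralog = present,
               putative_slim = frac >= threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  pres <- tapply(out$present_in_paralog, out$pattern, sum)
  attr(out, "paralog_fraction") <- data.frame(
    pattern = names(pres),
    paralog_fraction = as.numeric(pres) / length(sets),
    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  out
}

#' Fragment fingerprints and sharing summaries
#'
#' The fragment fingerprint is the presence/absence pattern of each
#' fragment across paralogs. Sharing summaries report what fraction of
#' putative SLiMs are unique to one paralog versus shared by at least
#' \code{shared_min} paralogs.
#'
#' @param conservation result of [fragment_conservation()].
#' @param shared_min sharing-bucket threshold (default 5).
#' @return list with \code{matrix} (logical pattern x paralog),
#'   \code{sharing} (data.frame pattern, n_paralogs),
#'   \code{pct_slims_unique}, \code{pct_slims_shared}.
#' @export
fragment_fingerprint <- function(conservation, shared_min = 5L) {
  pats <- sort(unique(conservation$pattern))
  pars <- sort(unique(conservation$paralog))
  m <- matrix(FALSE, length(pats), length(pars),
              dimnames = list(pats, pars))
  m[cbind(conservation$pattern, conservation$paralog)] <-
    conservation$present_in_paralog
  sharing <- data.frame(pattern = pats,
                        n_paralogs = as.integer(rowSums(m)),
                        stringsAsFactors = FALSE)
  slim_pats <- unique(conservation$pattern[conservation$putative_slim])
  n_slim <- length(slim_pats)
  cnt <- sharing$n_paralogs[match(slim_pats, sharing$pattern)]
  list(matrix = m, sharing = sharing,
       pct_slims_unique = if (n_slim) 100 * sum(cnt == 1L) / n_slim
                          else NA_real_,
       pct_slims_shared = if (n_slim) 100 * sum(cnt >= shared_min) / n_slim
                          else NA_real_)
}
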