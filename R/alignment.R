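#' Construct a labeled alignment
#'
#' The central sequence container: aligned sequences with per-sequence
#' metadata and per-column position labels (CCN or CRN). Columns without a
#' label carry \code{NA} and are excluded from all downstream scoring.
#'
#' @param records data.frame with columns \code{seq_id}, \code{paralog},
#'   \code{species}, \code{subfamily} (one of CC, CXC, CX3C, XC, ACKR,
#'   other), \code{role} (ligand or receptor) and optionally \code{regions}
#'   (a list column of named \code{c(start, end)} spans in 1-based ungapped
#'   coordinates, e.g. a signal peptide).
#' @param seqs named character vector of aligned sequences (names must match
#'   \code{seq_id}); the gap symbol is \code{"-"}.
#' @param labels character vector of column labels (length = alignment
#'   width) or NULL for all-unlabeled.
#' @param reference_id optional seq_id of the insertion-free reference row;
#'   if set, the reference must contain no gaps.
#' @return object of class \code{labeled_alignment}.
#' @export
labeled_alignment <- function(records, seqs, labels = NULL,
                              reference_id = NULL) {
  stopifnot(is.data.frame(records), is.character(seqs))
  need <- c("seq_id", "paralog", "species", "subfamily", "role")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(names(seqs))) names(seqs) <- records$seq_id
  if (!setequal(names(seqs), records$seq_id)) {
    stop("sequence names and records$seq_id do not match")
  }
  seqs <- seqs[records$seq_id]
  w <- unique(nchar(seqs))
  if (length(w) != 1L) {
    off <- names(seqs)[nchar(seqs) != max(nchar(seqs))]
    stop("ragged alignment: record(s) ", paste(off, collapse = ", "),
         " differ in aligned length")
  }
  if (is.null(labels)) labels <- rep(NA_character_, w)
  if (length(labels) != w) stop("labels length must equal alignment width")
  lab <- labels[!is.na(labels)]
  if (anyDuplicated(lab)) {
    stop("duplicate column labels: ",
         paste(unique(lab[duplicated(lab)]), collapse = ", "))
  }
  if (!is.null(reference_id)) {
    if (!reference_id %in% records$seq_id) {
      stop("reference_id ", reference_id, " not present in alignment")
    }
    if (grepl(GAP, seqs[[reference_id]], fixed = TRUE)) {
      stop("reference row ", reference_id,
           " contains gaps; insertion-free contract violated")
    }
  }
  structure(list(records = records, seqs = seqs, labels = labels,
                 reference_id = reference_id),
            class = "labeled_alignment")
}

#' @export
print.labeled_alignment <- function(x, ...) {
  cat("labeled_alignment: ", length(x$seqs), " sequences x ",
      nchar(x$seqs[[1]]), " columns (",
      sum(!is.na(x$labels)), " labeled)\n", sep = "")
  cat("  roles: ", paste(unique(x$records$role), collapse = ", "),
      "; subfamilies: ",
      paste(sort(unique(x$records$subfamily)), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Alignment width (number of columns)
#' @param aln a \code{labeled_alignment}.
#' @export
aln_width <- function(aln) nchar(aln$seqs[[1]])

#' Alignment as a character matrix (rows = sequences, columns = positions)
#' @param aln a \code{labeled_alignment}.
#' @export
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(m) <- names(aln$seqs)
  m
}

format_regions <- function(regions) {
  if (is.null(regions)) return("")
  vapply(regions, function(r) {
    if (is.null(r) || !length(r)) return("")
    paste(sprintf("%s:%d-%d", names(r), vapply(r, `[`, 0L, 1L),
                  vapply(r, `[`, 0L, 2L)), collapse = ";")
  }, "")
}

parse_regions <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(list())
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    nm <- sub(":.*$", "", parts)
    sp <- sub("^[^:]*:", "", parts)
    out <- lapply(strsplit(sp, "-", fixed = TRUE),
                  function(v) as.integer(v))
    names(out) <- nm
    out
  })
}

#' Read an aligned FASTA file with its metadata sidecar
#'
#' @param fasta path to an aligned FASTA file (gap symbol \code{"-"}).
#' @param meta path to a tab-separated sidecar with columns \code{seq_id},
#'   \code{paralog}, \code{species}, \code{subfamily}, \code{role} and
#'   optionally \code{regions} (\code{"name:start-end;..."} syntax) and
#'   \code{ortholog_group}.
#' @param reference_id optional insertion-free reference seq_id.
#' @return a \code{labeled_alignment} with all columns unlabeled.
#' @export
read_alignment <- function(fasta, meta, reference_id = NULL) {
  aa <- Biostrings::readAAStringSet(fasta)
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  md <- utils::read.delim(meta, stringsAsFactors = FALSE)
  absent <- setdiff(names(seqs), md$seq_id)
  if (length(absent)) {
    stop("missing metadata for record(s): ", paste(absent, collapse = ", "))
  }
  md <- md[match(names(seqs), md$seq_id), , drop = FALSE]
  if ("regions" %in% names(md)) {
    md$regions <- parse_regions(md$regions)
  }
  labeled_alignment(md, seqs, reference_id = reference_id)
}

#' Write an alignment and its metadata sidecar
#'
#' Round trips through [read_alignment()]: residues and metadata are
#' reproduced exactly.
#'
#' @param aln a \code{labeled_alignment}.
#' @param fasta,meta output paths.
#' @export
write_alignment <- function(aln, fasta, meta) {
  aa <- Biostrings::AAStringSet(aln$seqs)
  Biostrings::writeXStringSet(aa, fasta)
  md <- aln$records
  if ("regions" %in% names(md)) {
    md$regions <- format_regions(md$regions)
  }
  utils::write.table(md, meta, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(aln)
}

#' Project an alignment onto its insertion-free reference
#'
#' Deletes every column at which the reference row has a gap, preserving
#' the labels of retained columns. Idempotent; no rows are removed.
#'
#' @param aln a \code{labeled_alignment}.
#' @param reference_id reference sequence id (defaults to the alignment's).
#' @return a \code{labeled_alignment} satisfying the insertion-free
#'   contract.
#' @export
project_to_reference <- function(aln, reference_id = aln$reference_id) {
  if (is.null(reference_id)) stop("no reference_id given or stored")
  if (!reference_id %in% names(aln$seqs)) {
    stop("reference ", reference_id, " absent from alignment")
  }
  ref <- strsplit(aln$seqs[[reference_id]], "")[[1]]
  keep <- ref != GAP
  m <- aln_matrix(aln)[, keep, drop = FALSE]
  seqs <- apply(m, 1L, paste, collapse = "")
  labeled_alignment(aln$records, seqs, aln$labels[keep],
                    reference_id = reference_id)
}

#' Map a native residue index to its position label (and back)
#'
#' \code{map_residue} resolves the 1-based ungapped residue index of one
#' sequence to the label of the column it occupies. The inverse,
#' \code{label_to_index}, resolves a label back to the native index, or
#' reports the residue absent when that sequence has a gap at the column.
#'
#' @param aln a \code{labeled_alignment}.
#' @param seq_id sequence identifier.
#' @param native_index 1-based ungapped residue position.
#' @return \code{map_residue}: list with \code{label} (NA when the column
#'   is unlabeled) and \code{status} (\code{"labeled"} or
#'   \code{"unlabeled"}). \code{label_to_index}: the native index, or NA
#'   with attribute \code{status = "absent"} when gapped.
#' @export
map_residue <- function(aln, seq_id, native_index) {
  if (!seq_id %in% names(aln$seqs)) stop("unknown seq_id: ", seq_id)
  chars <- strsplit(aln$seqs[[seq_id]], "")[[1]]
  idx <- cumsum(chars != GAP)
  n <- idx[length(idx)]
  if (native_index < 1L || native_index > n) {
    stop("native_index ", native_index, " outside sequence ", seq_id,
         " (length ", n, ")")
  }
  col <- which(idx == native_index & chars != GAP)
  lab <- aln$labels[col]
  list(label = lab, column = col,
       status = if (is.na(lab)) "unlabeled" else "labeled")
}

#' @rdname map_residue
#' @param label a position label present among the alignment's columns.
#' @export
label_to_index <- function(aln, seq_id, label) {
  col <- match(label, aln$labels)
  if (is.na(col)) stop("label ", label, " not assigned in this alignment")
  if (!seq_id %in% names(aln$seqs)) stop("unknown seq_id: ", seq_id)
  chars <- strsplit(aln$seqs[[seq_id]], "")[[1]]
  if (chars[col] == GAP) {
    return(structure(NA_integer_, status = "absent"))
  }
  sum(chars[seq_len(col)] != GAP)
}

#' Extract ungapped unstructured-region strings per sequence
#'
#' Regions are resolved from column labels: \code{"NTc"}/\code{"NTr"} are
#' the anchor-stacked Cm columns (trimmed past an annotated signal peptide
#' when the record carries one), and \code{"ECL2"} returns the pre-anchor
#' (ECL2.1...) and post-anchor (ECL2.Cp...) segments separately, never
#' including the conserved-cysteine 45x50-45x52 block. A custom region is a
#' column span \code{c(start, end)}.
#'
#' @param aln a \code{labeled_alignment}.
#' @param region \code{"NTc"}, \code{"NTr"}, \code{"ECL2"} or an integer
#'   column span.
#' @return named character vector of ungapped strings, or for ECL2 a list
#'   with elements \code{pre} and \code{post}.
#' @export
extract_region <- function(aln, region) {
  m <- aln_matrix(aln)
  p <- parse_label(ifelse(is.na(aln$labels), "ZZ.1", aln$labels))
  take <- function(cols) {
    out <- apply(m[, cols, drop = FALSE], 1L, function(r) {
      paste(r[r != GAP], collapse = "")
    })
    names(out) <- names(aln$seqs)
    out
  }
  if (is.numeric(region)) {
    stopifnot(length(region) == 2L, region[1] >= 1L,
              region[2] <= aln_width(aln))
    return(take(seq(region[1], region[2])))
  }
  if (region %in% c("NTc", "NTr")) {
    cols <- which(p$sse == region & p$kind == "Cm")
    if (!length(cols)) stop("no ", region, " (Cm) columns labeled")
    cols <- cols[order(-p$index[cols])]  # Cm_k ... Cm1, N- to C-terminal
    out <- take(cols)
    # trim residues inside an annotated signal peptide (ungapped coords)
    if ("regions" %in% names(aln$records)) {
      for (i in seq_along(out)) {
        reg <- aln$records$regions[[i]]
        sp <- reg[["signal_peptide"]]
        if (!is.null(sp)) {
          chars <- strsplit(aln$seqs[[i]], "")[[1]]
          native <- cumsum(chars != GAP)
          keep <- vapply(cols, function(cc) {
            chars[cc] != GAP && native[cc] > sp[2]
          }, NA)
          out[i] <- paste(chars[cols[keep]], collapse = "")
        }
      }
    }
    empty <- !nzchar(out)
    if (any(empty)) {
      warning(region, " region empty for: ",
              paste(names(out)[empty], collapse = ", "))
    }
    return(out)
  }
  if (region == "ECL2") {
    pre <- which(p$sse == "ECL2" & p$kind == "plain")
    post <- which(p$sse == "ECL2" & p$kind == "Cp")
    if (!length(pre) && !length(post)) stop("no ECL2 columns labeled")
    list(pre = if (length(pre)) take(pre[order(p$index[pre])]) else
           stats::setNames(rep("", length(aln$seqs)), names(aln$seqs)),
         post = if (length(post)) take(post[order(p$index[post])]) else
           stats::setNames(rep("", length(aln$seqs)), names(aln$seqs)))
  } else {
    stop("unknown region: ", region)
  }
}
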