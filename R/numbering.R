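#' Define how alignment columns map to common-numbering labels
#'
#' A numbering configuration lists the SSE spans of an alignment and how
#' each is indexed. The numbering conventions are expressed through the
#' \code{kind} of each span:
#' \describe{
#'   \item{plain}{\code{SSE.index}, index counting 1-based (or from
#'     \code{start_index}) from the span start, e.g. \code{B3.1, B3.2, ...}}
#'   \item{gpcrdb}{GPCRdb generic numbers: \code{sse} is the helix prefix
#'     with trailing \code{"x"} (e.g. \code{"1x"}) and indexing starts at
#'     \code{start_index} (e.g. 22 for the extended anchor-cysteine TM1),
#'     yielding \code{1x22, 1x23, ...}}
#'   \item{Cm}{anchor-cysteine stacking toward the N-terminus: the column
#'     immediately preceding the anchor is \code{SSE.Cm1}, the one before
#'     it \code{SSE.Cm2}, and so on.}
#'   \item{Cp}{post-anchor ECL2 indexing starting at \code{start_index}
#'     (3, since the conserved ECL2 cysteine block occupies 45x50-45x52):
#'     \code{ECL2.Cp3, ECL2.Cp4, ...}}
#' }
#'
#' @param scheme \code{"CCN"} or \code{"CRN"}.
#' @param spans data.frame with columns \code{sse}, \code{start},
#'   \code{end} (alignment columns, 1-based inclusive) and optionally
#'   \code{kind} (default \code{"plain"}) and \code{start_index}
#'   (default 1; ignored for \code{Cm}).
#' @param anchor alignment column of the anchor cysteine used by Cm
#'   stacking (CCN: the CX.1 cysteine; CRN: the 1x22 cysteine). Required
#'   when any span has kind \code{"Cm"}.
#' @return object of class \code{numbering_config}.
#' @export
numbering_config <- function(scheme = c("CCN", "CRN"), spans, anchor = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(is.data.frame(spans), all(c("sse", "start", "end") %in%
                                        names(spans)))
  if (is.null(spans$kind)) spans$kind <- "plain"
  if (is.null(spans$start_index)) spans$start_index <- 1L
  spans$start_index[is.na(spans$start_index)] <- 1L
  spans <- spans[order(spans$start), , drop = FALSE]
  if (any(spans$end < spans$start)) stop("span end precedes start")
  if (nrow(spans) > 1L &&
      any(spans$start[-1L] <= spans$end[-nrow(spans)])) {
    stop("overlapping SSE spans in numbering config")
  }
  if (any(spans$kind == "Cm") && is.null(anchor)) {
    stop("Cm stacking requires an anchor column")
  }
  if (scheme == "CCN") {
    known <- spans$kind != "gpcrdb" & !(spans$sse %in% CCN_SSE)
    if (any(known)) {
      stop("unknown CCN SSE identifier(s): ",
           paste(unique(spans$sse[known]), collapse = ", "))
    }
  }
  structure(list(scheme = scheme, spans = spans, anchor = anchor),
            class = "numbering_config")
}

#' Read a numbering configuration from YAML
#'
#' Expected keys: \code{scheme}, \code{anchor} (optional) and
#' \code{spans}, a list of maps with \code{sse}, \code{start}, \code{end}
#' and optional \code{kind}, \code{start_index}.
#'
#' @param path YAML file path.
#' @export
read_numbering_config <- function(path) {
  y <- yaml::read_yaml(path)
  spans <- do.call(rbind, lapply(y$spans, function(s) {
    data.frame(sse = s$sse, start = as.integer(s$start),
               end = as.integer(s$end),
               kind = if (is.null(s$kind)) "plain" else s$kind,
               start_index = if (is.null(s$start_index)) 1L else
                 as.integer(s$start_index),
               stringsAsFactors = FALSE)
  }))
  numbering_config(y$scheme, spans,
                   anchor = if (is.null(y$anchor)) NULL else
                     as.integer(y$anchor))
}

#' Assign common-numbering labels to alignment columns
#'
#' Every column inside an SSE span receives its label per the span's
#' indexing convention (see [numbering_config()]). When the configuration
#' carries an anchor and the alignment a reference row, the reference
#' residue at the anchor column is checked to be cysteine; a non-cysteine
#' anchor (the CXCR6 case among human receptors) raises a warning and
#' assignment proceeds.
#'
#' @param aln a \code{labeled_alignment}.
#' @param cfg a \code{numbering_config}.
#' @return the alignment with column labels assigned.
#' @export
assign_labels <- function(aln, cfg) {
  stopifnot(inherits(cfg, "numbering_config"))
  w <- aln_width(aln)
  if (any(cfg$spans$end > w)) stop("SSE span exceeds alignment width")
  if (!is.null(cfg$anchor)) {
    if (cfg$anchor < 1L || cfg$anchor > w) {
      stop("anchor column outside the alignment")
    }
    ref_id <- aln$reference_id
    if (!is.null(ref_id)) {
      res <- substr(aln$seqs[[ref_id]], cfg$anchor, cfg$anchor)
      if (res != "C") {
        warning("anchor column ", cfg$anchor, " is '", res,
                "' (not cysteine) in reference ", ref_id,
                "; proceeding with stacking anyway")
      }
    }
  }
  labels <- rep(NA_character_, w)
  for (i in seq_len(nrow(cfg$spans))) {
    s <- cfg$spans[i, ]
    cols <- seq(s$start, s$end)
    labels[cols] <- switch(
      s$kind,
      plain = format_label(rep(s$sse, length(cols)),
                           s$start_index + seq_along(cols) - 1L, "plain"),
      gpcrdb = format_label(rep(s$sse, length(cols)),
                            s$start_index + seq_along(cols) - 1L, "gpcrdb"),
      Cm = format_label(rep(s$sse, length(cols)), cfg$anchor - cols, "Cm"),
      Cp = format_label(rep(s$sse, length(cols)),
                        s$start_index + seq_along(cols) - 1L, "Cp"),
      stop("unknown span kind: ", s$kind)
    )
  }
  labeled_alignment(aln$records, aln$seqs, labels,
                    reference_id = aln$reference_id)
}

#' Read or write residue-to-label mapping tables
#'
#' Plain TSV with columns \code{protein}, \code{native_index},
#' \code{label}, as used to attach label maps to complex structures and to
#' map variant tables.
#'
#' @param path TSV path.
#' @return data.frame with those three columns.
#' @export
read_label_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein", "native_index", "label")
  if (!all(need %in% names(tab))) {
    stop("label map must have columns: ", paste(need, collapse = ", "))
  }
  tab$native_index <- as.integer(tab$native_index)
  parse_label(tab$label)  # validates
  tab
}

#' Derive a residue-to-label map from an alignment row
#'
#' @param aln a \code{labeled_alignment}.
#' @param seq_id which sequence.
#' @return named character vector label per native index (names are the
#'   native indices); unlabeled positions are omitted.
#' @export
label_map_from_alignment <- function(aln, seq_id) {
  chars <- strsplit(aln$seqs[[seq_id]], "")[[1]]
  nongap <- which(chars != GAP)
  lab <- aln$labels[nongap]
  keep <- !is.na(lab)
  stats::setNames(lab[keep], seq_along(nongap)[keep])
}
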