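#' Secondary structure element vocabulary for common chemokine numbering
#'
#' CCN labels name chemokine positions by consensus secondary structure
#' element (SSE) and a 1-based index within the element, e.g. \code{"B3.3"}
#' is the third position of the third beta strand. N-terminal residues are
#' stacked gap-free against the first disulfide-bonding cysteine and indexed
#' \code{"NTc.CmK"} ("cysteine minus K").
#'
#' @format Character vector of valid CCN SSE identifiers, N- to C-terminal.
#' @export
CCN_SSE <- c("NTc", "CX", "cxb1", "B1", "b1b2", "B2", "b2b3", "B3",
             "b3h", "H", "CT")

#' The 20 standard amino-acid one-letter codes
#' @export
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Gap symbol used in aligned sequences
#' @export
GAP <- "-"

#' Parse common-numbering position labels
#'
#' Accepts the canonical string forms used across the package:
#' \itemize{
#'   \item SSE.index, e.g. \code{"B3.3"}, \code{"ECL2.5"}
#'   \item anchor-relative stacking, e.g. \code{"NTc.Cm3"}, \code{"NTr.Cm9"}
#'   \item post-anchor ECL2 indexing, e.g. \code{"ECL2.Cp3"}
#'   \item GPCRdb generic numbers, e.g. \code{"1x22"}, \code{"45x50"}
#' }
#'
#' @param x character vector of labels.
#' @return data.frame with columns \code{label}, \code{sse}, \code{kind}
#'   (one of \code{"plain"}, \code{"Cm"}, \code{"Cp"}, \code{"gpcrdb"}) and
#'   \code{index} (integer).
#' @export
parse_label <- function(x) {
  stopifnot(is.character(x))
  out <- data.frame(label = x, sse = NA_character_, kind = NA_character_,
                    index = NA_integer_, stringsAsFactors = FALSE)
  cm <- grepl("^[A-Za-z][A-Za-z0-9]*\\.Cm[0-9]+$", x)
  cp <- grepl("^[A-Za-z][A-Za-z0-9]*\\.Cp[0-9]+$", x)
  gp <- grepl("^[0-9]+x[0-9]+$", x)
  pl <- grepl("^[A-Za-z][A-Za-z0-9]*\\.[0-9]+$", x) & !cm & !cp
  out$sse[cm] <- sub("\\.Cm[0-9]+$", "", x[cm])
  out$kind[cm] <- "Cm"
  out$index[cm] <- as.integer(sub("^.*\\.Cm", "", x[cm]))
  out$sse[cp] <- sub("\\.Cp[0-9]+$", "", x[cp])
  out$kind[cp] <- "Cp"
  out$index[cp] <- as.integer(sub("^.*\\.Cp", "", x[cp]))
  out$sse[gp] <- paste0(sub("x[0-9]+$", "", x[gp]), "x")
  out$kind[gp] <- "gpcrdb"
  out$index[gp] <- as.integer(sub("^[0-9]+x", "", x[gp]))
  out$sse[pl] <- sub("\\.[0-9]+$", "", x[pl])
  out$kind[pl] <- "plain"
  out$index[pl] <- as.integer(sub("^.*\\.", "", x[pl]))
  bad <- !(cm | cp | gp | pl) & !is.na(x)
  if (any(bad)) {
    stop("invalid position label(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  out
}

#' Format a position label from its parts
#'
#' Inverse of [parse_label()]: \code{format_label(parse_label(x))} round
#' trips the canonical string.
#'
#' @param sse SSE identifier (for GPCRdb labels the helix prefix with a
#'   trailing \code{"x"}, e.g. \code{"1x"}), or the data.frame returned by
#'   [parse_label()].
#' @param index integer index.
#' @param kind one of \code{"plain"}, \code{"Cm"}, \code{"Cp"},
#'   \code{"gpcrdb"}.
#' @return character vector of canonical labels.
#' @export
format_label <- function(sse, index = NULL, kind = "plain") {
  if (is.data.frame(sse)) {
    index <- sse$index
    kind <- sse$kind
    sse <- sse$sse
  }
  stopifnot(length(sse) == length(index))
  kind <- rep_len(kind, length(sse))
  out <- character(length(sse))
  out[kind == "plain"] <- paste0(sse[kind == "plain"], ".",
                                 index[kind == "plain"])
  out[kind == "Cm"] <- paste0(sse[kind == "Cm"], ".Cm", index[kind == "Cm"])
  out[kind == "Cp"] <- paste0(sse[kind == "Cp"], ".Cp", index[kind == "Cp"])
  out[kind == "gpcrdb"] <- paste0(sse[kind == "gpcrdb"],
                                  index[kind == "gpcrdb"])
  out
}

#' Map a position label to its broad structural region
#'
#' CCN labels map to their SSE; CRN GPCRdb numbers map to the helix or loop
#' they belong to (\code{"1x22"} to \code{"TM1"}, \code{"45x50"} to
#' \code{"ECL2"}, ...), ECL2 pass-through and Cp labels to \code{"ECL2"},
#' and stacked N-terminal labels to \code{"NTr"}/\code{"NTc"}.
#'
#' @param x character vector of labels.
#' @return character vector of region names.
#' @export
label_region <- function(x) {
  p <- parse_label(x)
  reg <- p$sse
  gp <- p$kind == "gpcrdb" & !is.na(p$kind)
  helix <- sub("x$", "", p$sse[gp])
  loopmap <- c("12" = "ICL1", "23" = "ECL1", "34" = "ICL2", "45" = "ECL2",
               "56" = "ICL3", "67" = "ECL3", "8" = "H8")
  reg[gp] <- ifelse(helix %in% names(loopmap), loopmap[helix],
                    paste0("TM", helix))
  reg
}
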