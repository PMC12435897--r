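#' Human chemokine paralogs with subfamily assignments
#'
#' The 46 human chemokine paralogs (canonical gene symbols) with their
#' subfamily derived from the systematic name: 26 CC, 17 CXC, one CX3C
#' and two XC chemokines.
#'
#' @return data.frame with \code{paralog} and \code{subfamily}.
#' @export
chemokine_paralogs <- function() {
  cc <- c("CCL1", "CCL2", "CCL3", "CCL3L1", "CCL4", "CCL4L1", "CCL5",
          "CCL7", "CCL8", "CCL11", "CCL13", "CCL14", "CCL15", "CCL16",
          "CCL17", "CCL18", "CCL19", "CCL20", "CCL21", "CCL22", "CCL23",
          "CCL24", "CCL25", "CCL26", "CCL27", "CCL28")
  cxc <- c("CXCL1", "CXCL2", "CXCL3", "CXCL4", "CXCL4L1", "CXCL5",
           "CXCL6", "CXCL7", "CXCL8", "CXCL9", "CXCL10", "CXCL11",
           "CXCL12", "CXCL13", "CXCL14", "CXCL16", "CXCL17")
  data.frame(
    paralog = c(cc, cxc, "CX3CL1", "XCL1", "XCL2"),
    subfamily = c(rep("CC", length(cc)), rep("CXC", length(cxc)),
                  "CX3C", "XC", "XC"),
    stringsAsFactors = FALSE)
}

#' Human chemokine receptor paralogs with subfamily assignments
#'
#' The 23 human chemokine receptors: 10 CC and 6 CXC conventional
#' receptors, CX3CR1, XCR1, and the atypical set (ACKR1-4 and CCRL2)
#' flagged \code{ackr = TRUE}.
#'
#' @return data.frame with \code{paralog}, \code{subfamily}, \code{ackr}.
#' @export
receptor_paralogs <- function() {
  cc <- paste0("CCR", 1:10)
  cxc <- paste0("CXCR", 1:6)
  atyp <- c("ACKR1", "ACKR2", "ACKR3", "ACKR4", "CCRL2")
  data.frame(
    paralog = c(cc, cxc, "CX3CR1", "XCR1", atyp),
    subfamily = c(rep("CC", 10), rep("CXC", 6), "CX3C", "XC",
                  rep("ACKR", 5)),
    ackr = c(rep(FALSE, 18), rep(TRUE, 5)),
    stringsAsFactors = FALSE)
}
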