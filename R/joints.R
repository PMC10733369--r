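#' The 28-joint vocabulary of the DAS28 score
#'
#' The DAS28 assesses 28 predefined joints: shoulders, elbows, wrists,
#' metacarpophalangeal joints 1-5 (MCP), proximal interphalangeal joints 1-5
#' (PIP), and knees, each bilaterally. Joint identifiers are
#' `<joint>_<side>`, e.g. `mcp2_right` for the metacarpophalangeal joint of
#' the right index finger.
#'
#' @return Character vector of the 28 joint identifiers, in the fixed order
#'   used throughout the package (left side first, then right; within a side:
#'   shoulder, elbow, wrist, mcp1-5, pip1-5, knee).
#' @export
#' @examples
#' joint_names()
joint_names <- function() {
  base <- c("shoulder", "elbow", "wrist",
            paste0("mcp", 1:5), paste0("pip", 1:5), "knee")
  c(paste0(base, "_left"), paste0(base, "_right"))
}

#' @rdname joint_names
#' @export
tender_columns <- function() paste0("tender_", joint_names())

#' @rdname joint_names
#' @export
swollen_columns <- function() paste0("swollen_", joint_names())
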