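# Nucleus-level quality control.

#' Nucleus QC predicate
#'
#' A nucleus passes QC when it is neither abnormally shaped
#' (`solidity < 0.85`), nor abnormally small (`area < 30` square micron,
#' indicative of micronuclei), nor touching the field border. Inequalities are
#' strict: boundary values pass.
#'
#' @param area Nuclear area in square micron.
#' @param solidity Mask area / convex hull area.
#' @param border_touching Logical; TRUE when the mask touches the field edge.
#' @param min_area Area threshold (square micron), default 30.
#' @param min_solidity Solidity threshold, default 0.85.
#' @return Logical vector.
#' @export
nucleus_qc <- function(area, solidity, border_touching = FALSE,
                       min_area = 30, min_solidity = 0.85) {
  !(solidity < min_solidity) & !(area < min_area) & !border_touching
}
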