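#' Radiosensitivity classification of lung, breast and colorectal lines
#'
#' Literature-derived radiosensitive (RS) / radioresistant (RR) labels for
#' 42 cancer cell lines: 14 lung (7 RR / 7 RS), 16 breast (8 RR / 8 RS)
#' and 12 colorectal (7 RR / 5 RS). HCT116, the reference line of the
#' expression scaling, is among the radiosensitive colorectal lines.
#'
#' @return data.frame with columns `line`, `tissue`
#'   (lung/breast/colorectal) and `label` (RS/RR).
#' @export
load_classification <- function() {
  lung_rr <- c("A549", "H1703", "H661", "H1299", "H1339", "H292", "H358")
  lung_rs <- c("H23", "H441", "H1650", "H522", "HCC827", "H69", "H460")
  breast_rr <- c("MCF-7", "SK-BR-3", "ZR-751", "HCC1428", "T47D",
                 "HS578T", "UACC-812", "MDA-MB-175VII")
  breast_rs <- c("MDA-MB-361", "HCC70", "MDA-MB-231", "BT474", "JIMT-1",
                 "CAL-51", "HCC1395", "MDA-MB-468")
  colorectal_rr <- c("HT115", "DLD-1", "Lovo", "HT29", "Caco-2", "SW480",
                     "MDST8")
  colorectal_rs <- c("Colo-201", "Colo-205", "Colo-320", "HCT116", "SW48")
  df <- data.frame(
    line = c(lung_rr, lung_rs, breast_rr, breast_rs,
             colorectal_rr, colorectal_rs),
    tissue = rep(c("lung", "breast", "colorectal"),
                 times = c(length(lung_rr) + length(lung_rs),
                           length(breast_rr) + length(breast_rs),
                           length(colorectal_rr) + length(colorectal_rs))),
    label = c(rep("RR", length(lung_rr)), rep("RS", length(lung_rs)),
              rep("RR", length(breast_rr)), rep("RS", length(breast_rs)),
              rep("RR", length(colorectal_rr)),
              rep("RS", length(colorectal_rs))),
    stringsAsFactors = FALSE)
  df
}
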