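# IMGT unique-numbering conventions for TCR V domains.
#
# Positions run 1-128; the V segment covers 1-104 (ending at the second
# conserved cysteine, 2nd-CYS 104), CDR3 spans 105-117 and FR4 (J-encoded)
# 118-128.  Region boundaries are fixed by the scheme, not by the sequence.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP_CHAR <- "."

V_FRAME_LENGTH <- 104L  # gapped V-segment string length (positions 1-104)
IMGT_MAX_POSITION <- 128L
CDR3_POSITIONS <- 105:117

IMGT_REGIONS <- data.table::data.table(
  region = c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4"),
  start  = c(1L, 27L, 39L, 56L, 66L, 105L, 118L),
  end    = c(26L, 38L, 55L, 65L, 104L, 117L, 128L)
)

# Conserved anchors of the V-domain fold: 1st-CYS 23, conserved TRP 41,
# 2nd-CYS 104.
IMGT_ANCHORS <- c(`23` = "C", `41` = "W", `104` = "C")

#' Classify IMGT positions into framework and CDR regions
#'
#' Maps 1-based IMGT positions of a TCR V domain onto the fixed region
#' scheme: FR1 1-26, CDR1 27-38, FR2 39-55, CDR2 56-65, FR3 66-104,
#' CDR3 105-117, FR4 118-128.
#'
#' @param position integer vector of IMGT positions (1-128).
#' @return character vector of region labels.
#' @examples
#' imgt_region(c(1, 30, 96, 110))
#' @export
imgt_region <- function(position) {
  position <- as.integer(position)
  if (any(is.na(position) | position < 1L | position > IMGT_MAX_POSITION)) {
    abort("IMGT positions must lie in 1-%d", IMGT_MAX_POSITION)
  }
  idx <- findInterval(position, IMGT_REGIONS$start)
  IMGT_REGIONS$region[idx]
}

is_framework_position <- function(position, include_fr4 = FALSE) {
  reg <- imgt_region(position)
  reg %in% c("FR1", "FR2", "FR3", if (include_fr4) "FR4")
}

valid_aa <- function(x) {
  all(strsplit(paste(x, collapse = ""), "")[[1]] %in% AA20)
}

# Packaged J-segment name pools used by the synthetic generator; allele-free
# IMGT-style identifiers.
TRAJ_NAMES <- paste0("TRAJ", c(4L, 9L, 13L, 23L, 31L, 42L, 49L, 53L))
TRBJ_NAMES <- c("TRBJ1-1", "TRBJ1-2", "TRBJ1-5",
                "TRBJ2-1", "TRBJ2-3", "TRBJ2-5", "TRBJ2-7")

V_GENE_PATTERN <- "^TR[AB]V[0-9]+(-[0-9]+)?(\\*[0-9]+)?$"

# Strip an IMGT allele suffix ("*01") down to the gene level.
strip_allele <- function(x) sub("\\*[0-9]+$", "", x)
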