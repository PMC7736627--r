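## Canonical vocabulary for the 39 elements of a vertebrate mitogenome:
## 13 protein-coding genes, 22 tRNAs, 2 rRNAs, the light-strand replication
## origin (OL) and the control region (D-loop), in the canonical gene order
## (tRNA-Phe first, D-loop last).

.canonical_elements <- data.frame(
  name = c(
    "tRNA-Phe", "12S-rRNA", "tRNA-Val", "16S-rRNA", "tRNA-Leu(UUR)",
    "ND1", "tRNA-Ile", "tRNA-Gln", "tRNA-Met", "ND2", "tRNA-Trp",
    "tRNA-Ala", "tRNA-Asn", "OL", "tRNA-Cys", "tRNA-Tyr", "COI",
    "tRNA-Ser(UCN)", "tRNA-Asp", "COII", "tRNA-Lys", "ATP8", "ATP6",
    "COIII", "tRNA-Gly", "ND3", "tRNA-Arg", "ND4L", "ND4", "tRNA-His",
    "tRNA-Ser(AGY)", "tRNA-Leu(CUN)", "ND5", "ND6", "tRNA-Glu", "CYTB",
    "tRNA-Thr", "tRNA-Pro", "D-loop"),
  category = c(
    "tRNA", "rRNA", "tRNA", "rRNA", "tRNA",
    "PCG", "tRNA", "tRNA", "tRNA", "PCG", "tRNA",
    "tRNA", "tRNA", "origin", "tRNA", "tRNA", "PCG",
    "tRNA", "tRNA", "PCG", "tRNA", "PCG", "PCG",
    "PCG", "tRNA", "PCG", "tRNA", "PCG", "PCG", "tRNA",
    "tRNA", "tRNA", "PCG", "PCG", "tRNA", "PCG",
    "tRNA", "tRNA", "control"),
  stringsAsFactors = FALSE
)

## Aliases absorb the mixed naming used across annotation sources
## ("ATPase6" vs "ATP6", "Cyt b" vs "CYTB", "COX1" vs "COI", ...).
.element_aliases <- c(
  "ATPASE6" = "ATP6", "ATPASE8" = "ATP8", "ATP SYNTHASE 6" = "ATP6",
  "CYT B" = "CYTB", "CYTB" = "CYTB", "COB" = "CYTB",
  "COX1" = "COI", "COX2" = "COII", "COX3" = "COIII",
  "CO1" = "COI", "CO2" = "COII", "CO3" = "COIII",
  "12S RRNA" = "12S-rRNA", "16S RRNA" = "16S-rRNA",
  "12S" = "12S-rRNA", "16S" = "16S-rRNA",
  "RRNS" = "12S-rRNA", "RRNL" = "16S-rRNA",
  "O_L" = "OL", "OL" = "OL", "ORIL" = "OL",
  "D-LOOP" = "D-loop", "DLOOP" = "D-loop", "CONTROL REGION" = "D-loop",
  "TRNA-LEU1" = "tRNA-Leu(UUR)", "TRNA-LEU2" = "tRNA-Leu(CUN)",
  "TRNA-SER1" = "tRNA-Ser(UCN)", "TRNA-SER2" = "tRNA-Ser(AGY)"
)

#' Canonical mitogenome element registry
#'
#' The frozen vocabulary of the 39 elements of a complete vertebrate
#' mitogenome in canonical order (tRNA-Phe first, D-loop last), with their
#' categories (13 PCG, 22 tRNA, 2 rRNA, 1 origin, 1 control).
#'
#' @return A data frame with columns `name` and `category`, one row per
#'   canonical element, in canonical order.
#' @export
canonical_elements <- function() .canonical_elements

#' Resolve an element name against the canonical registry
#'
#' Maps common naming variants (e.g. `"ATPase6"`, `"Cyt b"`, `"COX1"`) onto
#' the canonical labels used throughout the package. Unknown names are
#' returned unchanged with a warning when `warn = TRUE`.
#'
#' @param name character vector of element names.
#' @param warn warn about names that resolve to nothing canonical.
#' @return Character vector of canonical names.
#' @export
canonical_name <- function(name, warn = FALSE) {
  out <- as.character(name)
  key <- toupper(trimws(out))
  known <- toupper(.canonical_elements$name)
  for (i in seq_along(out)) {
    if (key[i] %in% known) {
      out[i] <- .canonical_elements$name[match(key[i], known)]
    } else if (key[i] %in% names(.element_aliases)) {
      out[i] <- unname(.element_aliases[key[i]])
    } else if (warn) {
      warning("unknown element name: ", out[i], call. = FALSE)
    }
  }
  out
}

.pcg_names <- .canonical_elements$name[.canonical_elements$category == "PCG"]
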