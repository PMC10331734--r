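#' Chromophore registry
#'
#' Reference information for the six fluorescent proteins covered by the
#' shipped parameter set.  EBFP appears twice because its chromophore
#' histidine is parameterized in both neutral isomers (HID and HIE), so
#' the registry holds seven entries.
#'
#' @return data frame with columns `protein` (registry key), `base_protein`,
#'   `his_form` (HID/HIE for the two EBFP forms, otherwise `NA`),
#'   `tripeptide` (three one-letter-coded residues), `pdb_chromophore_code`
#'   (3-letter chemical-component code), `reference_pdb_id`, and
#'   `net_charge` (elementary charges, -1 or 0).
#' @export
#' @examples
#' chromophore_registry()
chromophore_registry <- function() {
  data.frame(
    protein = c("EGFP", "EBFP-HID", "EBFP-HIE", "ECFP", "EYFP",
                "DsRed", "mCherry"),
    base_protein = c("EGFP", "EBFP", "EBFP", "ECFP", "EYFP",
                     "DsRed", "mCherry"),
    his_form = c(NA, "HID", "HIE", NA, NA, NA, NA),
    tripeptide = c("TYG", "SHG", "SHG", "TWG", "GYG", "QYG", "MYG"),
    residues = c("Thr-Tyr-Gly", "Ser-His-Gly", "Ser-His-Gly",
                 "Thr-Trp-Gly", "Gly-Tyr-Gly", "Gln-Tyr-Gly",
                 "Met-Tyr-Gly"),
    pdb_chromophore_code = c("CRO", "IIC", "IIC", "CRF", "CR2",
                             "CRQ", "CH6"),
    reference_pdb_id = c("2Y0G", "1BFP", "1BFP", "2WSN", "3V3D",
                         "2VAD", "2H5Q"),
    net_charge = c(-1L, 0L, 0L, 0L, -1L, -1L, -1L),
    stringsAsFactors = FALSE
  )
}

#' Look up one chromophore by protein name
#'
#' @param name registry key (`"EGFP"`, `"EBFP-HID"`, ...).  A bare
#'   protein name is accepted when it identifies a unique entry; `"EBFP"`
#'   alone is ambiguous and errors.
#' @return a one-row data frame (a `ChromophoreSpec`).
#' @export
#' @examples
#' chromophore_spec("EGFP")$net_charge  # -1
chromophore_spec <- function(name) {
  reg <- chromophore_registry()
  hit <- reg[reg$protein == name, , drop = FALSE]
  if (!nrow(hit)) hit <- reg[reg$base_protein == name, , drop = FALSE]
  if (!nrow(hit)) {
    stop("chromophore not found in registry: ", name,
         " (known: ", paste(reg$protein, collapse = ", "), ")")
  }
  if (nrow(hit) > 1L) {
    stop("'", name, "' is ambiguous; use one of: ",
         paste(hit$protein, collapse = ", "))
  }
  hit
}
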