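#' Reference values from the xFP chromophore charge tables
#'
#' Selected amide-fix fitted charges distributed with the xFP
#' chromophore parameter set, useful as transcription anchors when
#' regenerating charge tables: the amino-terminal nitrogen charges of
#' the proline-like DsRed and mCherry chromophores (whose N carries no
#' hydrogen and is left free while the adjacent ACE carbonyl is pinned),
#' and the extreme free-fit charges of the EGFP chromophore (its
#' C-terminal carbonyl carbon C3 and the adjacent alpha carbon CA3).
#' The Cornell proline backbone nitrogen (-0.2548 e) is the comparable
#' consensus value for an H-less amide nitrogen; see
#' [consensus_terminal_charges()].
#'
#' @return data frame with columns `chromophore`, `atom`, `model`
#'   (`amide_fix` or `free_fit`) and `charge` (e).
#' @export
xfp_charge_benchmarks <- function() {
  data.frame(
    chromophore = c("DsRed", "mCherry", "EGFP", "EGFP"),
    atom = c("N", "N", "C3", "CA3"),
    model = c("amide_fix", "amide_fix", "free_fit", "free_fit"),
    charge = c(-0.292329, -0.283649, 0.830, -0.768),
    stringsAsFactors = FALSE
  )
}
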