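#' Published per-subject cerebellum CBF values (FAIR ASST vs PICORE)
#'
#' Per-subject cerebellum grey- and white-matter CBF values
#' (mL/100 g/min) from a five-subject 3 T comparison of two pulsed ASL
#' labeling schemes: FAIR ASST (flow-sensitive alternating inversion
#' recovery with superior saturation of the upper labeled bolus) and
#' PICORE (proximal-only inversion with an off-resonance control). These
#' printed values are the worked-example input for [perfusion_report()],
#' [group_stats()] and [paired_ttest()]: reconstructing the derived group
#' rows (means, S.D.s, C.V.s, GM/WM ratios) and method-comparison
#' p-values from them exercises the full reporting path.
#'
#' @return Data.frame with columns `subject`, `fair_gm`, `fair_wm`,
#'   `picore_gm`, `picore_wm` (CBF, mL/100 g/min).
#' @examples
#' ref <- cerebellum_cbf_reference()
#' perfusion_report(ref, methods = c("fair", "picore"))
#' paired_ttest(ref$fair_gm, ref$picore_gm)
#' @export
cerebellum_cbf_reference <- function() {
  data.frame(
    subject   = 1:5,
    fair_gm   = c(42.58, 45.07, 37.89, 41.82, 51.57),
    fair_wm   = c(29.56, 28.63, 20.48, 26.62, 32.53),
    picore_gm = c(41.97, 44.47, 30.28, 33.59, 51.45),
    picore_wm = c(33.50, 28.89, 19.04, 14.71, 22.51)
  )
}
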