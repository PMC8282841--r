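#' Reference ISSR panel summaries
#'
#' Published per-primer summary tables for a 32-primer ISSR panel scored
#' on 44 Bambara groundnut accessions from 11 populations: the
#' diversity table (`na`, `ne`, `h`, `i`, TSB, PB, PPB, `nm` per
#' primer) and the marker-efficiency table (`h`, `pic`, `emr`, `havp`,
#' `mi`, `d`, `rp` per primer). They serve as worked-example inputs:
#' the package's aggregation and index functions reproduce the panel's
#' overall bookkeeping and column means from these per-primer values.
#'
#' @param which `"diversity"` or `"efficiency"`.
#' @return data frame with 32 rows (one per primer).
#' @examples
#' eff <- issr_reference_panel("efficiency")
#' aggregate_metrics(eff)$pic   # panel mean PIC
#' @export
issr_reference_panel <- function(which = c("diversity", "efficiency")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0("issr_panel_", which, ".csv"),
                   package = "bandpop", mustWork = TRUE)
  utils::read.csv(f, check.names = FALSE)
}
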