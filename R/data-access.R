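#' Bundled reference screen results
#'
#' Loads the bundled summary table of a three-tissue cannabis-extract
#' inflammation screen (EpiDermFT skin + UVC; EpiOral and EpiIntestinal
#' tissues + TNFa): one row per dataset with its printed one-sample t
#' statistic over 241 pathways (df = 240), two-sided p-value and drug
#' efficiency index at reporting precision. These printed t statistics are
#' the inputs for reproducing the CDEI formula layer exactly.
#'
#' @return `data.frame` with columns `experiment`, `dataset`,
#'   `sample_class`, `n_profiles`, `t_value`, `p_value`, `cdei`.
#' @examples
#' ref <- referenceScreenResults()
#' subset(ref, experiment == "EpiOral" & sample_class == "treated")
#' @export
referenceScreenResults <- function() {
  path <- system.file("extdata", "reference_screen_results.tsv",
                      package = "cdei", mustWork = TRUE)
  # leading '#' lines are comments, but '#' also occurs inside extract
  # labels, so strip comment lines by hand rather than via comment.char
  txt <- readLines(path)
  utils::read.delim(text = paste(txt[!grepl("^#", txt)], collapse = "\n"),
                    na.strings = "NA", check.names = FALSE)
}
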