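#' AAL-90 region labels
#'
#' The 90 cerebral parcels of the automated anatomical labeling (AAL)
#' atlas in standard order (odd indices = left hemisphere, even = right),
#' read from the bundled fixture.
#'
#' @return a data.frame with columns `id` (1--90) and `name`.
#' @export
#' @examples
#' head(aal90_labels())
aal90_labels <- function() {
  path <- system.file("extdata", "aal90_regions.tsv", package = "brainctrl",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(identical(df$id, 1:90))
  df
}
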