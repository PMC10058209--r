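#' Published AK classification table
#'
#' Loads the published validation table shipped with the package: for each
#' of the 21 AK samples of the original cohort, the histopathological grade,
#' the Euclidean distances to the reference NL and L centroids in
#' signature-PCA space, and the published subclass call. Useful for checking
#' that the nearest-centroid decision rule reproduces the published
#' classification column from the printed distance pairs alone.
#'
#' @return A data.frame with columns `sample_id`, `grade`, `dist_to_NL`,
#'   `dist_to_L`, `classification`.
#' @examples
#' tab <- published_ak_table()
#' all(classify_distance_pairs(tab$dist_to_NL, tab$dist_to_L) ==
#'     tab$classification)
#' @export
published_ak_table <- function() {
  path <- system.file("extdata", "ak_reference_classification.tsv",
                      package = "akstrat", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", quote = "",
                    stringsAsFactors = FALSE)
}
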