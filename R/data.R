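#' Path to a bundled example data file
#'
#' The package ships one example dataset:
#' `occurrences_rarefied_synthetic.csv`, a synthetic stand-in for a rarefied
#' tick-occurrence compilation: 181 presence-only records over an
#' eastern-North-American extent, pairwise separated by at least 50 km
#' (great-circle), each with a coordinate-uncertainty radius below 10,000 m.
#' The coordinates are simulated (clustered sampling thinned with
#' [thin_occurrences()]), not real collection localities.
#'
#' @param file file name; with no argument, lists available files.
#' @return full path to the file.
#' @export
#' @examples
#' occ <- read_occurrences(nichecal_example("occurrences_rarefied_synthetic.csv"))
#' nrow(occ)
nichecal_example <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "nichecal")))
  }
  path <- system.file("extdata", file, package = "nichecal")
  if (!nzchar(path)) stop("no such example file: ", file, call. = FALSE)
  path
}
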