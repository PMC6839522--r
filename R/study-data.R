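#' Locate the deposited study matrix
#'
#' The published 114-taxon, 202-character crocodylian matrix is distributed
#' as supplementary material of the original study, not with this package.
#' To rerun the study-level checks, download it and either set
#' `options(maxpars.study_matrix = "/path/to/matrix.nex")` or place it at
#' `inst/extdata/study/matrix.nex` (source tree) before installing.
#'
#' @return The path to the file, or `NA_character_` if it is not available.
#' @export
study_matrix_path <- function() {
  opt <- getOption("maxpars.study_matrix", NULL)
  if (!is.null(opt) && file.exists(opt)) return(opt)
  p <- system.file("extdata", "study", "matrix.nex", package = "maxpars")
  if (nzchar(p) && file.exists(p)) return(p)
  NA_character_
}
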