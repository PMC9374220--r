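#' Wood turtle population attributes
#'
#' The published attribute table for the 19 wood turtle (*Glyptemys
#' insculpta*) sampling sites in eastern Canada: sample size (N), expected
#' heterozygosity (HE), estimated population size (PSize) and
#' element-occurrence viability rank (EO), with the shore of the
#' St. Lawrence River each site lies on. These are the inputs of the six
#' standard conservation scenarios; the underlying genotypes are not
#' distributed, so the population graph itself cannot be rebuilt from this
#' table.
#'
#' @return data.frame with columns `Id`, `N`, `HE`, `PSize`, `EO`, `Shore`.
#' @export
wood_turtle_attributes <- function() {
  path <- system.file("extdata", "wood_turtle_populations.csv",
                      package = "bridesnet", mustWork = TRUE)
  read_population_attributes(path)
}
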