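#' Reference hierarchy parameters for fast-folding systems
#'
#' Mean memory-time ratio `c`, friction-coefficient ratio `d`, number of
#' fitted kernel components `n`, and free-energy barrier height `U0` (kBT)
#' for the four reference systems: the lambda-repressor fragment, the
#' designed three-helix bundle alpha-3D, protein G, and the Ala9
#' homopeptide.  These parameter sets drive the synthetic-data generator.
#'
#' @param protein one of `"lambda-repressor"`, `"alpha3D"`, `"protein-G"`,
#'   `"Ala9"` (case-insensitive; a few aliases are accepted).
#' @return list with `ratios` (a `hierarchy_ratios` object), `n`, and `U0`.
#' @examples
#' reference_parameters("protein-G")
#' @export
reference_parameters <- function(protein) {
  tab <- reference_table()
  key <- tolower(gsub("[^a-z0-9]", "", tolower(protein)))
  alias <- c("lambdarepressor" = "lambda-repressor", "lambda" = "lambda-repressor",
             "alpha3d" = "alpha3D", "a3d" = "alpha3D",
             "proteing" = "protein-G", "ala9" = "Ala9")
  if (!key %in% names(alias))
    stop(sprintf("unknown system '%s'; known: %s", protein,
                 paste(tab$protein, collapse = ", ")))
  row <- tab[tab$protein == alias[[key]], ]
  r <- structure(list(c = row$c, d = row$d,
                      alpha_sub_pred = log(row$c / row$d) / log(row$c)),
                 class = "hierarchy_ratios")
  list(protein = row$protein, ratios = r, n = row$n, U0 = row$U0)
}

#' Table of reference hierarchy parameters
#'
#' @return data.frame with columns `protein`, `U0`, `c`, `d`, `n`.
#' @export
reference_table <- function() {
  path <- system.file("extdata", "reference_parameters.csv", package = "memgle")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
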