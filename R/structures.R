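#' Registry of glucosinolate structures
#'
#' Canonical table of the leaf glucosinolate (GSL) structures handled by the
#' package: the methionine-derived aliphatic structures (short 3-carbon,
#' short 4-carbon and long chains, in their methylthio, methylsulfinyl,
#' alkenyl, hydroxy-alkenyl and hydroxypropyl modification states) and the
#' three tryptophan-derived indole structures.
#'
#' @return A data frame with columns `id` (canonical structure name),
#'   `chain_class` (one of `"short3C"`, `"short4C"`, `"long"`, `"indole"`)
#'   and `mod_class` (one of `"MT"`, `"MSO"`, `"alkenyl"`, `"OH-alkenyl"`,
#'   `"OH-propyl"`, `"indole"`).
#' @examples
#' gsl_structures()
#' @export
gsl_structures <- function() {
  df <- data.frame(
    id = c("3MSO", "4MSO", "5MSO", "6MSO", "7MSO", "8MSO",
           "3MT", "4MT",
           "Allyl", "But-3-enyl", "OH-But-3-enyl", "OH-Propyl",
           "I3M", "4MI3M", "NMI3M"),
    chain_class = c("short3C", "short4C", "long", "long", "long", "long",
                    "short3C", "short4C",
                    "short3C", "short4C", "short4C", "short3C",
                    "indole", "indole", "indole"),
    mod_class = c("MSO", "MSO", "MSO", "MSO", "MSO", "MSO",
                  "MT", "MT",
                  "alkenyl", "alkenyl", "OH-alkenyl", "OH-propyl",
                  "indole", "indole", "indole"),
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(df$id),
            all((df$chain_class == "indole") == (df$mod_class == "indole")))
  df
}

#' Leaf glucosinolate profile
#'
#' A profile maps structure ids to concentrations in pmol per mm^2 of leaf
#' tissue. Unknown structure ids and negative amounts are rejected.
#'
#' @param concentrations Named numeric vector of concentrations
#'   (pmol/mm^2); names must be ids from [gsl_structures()]. Structures not
#'   named are taken as zero.
#' @param sample_id Character scalar identifying the sample.
#' @return An object of class `gsl_profile`: a named numeric vector over all
#'   registry structures with attribute `sample_id`.
#' @examples
#' p <- gsl_profile(c(`4MSO` = 10, I3M = 5), sample_id = "s1")
#' total_aliphatic(p)
#' @export
gsl_profile <- function(concentrations, sample_id = "sample") {
  reg <- gsl_structures()
  if (length(concentrations) && is.null(names(concentrations)))
    stop("concentrations must be a named numeric vector")
  bad <- setdiff(names(concentrations), reg$id)
  if (length(bad))
    stop("unknown structure id(s): ", paste(bad, collapse = ", "))
  if (any(!is.finite(concentrations)) || any(concentrations < 0))
    stop("all concentrations must be finite and >= 0")
  x <- stats::setNames(numeric(nrow(reg)), reg$id)
  x[names(concentrations)] <- as.numeric(concentrations)
  structure(x, sample_id = as.character(sample_id)[1], class = "gsl_profile")
}

#' @export
print.gsl_profile <- function(x, ...) {
  cat("<gsl_profile> sample:", attr(x, "sample_id"), "\n")
  nz <- x[x > 0]
  if (!length(nz)) cat("  (all structures zero)\n")
  else print(round(unclass(nz), 3))
  cat("  total aliphatic:", round(total_aliphatic(x), 3),
      " total indole:", round(total_indole(x), 3), "pmol/mm^2\n")
  invisible(x)
}

sum_class <- function(profile, indole) {
  reg <- gsl_structures()
  keep <- if (indole) reg$chain_class == "indole" else reg$chain_class != "indole"
  sum(unclass(profile)[reg$id[keep]])
}

#' Total aliphatic glucosinolate content
#'
#' Sum of all aliphatic (non-indole) structure concentrations in a profile.
#'
#' @param profile A [gsl_profile()].
#' @return Non-negative scalar, pmol/mm^2.
#' @export
total_aliphatic <- function(profile) {
  stopifnot(inherits(profile, "gsl_profile"))
  sum_class(profile, indole = FALSE)
}

#' Total indole glucosinolate content
#'
#' Sum of the indole structures (I3M, 4MI3M, NMI3M) in a profile.
#'
#' @param profile A [gsl_profile()].
#' @return Non-negative scalar, pmol/mm^2.
#' @export
total_indole <- function(profile) {
  stopifnot(inherits(profile, "gsl_profile"))
  sum_class(profile, indole = TRUE)
}
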