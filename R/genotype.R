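GSL_GENES <- c("myb28", "myb29", "mam1", "gsox1", "gsox3",
               "aop2", "aop3", "gsoh", "esp")

#' Multi-locus glucosinolate genotype
#'
#' Allelic state (functional / nonfunctional) at the nine manipulated genes of
#' the aliphatic GSL pathway. The nine genes span seven loci: GSOX1 and GSOX3
#' share the GSOX locus, and AOP2/AOP3 are alternate alleles of the single AOP
#' locus, so at most one of them can be functional (the Col-0 reference is
#' null at both).
#'
#' @param label Genotype name, e.g. `"myb28/AOP2"`.
#' @param myb28,myb29,mam1,gsox1,gsox3,aop2,aop3,gsoh,esp Logical scalars;
#'   `TRUE` = functional allele, `FALSE` = nonfunctional.
#' @return An object of class `gsl_genotype` (named logical vector with a
#'   `label` attribute).
#' @examples
#' col0 <- gsl_genotype("Col-0")
#' gsl_genotype("myb28", myb28 = FALSE)
#' @export
gsl_genotype <- function(label,
                         myb28 = TRUE, myb29 = TRUE, mam1 = TRUE,
                         gsox1 = TRUE, gsox3 = TRUE,
                         aop2 = FALSE, aop3 = FALSE,
                         gsoh = TRUE, esp = FALSE) {
  g <- c(myb28 = myb28, myb29 = myb29, mam1 = mam1, gsox1 = gsox1,
         gsox3 = gsox3, aop2 = aop2, aop3 = aop3, gsoh = gsoh, esp = esp)
  if (!is.logical(g) || anyNA(g) || length(g) != 9L)
    stop("all nine allele states must be TRUE or FALSE")
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("label must be a non-empty string")
  if (g[["aop2"]] && g[["aop3"]])
    stop("AOP2 and AOP3 are alternate alleles of one locus; ",
         "at most one can be functional")
  structure(g, label = label, class = "gsl_genotype")
}

#' @export
print.gsl_genotype <- function(x, ...) {
  cat("<gsl_genotype>", attr(x, "label"), "\n ",
      paste0(toupper(GSL_GENES), ifelse(unclass(x), "+", "-"),
             collapse = " "), "\n")
  invisible(x)
}

#' Parse a +/- allele string into a genotype
#'
#' The allele string gives the states of the nine genes in the fixed order
#' MYB28, MYB29, MAM1, GSOX1, GSOX3, AOP2, AOP3, GSOH, ESP, e.g. the Col-0
#' reference is `"+++++--+-"`.
#'
#' @param string Nine-character string of `+` and `-`.
#' @param label Optional genotype label; defaults to the string itself.
#' @return A [gsl_genotype()].
#' @examples
#' parse_allele_string("+++++--+-", "Col-0")
#' @export
parse_allele_string <- function(string, label = string) {
  ch <- strsplit(string, "")[[1]]
  if (length(ch) != 9L || !all(ch %in% c("+", "-")))
    stop("allele string must be nine characters of '+'/'-'")
  st <- as.list(ch == "+")
  names(st) <- GSL_GENES
  do.call(gsl_genotype, c(list(label = label), st))
}

#' The 17-genotype laboratory population
#'
#' The structured mutant population in the Col-0 background: single, double
#' and triple combinations of loss-of-function alleles (myb28, myb29, gsm1 =
#' mam1, gsox1, gsox3, gsoh) and gain-of-function transgenes (AOP2, ESP),
#' each genotype named by its deviations from Col-0.
#'
#' @return Named list of 17 [gsl_genotype()] objects.
#' @examples
#' names(gsl_population())
#' @export
gsl_population <- function() {
  spec <- list(
    "Col-0"            = list(),
    "myb28"            = list(myb28 = FALSE),
    "myb29"            = list(myb29 = FALSE),
    "gsm1"             = list(mam1 = FALSE),
    "gsox1"            = list(gsox1 = FALSE),
    "gsox3"            = list(gsox3 = FALSE),
    "AOP2"             = list(aop2 = TRUE),
    "AOP2/gsoh"        = list(aop2 = TRUE, gsoh = FALSE),
    "gsoh"             = list(gsoh = FALSE),
    "myb28/gsoh"       = list(myb28 = FALSE, gsoh = FALSE),
    "myb28/gsm1"       = list(myb28 = FALSE, mam1 = FALSE),
    "myb28/AOP2"       = list(myb28 = FALSE, aop2 = TRUE),
    "myb29/gsm1"       = list(myb29 = FALSE, mam1 = FALSE),
    "myb29/AOP2/gsoh"  = list(myb29 = FALSE, aop2 = TRUE, gsoh = FALSE),
    "myb28/myb29"      = list(myb28 = FALSE, myb29 = FALSE),
    "myb28/myb29/gsoh" = list(myb28 = FALSE, myb29 = FALSE, gsoh = FALSE),
    "ESP"              = list(esp = TRUE)
  )
  out <- lapply(names(spec), function(nm)
    do.call(gsl_genotype, c(list(label = nm), spec[[nm]])))
  stats::setNames(out, names(spec))
}

# Locus-level view used by the caller and frequency code. The GSOX locus is
# scored nonfunctional if either GSOX gene is knocked out (either single
# mutant accumulates MT GSL in the chamber); AOP is three-state.
genotype_locus_states <- function(genotype) {
  stopifnot(inherits(genotype, "gsl_genotype"))
  g <- unclass(genotype)
  list(
    MYB28 = if (g[["myb28"]]) "+" else "-",
    MYB29 = if (g[["myb29"]]) "+" else "-",
    MAM1  = if (g[["mam1"]]) "+" else "-",
    GSOX  = if (g[["gsox1"]] && g[["gsox3"]]) "+" else "-",
    AOP   = if (g[["aop2"]]) "AOP2" else if (g[["aop3"]]) "AOP3" else "null",
    GSOH  = if (g[["gsoh"]]) "+" else "-",
    ESP   = if (g[["esp"]]) "+" else "-"
  )
}
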