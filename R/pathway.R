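#' Parameters of the forward pathway model
#'
#' Quantitative knobs of the rule-based forward model that maps a multi-locus
#' GSL genotype to a predicted mean leaf profile. Defaults are calibrated so
#' that, relative to Col-0, the myb28 single mutant retains exactly 50% and
#' the myb29 single mutant exactly 75% of total aliphatic GSL, and the
#' myb28/myb29 double mutant none. With a long-chain fraction of 1/6 of the
#' Col-0 total, those totals fix the short-chain multipliers at 0.6 (myb28)
#' and 0.7 (myb29); loss of MYB28 additionally abolishes the long-chain pool.
#'
#' @param base_short3C,base_short4C,base_long Col-0 class pools (pmol/mm^2).
#'   The short-chain split (default 17:3 = 85:15) is the dominant:minor
#'   chain-class ratio; MAM1 decides which chain length receives the dominant
#'   share.
#' @param myb28_short_mult,myb28_long_mult Multipliers applied to the short
#'   and long-chain pools when MYB28 is nonfunctional.
#' @param myb29_short_mult,myb29_long_mult Same for MYB29 loss.
#' @param aop_conversion Fraction of dominant-class MSO converted to alkenyl
#'   by AOP2 (or of 3MSO to OH-Propyl by AOP3); default 1 (complete).
#' @param gsoh_conversion Fraction of But-3-enyl hydroxylated to
#'   OH-But-3-enyl by GSOH; default 0.5 so that both alkenyl and
#'   hydroxy-alkenyl co-occur, as in observed profiles of AOP2 lines.
#' @param gsox_conversion Fraction of short-chain MSO that remains as MT when
#'   the GSOX locus is impaired, chamber conditions only.
#' @param long_fractions Distribution of the long pool over 5MSO..8MSO.
#' @param indole_base Named per-structure indole pool (pmol/mm^2).
#' @param field_mode If `TRUE` (default) MT structures never accumulate,
#'   matching field-grown material; set `FALSE` for chamber conditions.
#' @return Object of class `pathway_params` (a validated list).
#' @examples
#' pathway_params()
#' @export
pathway_params <- function(base_short3C = 3, base_short4C = 17, base_long = 4,
                           myb28_short_mult = 0.6, myb28_long_mult = 0,
                           myb29_short_mult = 0.7, myb29_long_mult = 1,
                           aop_conversion = 1, gsoh_conversion = 0.5,
                           gsox_conversion = 0.3,
                           long_fractions = c(`5MSO` = 0.10, `6MSO` = 0.05,
                                              `7MSO` = 0.10, `8MSO` = 0.75),
                           indole_base = c(I3M = 4, `4MI3M` = 0.5,
                                           NMI3M = 0.5),
                           field_mode = TRUE) {
  p <- list(base_short3C = base_short3C, base_short4C = base_short4C,
            base_long = base_long,
            myb28_short_mult = myb28_short_mult,
            myb28_long_mult = myb28_long_mult,
            myb29_short_mult = myb29_short_mult,
            myb29_long_mult = myb29_long_mult,
            aop_conversion = aop_conversion,
            gsoh_conversion = gsoh_conversion,
            gsox_conversion = gsox_conversion,
            long_fractions = long_fractions,
            indole_base = indole_base,
            field_mode = isTRUE(field_mode))
  pools <- c(base_short3C, base_short4C, base_long)
  if (any(pools < 0)) stop("class pools must be >= 0")
  fr <- c(myb28_short_mult, myb28_long_mult, myb29_short_mult,
          myb29_long_mult, aop_conversion, gsoh_conversion, gsox_conversion)
  if (any(fr < 0 | fr > 1))
    stop("multipliers and conversion fractions must lie in [0, 1]")
  if (!setequal(names(long_fractions), c("5MSO", "6MSO", "7MSO", "8MSO")) ||
      any(long_fractions < 0) || abs(sum(long_fractions) - 1) > 1e-8)
    stop("long_fractions must be a distribution over 5MSO..8MSO")
  if (any(indole_base < 0) ||
      !all(names(indole_base) %in% c("I3M", "4MI3M", "NMI3M")))
    stop("indole_base must be non-negative amounts of I3M/4MI3M/NMI3M")
  class(p) <- "pathway_params"
  p
}

#' Predict the mean leaf profile of a genotype
#'
#' Deterministic (noise-free) forward model. The class pools are scaled by
#' the MYB regulator multipliers, the short pool is split between 3C and 4C
#' chains with the dominant share assigned by MAM1, the long pool is spread
#' over 5MSO..8MSO (MYB28-dependent), and the side-chain modification
#' enzymes then redistribute mass within each chain class: GSOX loss leaves
#' an MT fraction (chamber only), AOP2 converts dominant-class MSO to
#' alkenyl, AOP3 converts 3MSO to OH-Propyl, and GSOH hydroxylates part of
#' the But-3-enyl made by AOP2. Conversions never change class totals, so
#' total aliphatic GSL depends only on the MYB states. The three indole
#' structures are a passive pool, unaffected by these loci.
#'
#' @param genotype A [gsl_genotype()].
#' @param params A [pathway_params()].
#' @param sample_id Sample id for the returned profile.
#' @return A [gsl_profile()] of predicted mean concentrations (pmol/mm^2).
#' @examples
#' pop <- gsl_population()
#' col0 <- predict_profile(pop[["Col-0"]])
#' m28 <- predict_profile(pop[["myb28"]])
#' total_aliphatic(m28) / total_aliphatic(col0)  # 0.5
#' @export
predict_profile <- function(genotype, params = pathway_params(),
                            sample_id = attr(genotype, "label")) {
  stopifnot(inherits(genotype, "gsl_genotype"),
            inherits(params, "pathway_params"))
  g <- unclass(genotype)
  x <- stats::setNames(numeric(nrow(gsl_structures())), gsl_structures()$id)
  x[names(params$indole_base)] <- params$indole_base

  if (g[["myb28"]] || g[["myb29"]]) {
    short_mult <- (if (g[["myb28"]]) 1 else params$myb28_short_mult) *
                  (if (g[["myb29"]]) 1 else params$myb29_short_mult)
    long_mult  <- (if (g[["myb28"]]) 1 else params$myb28_long_mult) *
                  (if (g[["myb29"]]) 1 else params$myb29_long_mult)

    short_total <- (params$base_short3C + params$base_short4C) * short_mult
    dom_share <- params$base_short4C / (params$base_short3C + params$base_short4C)
    if (g[["mam1"]]) {             # 4C dominant
      c4 <- short_total * dom_share; c3 <- short_total - c4
    } else {                       # 3C dominant
      c3 <- short_total * dom_share; c4 <- short_total - c3
    }
    long_total <- params$base_long * long_mult
    x[names(params$long_fractions)] <- long_total * params$long_fractions

    # GSOX locus: either gene knocked out leaves an MT fraction unoxidized,
    # but only under chamber conditions; field material carries no MT.
    mt3 <- mt4 <- 0
    if (!(g[["gsox1"]] && g[["gsox3"]]) && !params$field_mode) {
      mt3 <- c3 * params$gsox_conversion
      mt4 <- c4 * params$gsox_conversion
      c3 <- c3 - mt3; c4 <- c4 - mt4
    }
    x["3MT"] <- mt3; x["4MT"] <- mt4

    # AOP locus acts on the MSO remaining after GSOX.
    if (g[["aop2"]]) {
      if (g[["mam1"]]) {
        conv <- c4 * params$aop_conversion
        c4 <- c4 - conv
        buten <- conv
        x["Allyl"] <- 0
      } else {
        conv <- c3 * params$aop_conversion
        c3 <- c3 - conv
        buten <- 0
        x["Allyl"] <- conv
      }
      if (g[["gsoh"]] && buten > 0) {
        x["OH-But-3-enyl"] <- buten * params$gsoh_conversion
        buten <- buten - x["OH-But-3-enyl"]
      }
      x["But-3-enyl"] <- buten
    } else if (g[["aop3"]]) {
      conv <- c3 * params$aop_conversion
      c3 <- c3 - conv
      x["OH-Propyl"] <- conv
    }
    x["3MSO"] <- c3; x["4MSO"] <- c4
  }
  gsl_profile(x[x > 0], sample_id = sample_id)
}

#' Predicted qualitative chemotype of a genotype
#'
#' The set of structures with nonzero predicted amount under the noise-free
#' forward model, i.e. the qualitative chemotype used for haplotype naming.
#'
#' @param genotype A [gsl_genotype()].
#' @param field_mode Whether to predict field material (no MT accumulation).
#' @param params A [pathway_params()]; its `field_mode` is overridden by the
#'   `field_mode` argument.
#' @return Character vector of structure ids.
#' @examples
#' predict_structures(gsl_population()[["myb28/myb29"]])
#' @export
predict_structures <- function(genotype, field_mode = TRUE,
                               params = pathway_params()) {
  params$field_mode <- isTRUE(field_mode)
  prof <- predict_profile(genotype, params)
  names(prof)[unclass(prof) > 0]
}

# Aliphatic structure sets seen in single representative field-grown HPLC
# traces of each population genotype (one trace per genotype).
field_trace_sets <- function() {
  list(
    "Col-0"            = c("3MSO", "4MSO", "5MSO", "6MSO", "7MSO", "8MSO"),
    "myb28"            = c("3MSO", "4MSO", "5MSO", "8MSO"),
    "myb29"            = c("3MSO", "4MSO", "5MSO", "6MSO", "7MSO", "8MSO"),
    "gsm1"             = c("3MSO", "4MSO", "7MSO", "8MSO"),
    "gsox1"            = c("3MSO", "4MSO", "5MSO", "6MSO", "7MSO", "8MSO"),
    "gsox3"            = c("3MSO", "4MSO", "5MSO", "6MSO", "7MSO", "8MSO"),
    "AOP2"             = c("3MSO", "OH-But-3-enyl", "5MSO", "But-3-enyl",
                           "7MSO", "8MSO"),
    "AOP2/gsoh"        = c("3MSO", "4MSO", "Allyl", "5MSO", "But-3-enyl",
                           "7MSO", "8MSO"),
    "gsoh"             = c("3MSO", "4MSO", "5MSO", "But-3-enyl", "7MSO",
                           "8MSO"),
    "myb28/gsoh"       = c("3MSO", "4MSO", "8MSO"),
    "myb28/gsm1"       = c("3MSO", "4MSO"),
    "myb28/AOP2"       = c("3MSO", "OH-But-3-enyl", "But-3-enyl"),
    "myb29/gsm1"       = c("3MSO", "4MSO", "7MSO", "8MSO"),
    "myb29/AOP2/gsoh"  = c("3MSO", "4MSO", "Allyl", "5MSO", "But-3-enyl",
                           "7MSO", "8MSO"),
    "myb28/myb29"      = character(0),
    "myb28/myb29/gsoh" = character(0),
    "ESP"              = c("3MSO", "4MSO", "5MSO", "6MSO", "7MSO", "8MSO")
  )
}

#' Concordance of predicted chemotypes with observed field traces
#'
#' Compares the model-predicted aliphatic structure set of every population
#' genotype (field mode) against the structure set visible in a single
#' representative field-grown HPLC trace of that genotype. Single traces
#' carry detection-level quirks the deterministic rules do not model --
#' minor long-chain homologs dropping below detection, trace amounts of a
#' precursor surviving an essentially complete conversion -- so differences
#' are reported rather than treated as errors.
#'
#' @param params A [pathway_params()].
#' @return Data frame with one row per genotype: the predicted and observed
#'   sets, the structures missing from each, and whether they match exactly.
#' @export
trace_concordance <- function(params = pathway_params()) {
  obs <- field_trace_sets()
  pop <- gsl_population()
  rows <- lapply(names(obs), function(nm) {
    pred <- setdiff(predict_structures(pop[[nm]], field_mode = TRUE, params),
                    gsl_structures()$id[gsl_structures()$chain_class == "indole"])
    data.frame(genotype = nm,
               predicted = paste(sort(pred), collapse = ","),
               observed = paste(sort(obs[[nm]]), collapse = ","),
               predicted_only = paste(sort(setdiff(pred, obs[[nm]])), collapse = ","),
               observed_only = paste(sort(setdiff(obs[[nm]], pred)), collapse = ","),
               exact = setequal(pred, obs[[nm]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
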