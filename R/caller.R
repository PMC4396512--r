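GSL_LOCI <- c("MYB28", "MYB29", "MAM1", "GSOX", "AOP", "GSOH", "ESP")

# Col-0 reference state at the seven loci.
COL0_LOCUS_STATE <- list(MYB28 = "+", MYB29 = "+", MAM1 = "+", GSOX = "+",
                         AOP = "null", GSOH = "+", ESP = "-")

#' Decision thresholds for the haplotype caller
#'
#' Numeric thresholds used to turn a quantitative GSL profile into
#' functional/nonfunctional calls. The amount breaks separate the four
#' total-aliphatic classes (0 / 50% / 75% / 100% of a Col-0-equivalent
#' reference total) at the midpoints between the calibrated class means.
#'
#' @param detection_limit Concentration (pmol/mm^2) below which a structure
#'   counts as absent.
#' @param dominance_ratio Minimum major:minor chain-class ratio required to
#'   call the MAM1 state; profiles between the two calls are left `NA`.
#' @param amount_breaks Strictly increasing fractions of `reference_total`
#'   separating the 0/50/75/100 total-aliphatic classes.
#' @param reference_total Col-0-equivalent total aliphatic GSL (pmol/mm^2).
#'   Leave `NULL` to have panel-level callers estimate it as the panel's
#'   upper-quartile total (totals vary across environments, so a fixed
#'   reference only makes sense within one panel).
#' @return Object of class `caller_thresholds`.
#' @export
caller_thresholds <- function(detection_limit = 0.5, dominance_ratio = 2,
                              amount_breaks = c(0.05, 0.625, 0.875),
                              reference_total = NULL) {
  stopifnot(detection_limit >= 0, dominance_ratio > 1,
            length(amount_breaks) == 3, all(diff(amount_breaks) > 0),
            all(amount_breaks > 0 & amount_breaks < 1))
  if (!is.null(reference_total) && reference_total <= 0)
    stop("reference_total must be > 0")
  structure(list(detection_limit = detection_limit,
                 dominance_ratio = dominance_ratio,
                 amount_breaks = amount_breaks,
                 reference_total = reference_total),
            class = "caller_thresholds")
}

#' Estimate the reference total aliphatic content of a panel
#'
#' Upper-quartile total aliphatic GSL across profiles, a robust stand-in for
#' the Col-0-equivalent (100% class) total when no reference is measured.
#'
#' @param profiles List of [gsl_profile()] objects.
#' @return Scalar pmol/mm^2.
#' @export
estimate_reference_total <- function(profiles) {
  tot <- vapply(profiles, total_aliphatic, numeric(1))
  as.numeric(stats::quantile(tot, 0.75, names = FALSE))
}

#' Call a multi-locus GSL haplotype from a leaf profile
#'
#' Inverse inference: assigns a functional (`"+"`), nonfunctional (`"-"`) or
#' unobservable (`NA`) state at seven aliphatic-pathway loci from the
#' presence, absence and relative abundance of GSL structures. Epistasis
#' makes some loci unobservable: with no aliphatic GSL at all (both MYB
#' regulators off) the downstream loci MAM1, GSOX, AOP and GSOH cannot be
#' scored, and GSOH is only scoreable when AOP2 supplies its But-3-enyl
#' substrate. ESP acts on activation products, not the intact profile, and
#' is always `NA`.
#'
#' @param profile A [gsl_profile()].
#' @param thresholds A [caller_thresholds()] with a set `reference_total`.
#' @return Object of class `haplotype_call`: per-locus calls with rule
#'   traces, the Col-0-referenced haplotype name and the chemotype string.
#' @examples
#' th <- caller_thresholds(reference_total = 24)
#' call_haplotype(predict_profile(gsl_population()[["AOP2"]]), th)
#' @export
call_haplotype <- function(profile, thresholds) {
  stopifnot(inherits(profile, "gsl_profile"),
            inherits(thresholds, "caller_thresholds"))
  if (is.null(thresholds$reference_total))
    stop("thresholds$reference_total is not set; supply it or estimate it ",
         "with estimate_reference_total()")
  det <- thresholds$detection_limit
  x <- unclass(profile)
  pres <- function(ids) any(x[ids] > det)
  amt <- function(ids) sum(x[ids])

  ali <- total_aliphatic(profile)
  ratio <- ali / thresholds$reference_total
  cls <- c("0", "50", "75", "100")[findInterval(ratio, thresholds$amount_breaks) + 1L]

  calls <- stats::setNames(vector("list", length(GSL_LOCI)), GSL_LOCI)
  mk <- function(state, evidence) list(state = state, evidence = evidence)
  calls$ESP <- mk(NA_character_, NA_character_)

  c3_ids <- c("3MSO", "3MT", "Allyl", "OH-Propyl")
  c4_ids <- c("4MSO", "4MT", "But-3-enyl", "OH-But-3-enyl")
  long_ids <- c("5MSO", "6MSO", "7MSO", "8MSO")
  mso_ids <- c("3MSO", "4MSO", long_ids)
  alkenyl_ids <- c("Allyl", "But-3-enyl", "OH-But-3-enyl")

  if (ali < det || cls == "0") {
    ev <- "total aliphatic below detection: both MYB regulators nonfunctional"
    calls$MYB28 <- mk("-", ev)
    calls$MYB29 <- mk("-", ev)
    for (l in c("MAM1", "GSOX", "AOP", "GSOH"))
      calls[[l]] <- mk(NA_character_, NA_character_)
    chem <- "0"
  } else {
    long_present <- pres(long_ids)
    calls$MYB28 <-
      if (long_present) mk("+", "long-chain GSL present")
      else mk("-", "short-chain present without long-chain GSL")
    m28 <- calls$MYB28$state
    calls$MYB29 <-
      if (m28 == "+" && cls == "100")
        mk("+", sprintf("total aliphatic %.0f%% of reference", 100 * ratio))
      else if (m28 == "+" && cls == "75")
        mk("-", sprintf("total aliphatic %.0f%% of reference", 100 * ratio))
      else if (m28 == "-" && cls == "50")
        mk("+", sprintf("total aliphatic %.0f%% of reference", 100 * ratio))
      else
        mk(NA_character_, NA_character_)
    if (is.na(calls$MYB29$state))
      warning("ambiguous total-aliphatic class for MYB29 (", round(ratio, 3),
              " of reference with MYB28 ", m28, "); left NA", call. = FALSE)

    c3 <- amt(c3_ids); c4 <- amt(c4_ids)
    calls$MAM1 <-
      if (c4 > det && c4 >= thresholds$dominance_ratio * c3)
        mk("+", sprintf("4C:3C = %.1f", c4 / max(c3, 1e-12)))
      else if (c3 > det && c3 >= thresholds$dominance_ratio * c4)
        mk("-", sprintf("3C:4C = %.1f", c3 / max(c4, 1e-12)))
      else mk(NA_character_, NA_character_)

    calls$AOP <-
      if (pres(alkenyl_ids)) mk("AOP2", "alkenyl GSL present")
      else if (pres("OH-Propyl")) mk("AOP3", "OH-Propyl present")
      else if (pres(mso_ids)) mk("null", "MSO present without alkenyl or OH-Propyl")
      else mk(NA_character_, NA_character_)

    calls$GSOH <-
      if (pres("OH-But-3-enyl")) mk("+", "OH-But-3-enyl present")
      else if (pres("But-3-enyl")) mk("-", "But-3-enyl without OH-But-3-enyl")
      else mk(NA_character_, NA_character_)

    calls$GSOX <-
      if (pres(c("3MT", "4MT"))) mk("-", "MT GSL above detection")
      else if (pres(mso_ids) || pres(alkenyl_ids))
        mk("+", "MSO/alkenyl present without MT")
      else mk(NA_character_, NA_character_)

    chain <- switch(calls$MAM1$state %||% "NA", "+" = "4C", "-" = "3C", "NA")
    modc <- if (pres("OH-But-3-enyl")) "OH-alkenyl"
            else if (pres(alkenyl_ids)) "alkenyl"
            else if (pres("OH-Propyl")) "OH-propyl" else "MSO"
    chem <- paste(chain, modc, paste0(cls, "%"), sep = "/")
  }

  out <- structure(list(calls = calls, chemotype = chem), class = "haplotype_call")
  out$name <- haplotype_name(out)
  out
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Call haplotypes for a panel of profiles
#'
#' Applies [call_haplotype()] to every profile, estimating the panel
#' reference total with [estimate_reference_total()] when the thresholds do
#' not fix one.
#'
#' @param profiles List of [gsl_profile()] objects.
#' @param thresholds A [caller_thresholds()].
#' @return List of `haplotype_call` objects (named by sample id).
#' @export
call_haplotypes <- function(profiles, thresholds = caller_thresholds()) {
  if (is.null(thresholds$reference_total))
    thresholds$reference_total <- estimate_reference_total(profiles)
  out <- lapply(profiles, call_haplotype, thresholds = thresholds)
  stats::setNames(out, vapply(profiles, attr, character(1), "sample_id"))
}

#' Canonical Col-0-referenced haplotype name
#'
#' Deterministic name listing the deviations of a call from the Col-0
#' reference state (MYB28+, MYB29+, MAM1+, GSOX+, AOP null, GSOH+, ESP-),
#' in fixed locus order. `NA` states implied by epistasis (downstream loci
#' of a double-myb profile, GSOH without AOP2, ESP) are structural and not
#' named; any other `NA` appears as `"<LOCUS>-NA"`. A call matching Col-0
#' everywhere is named `"Col-0"`. The name depends only on the states, never
#' on the evidence traces.
#'
#' @param call A `haplotype_call`.
#' @return Character scalar.
#' @export
haplotype_name <- function(call) {
  stopifnot(inherits(call, "haplotype_call"))
  st <- vapply(call$calls, function(z) z$state %||% NA_character_, character(1))
  both_myb_off <- identical(unname(st[c("MYB28", "MYB29")]), c("-", "-"))
  tok <- character(0)
  add <- function(tok, locus, minus_name, plus_name = NULL) {
    s <- st[[locus]]
    if (is.na(s)) {
      structural <- both_myb_off || locus == "ESP" ||
        (locus == "GSOH" && (!identical(st[["AOP"]], "AOP2") ||
                             identical(st[["MAM1"]], "-")))
      if (!structural) tok <- c(tok, paste0(locus, "-NA"))
    } else if (s == "-" && !is.null(minus_name)) tok <- c(tok, minus_name)
    else if (s %in% c("+", "AOP2", "AOP3") && !is.null(plus_name))
      tok <- c(tok, plus_name)
    tok
  }
  tok <- add(tok, "MYB28", "myb28")
  tok <- add(tok, "MYB29", "myb29")
  tok <- add(tok, "MAM1", "gsm1")
  tok <- add(tok, "GSOX", "gsox")
  if (!is.na(st[["AOP"]]) && st[["AOP"]] != "null")
    tok <- c(tok, st[["AOP"]])
  else if (is.na(st[["AOP"]]) && !both_myb_off)
    tok <- c(tok, "AOP-NA")
  tok <- add(tok, "GSOH", "gsoh")
  if (!is.na(st[["ESP"]]) && st[["ESP"]] == "+") tok <- c(tok, "ESP")
  if (!length(tok)) "Col-0" else paste(tok, collapse = "/")
}

#' @export
print.haplotype_call <- function(x, ...) {
  st <- vapply(x$calls, function(z) z$state %||% "NA", character(1))
  cat("<haplotype_call>", x$name, " chemotype:", x$chemotype, "\n ",
      paste(names(st), st, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Forward-inverse round trip for one genotype
#'
#' Runs [predict_profile()] then [call_haplotype()] and checks, locus by
#' locus, that every observable locus is called at its true state and every
#' epistatically unobservable locus is called `NA`. Observability follows
#' the pathway rules: ESP never; MAM1/GSOX/AOP/GSOH only when aliphatic GSL
#' accumulate (at least one MYB functional); GSOH only when AOP2 and MAM1
#' supply But-3-enyl; GSOX only under chamber conditions (field material
#' never accumulates the diagnostic MT structures).
#'
#' @param genotype A [gsl_genotype()].
#' @param params A [pathway_params()]; chamber mode
#'   (`field_mode = FALSE`) makes all seven epistasis rules scoreable.
#' @param thresholds A [caller_thresholds()]; if `reference_total` is unset
#'   it is taken from the noise-free Col-0 prediction under `params`.
#' @param profile Optional profile to call instead of the noise-free
#'   prediction (e.g. a noisy simulated profile of this genotype).
#' @return Data frame (one row per locus) with the true state, call,
#'   expected observability and per-locus agreement; attribute `agreement`
#'   is the fraction of loci in agreement.
#' @examples
#' rt <- round_trip(gsl_population()[["myb28/myb29"]])
#' attr(rt, "agreement")
#' @export
round_trip <- function(genotype,
                       params = pathway_params(field_mode = FALSE),
                       thresholds = caller_thresholds(),
                       profile = NULL) {
  stopifnot(inherits(genotype, "gsl_genotype"))
  if (is.null(thresholds$reference_total))
    thresholds$reference_total <-
      total_aliphatic(predict_profile(gsl_genotype("Col-0"), params))
  if (is.null(profile)) profile <- predict_profile(genotype, params)
  call <- call_haplotype(profile, thresholds)

  truth <- genotype_locus_states(genotype)
  g <- unclass(genotype)
  has_ali <- g[["myb28"]] || g[["myb29"]]
  observable <- c(
    MYB28 = TRUE, MYB29 = TRUE,
    MAM1 = has_ali, GSOX = has_ali && !params$field_mode,
    AOP = has_ali,
    GSOH = has_ali && g[["aop2"]] && g[["mam1"]],
    ESP = FALSE
  )
  called <- vapply(call$calls, function(z) z$state %||% NA_character_,
                   character(1))
  ok <- vapply(GSL_LOCI, function(l) {
    if (observable[[l]]) identical(called[[l]], truth[[l]])
    else is.na(called[[l]])
  }, logical(1))
  out <- data.frame(locus = GSL_LOCI,
                    truth = unlist(truth[GSL_LOCI]),
                    call = called[GSL_LOCI],
                    observable = observable[GSL_LOCI],
                    ok = ok,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "agreement") <- mean(ok)
  attr(out, "name") <- call$name
  out
}
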