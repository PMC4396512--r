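FREQ_LOCI <- c("MYB28", "MYB29", "MAM1", "GSOX", "AOP", "GSOH")

call_states <- function(call) {
  vapply(call$calls[FREQ_LOCI],
         function(z) if (is.na(z$state)) NA_character_ else z$state,
         character(1))
}

state_key <- function(states) {
  paste(ifelse(is.na(states), "NA", states), collapse = "|")
}

#' Single-locus allele frequencies from haplotype calls
#'
#' Frequency of each allelic state at every locus, with `NA` calls excluded
#' from both numerator and denominator. The AOP locus is three-state
#' (AOP2/AOP3/null); the others are binary, summarized as the frequency of
#' the functional allele. ESP is always `NA` in calls and is dropped.
#'
#' @param calls List of `haplotype_call` objects (see [call_haplotype()]).
#' @return Object of class `allele_frequencies`: `freq` (per-locus state
#'   probabilities), `n` (informative calls per locus), `n_panel`. Loci with
#'   zero informative calls get an `NA` frequency and a warning.
#' @export
allele_frequencies <- function(calls) {
  if (!length(calls)) stop("empty panel")
  st <- t(vapply(calls, call_states, character(length(FREQ_LOCI))))
  colnames(st) <- FREQ_LOCI
  freq <- list(); n <- integer(0)
  for (l in FREQ_LOCI) {
    v <- st[, l]
    v <- v[!is.na(v)]
    n[[l]] <- length(v)
    if (!length(v)) {
      warning("no informative calls at locus ", l, call. = FALSE)
      freq[[l]] <- NA_real_
    } else if (l == "AOP") {
      tab <- table(factor(v, levels = c("AOP2", "AOP3", "null")))
      freq[[l]] <- as.numeric(tab) / length(v)
      names(freq[[l]]) <- names(tab)
    } else {
      freq[[l]] <- mean(v == "+")
    }
  }
  structure(list(freq = freq, n = n, n_panel = length(calls)),
            class = "allele_frequencies")
}

# Normalise a frequency spec (allele_frequencies object, or a named list
# mixing scalars p(functional) and named state-probability vectors) to a
# named list of named probability vectors.
as_freq_list <- function(freqs, loci = NULL) {
  if (inherits(freqs, "allele_frequencies")) freqs <- freqs$freq
  if (is.numeric(freqs) && !is.null(names(freqs))) freqs <- as.list(freqs)
  if (!is.list(freqs) || is.null(names(freqs)))
    stop("freqs must be an allele_frequencies object or a named list")
  if (is.null(loci)) loci <- names(freqs)
  out <- lapply(loci, function(l) {
    p <- freqs[[l]]
    if (is.null(p) || anyNA(p))
      stop("undefined allele frequency at locus ", l)
    if (length(p) == 1L) p <- c(`+` = p, `-` = 1 - p)
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("state probabilities at locus ", l, " must sum to 1")
    p
  })
  stats::setNames(out, loci)
}

#' Expected multi-locus haplotype frequencies under linkage equilibrium
#'
#' Product of single-locus marginal probabilities over the multi-locus state
#' space -- the null expectation if no selection, drift or structure couples
#' the loci. With `epistasis = TRUE` (the GSL pathway space) states that are
#' unobservable by the pathway rules are `NA` and their expectation is
#' marginalized over the hidden locus: both MYB regulators off hides MAM1,
#' GSOX, AOP and GSOH; GSOH is hidden unless AOP2 and MAM1 provide its
#' substrate. With `epistasis = FALSE` the space is the full cross-product
#' of the supplied loci (any number of them), used e.g. for exhaustive
#' small-panel checks.
#'
#' @param freqs An [allele_frequencies()] object, or a named list/vector of
#'   per-locus frequencies (scalar = frequency of `"+"`; named vector =
#'   multi-state probabilities).
#' @param loci Loci to include, in order; default all loci in `freqs`.
#' @param epistasis Apply the GSL structural observability rules (requires
#'   the standard locus set).
#' @return Data frame with one column per locus (states as character, `NA`
#'   where marginalized), a `key` column and a `prob` column summing to 1.
#'   Attribute `n_params` counts the independent frequencies behind it.
#' @examples
#' expected_haplotype_frequencies(c(A = 0.9, B = 0.5, C = 0.2),
#'                                epistasis = FALSE)
#' @export
expected_haplotype_frequencies <- function(freqs, loci = NULL,
                                           epistasis = NULL) {
  fl <- as_freq_list(freqs, loci)
  loci <- names(fl)
  if (is.null(epistasis)) epistasis <- all(FREQ_LOCI %in% loci)
  if (epistasis && !all(FREQ_LOCI %in% loci))
    stop("epistasis rules need loci ", paste(FREQ_LOCI, collapse = ", "))

  if (!epistasis) {
    grid <- expand.grid(lapply(fl, names), stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    prob <- rep(1, nrow(grid))
    for (l in loci) prob <- prob * fl[[l]][grid[[l]]]
  } else {
    rows <- list()
    p <- function(l, s) fl[[l]][[s]]
    # both regulators off: downstream loci hidden
    rows[[1]] <- data.frame(MYB28 = "-", MYB29 = "-", MAM1 = NA, GSOX = NA,
                            AOP = NA, GSOH = NA,
                            prob = p("MYB28", "-") * p("MYB29", "-"),
                            stringsAsFactors = FALSE)
    myb <- list(c("+", "+"), c("+", "-"), c("-", "+"))
    k <- 2L
    for (m in myb) for (mam in c("+", "-")) for (gx in c("+", "-"))
      for (aop in c("AOP2", "AOP3", "null")) {
        base <- p("MYB28", m[1]) * p("MYB29", m[2]) * p("MAM1", mam) *
          p("GSOX", gx) * p("AOP", aop)
        gsoh_states <- if (aop == "AOP2" && mam == "+") c("+", "-") else NA
        for (gs in gsoh_states) {
          pr <- base * (if (is.na(gs)) 1 else p("GSOH", gs))
          rows[[k]] <- data.frame(MYB28 = m[1], MYB29 = m[2], MAM1 = mam,
                                  GSOX = gx, AOP = aop, GSOH = gs,
                                  prob = pr, stringsAsFactors = FALSE)
          k <- k + 1L
        }
      }
    grid <- do.call(rbind, rows)
    prob <- grid$prob
    grid$prob <- NULL
  }
  out <- grid
  out$key <- apply(out, 1, function(r) state_key(unlist(r)))
  out$prob <- prob
  stopifnot(abs(sum(out$prob) - 1) < 1e-8)
  attr(out, "n_params") <- sum(vapply(fl, function(v) length(v) - 1L,
                                      integer(1)))
  attr(out, "loci") <- loci
  out
}

#' Observed haplotype counts from calls
#'
#' Tabulates calls by their multi-locus state key (the six variable loci,
#' `NA` for unobservable states).
#'
#' @param calls List of `haplotype_call` objects.
#' @return Named integer vector of counts.
#' @export
observed_haplotype_counts <- function(calls) {
  keys <- vapply(calls, function(cl) state_key(call_states(cl)), character(1))
  tab <- table(keys)
  stats::setNames(as.integer(tab), names(tab))
}

# Vectorized chi-square statistics for a state x reps count matrix, with
# per-rep re-estimation of locus frequencies and expectations (parametric
# bootstrap honouring the estimation step).
refit_stats <- function(C, space, n) {
  loci <- attr(space, "loci")
  logE <- matrix(0, nrow(C), ncol(C))
  for (l in loci) {
    v <- space[[l]]
    states <- unique(v[!is.na(v)])
    M <- vapply(states, function(s) !is.na(v) & v == s, logical(nrow(space)))
    cnt <- t(M) %*% C                       # state-value x reps
    tot <- colSums(cnt)
    P <- sweep(cnt, 2, pmax(tot, 1), "/")   # estimated per-rep frequencies
    logP <- log(P); logP[!is.finite(logP)] <- -700  # avoid 0 * -Inf = NaN
    logE <- logE + M %*% logP               # NA rows contribute 0
  }
  E <- n * exp(logE)
  D <- (C - E)^2 / E
  D[C == 0 & E == 0] <- 0
  colSums(D)
}

#' Test observed vs expected multi-locus haplotype frequencies
#'
#' Global goodness-of-fit of observed haplotype counts to the
#' linkage-equilibrium expectation, plus a per-haplotype classification of
#' over/under-representation. The global statistic is the Pearson chi-square
#' over all states with positive expectation (unobserved states enter with
#' zero counts). Its p value comes either from the asymptotic chi-square
#' reference with `df = #states - 1 - #estimated frequencies`, or (default)
#' from Monte-Carlo multinomial resampling under the expectation; because
#' the expectation is itself estimated from the panel's allele frequencies,
#' the resampler re-estimates those frequencies inside every replicate
#' (`refit = TRUE`), which keeps the test calibrated. Per-haplotype raw p
#' values are two-sided exact binomial tests of the single cell, reported
#' alongside Bonferroni-adjusted values.
#'
#' @param observed Named count vector (keys as in
#'   [observed_haplotype_counts()]).
#' @param expected Expectation data frame from
#'   [expected_haplotype_frequencies()].
#' @param mode `"montecarlo"` (default) or `"asymptotic"`.
#' @param reps Monte-Carlo replicates.
#' @param seed Seed for the resampler; required in Monte-Carlo mode.
#' @param refit Re-estimate allele frequencies within each resample.
#' @param alpha Significance level for the over/under classification (raw
#'   p, as in descriptive haplotype maps).
#' @return Object of class `freq_test_result`: observed/expected table,
#'   `global_chi2`, `global_df`, `global_p`, per-haplotype classification,
#'   and the Monte-Carlo settings used.
#' @export
observed_vs_expected_test <- function(observed, expected,
                                      mode = c("montecarlo", "asymptotic"),
                                      reps = 10000, seed = NULL,
                                      refit = TRUE, alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(observed), !is.null(names(observed)))
  n <- sum(observed)
  if (n <= 0) stop("n must be > 0")
  n_params <- attr(expected, "n_params")
  loci_attr <- attr(expected, "loci")
  extra <- setdiff(names(observed), expected$key)
  if (length(extra)) {
    add <- expected[rep(1, length(extra)), , drop = FALSE]
    add[] <- NA
    add$key <- extra
    add$prob <- 0
    expected <- rbind(expected, add)
  }
  O <- stats::setNames(numeric(nrow(expected)), expected$key)
  O[names(observed)] <- observed
  E <- n * expected$prob

  contrib <- ifelse(E > 0, (O - E)^2 / E, ifelse(O > 0, Inf, 0))
  chi2 <- sum(contrib)
  df <- sum(expected$prob > 0) - 1L - (if (is.null(n_params)) 0L else n_params)
  infinite_cells <- expected$key[!is.finite(contrib)]

  if (mode == "asymptotic") {
    p <- if (is.finite(chi2)) stats::pchisq(chi2, df, lower.tail = FALSE)
         else NA_real_
    mc <- NULL
  } else {
    if (is.null(seed)) stop("seed is required in Monte-Carlo mode")
    pos <- expected$prob > 0          # zero-probability states are never sampled
    space <- expected[pos, , drop = FALSE]
    attr(space, "loci") <- loci_attr
    pr <- space$prob
    sim <- withr_seed(seed, {
      C <- stats::rmultinom(reps, n, pr)
      if (refit && !is.null(loci_attr)) refit_stats(C, space, n)
      else {
        Em <- matrix(n * pr, nrow(C), ncol(C))
        D <- (C - Em)^2 / Em
        D[Em == 0] <- 0
        colSums(D)
      }
    })
    p <- (1 + sum(sim >= chi2)) / (reps + 1)
    mc <- list(reps = reps, seed = seed, refit = refit)
  }

  raw_p <- vapply(seq_along(O), function(i) {
    if (expected$prob[i] <= 0) return(NA_real_)
    stats::binom.test(O[i], n, expected$prob[i])$p.value
  }, numeric(1))
  adj_p <- pmin(1, raw_p * sum(expected$prob > 0))
  direction <- ifelse(raw_p > alpha | is.na(raw_p), "none",
                      ifelse(O > E, "over", "under"))

  tab <- data.frame(key = expected$key, observed = unname(O), expected = E,
                    direction = direction, raw_p = raw_p, adj_p = adj_p,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, global_chi2 = chi2, global_df = df,
                 global_p = p, n_panel = n, mode = mode, mc = mc,
                 infinite_cells = infinite_cells),
            class = "freq_test_result")
}

#' @export
print.freq_test_result <- function(x, ...) {
  cat("<freq_test_result> n =", x$n_panel, " states =", nrow(x$table), "\n",
      sprintf("global chi^2 = %.3f, df = %d, p = %.4g (%s)\n",
              x$global_chi2, x$global_df, x$global_p, x$mode))
  sig <- x$table[x$table$direction != "none" & !is.na(x$table$raw_p), ]
  if (nrow(sig)) {
    cat(" deviating haplotypes:\n")
    print(sig[, c("key", "observed", "expected", "direction", "raw_p")],
          row.names = FALSE)
  }
  invisible(x)
}

#' One-call haplotype frequency test for a panel
#'
#' Convenience pipeline: allele frequencies, linkage-equilibrium
#' expectation, and the observed-vs-expected test, from a list of calls.
#' Calls whose state key falls outside the observable state space (i.e.
#' with a non-structural `NA` from an ambiguous profile) are calling
#' failures, not haplotypes; they are dropped from the test and counted in
#' the result's `n_dropped`.
#'
#' @inheritParams observed_vs_expected_test
#' @param calls List of `haplotype_call` objects.
#' @return A `freq_test_result` (with `n_dropped` uncallable profiles).
#' @export
haplotype_frequency_test <- function(calls, mode = c("montecarlo", "asymptotic"),
                                     reps = 10000, seed = NULL, refit = TRUE) {
  freqs <- allele_frequencies(calls)
  expected <- expected_haplotype_frequencies(freqs, loci = FREQ_LOCI,
                                             epistasis = TRUE)
  observed <- observed_haplotype_counts(calls)
  callable <- names(observed) %in% expected$key
  if (any(!callable))
    warning(sum(observed[!callable]), " profile(s) with ambiguous calls ",
            "dropped from the frequency test", call. = FALSE)
  res <- observed_vs_expected_test(observed[callable], expected, mode = mode,
                                   reps = reps, seed = seed, refit = refit)
  res$n_dropped <- sum(observed[!callable])
  res
}

#' Haplotype frequency test from panel counts
#'
#' Variant of [haplotype_frequency_test()] that starts from haplotype
#' counts over a known state space rather than from calls: single-locus
#' frequencies are estimated from the counts (marginalizing `NA` states),
#' the linkage-equilibrium expectation is rebuilt from them, and the
#' observed counts are tested against it. Used for simulation studies
#' where panels are drawn directly on the haplotype space.
#'
#' @inheritParams observed_vs_expected_test
#' @param observed Named counts; names must be keys of `space`.
#' @param space State-space data frame from
#'   [expected_haplotype_frequencies()] (its probabilities are ignored;
#'   only the states matter).
#' @return A `freq_test_result`.
#' @export
haplotype_frequency_test_counts <- function(observed, space,
                                            mode = c("montecarlo", "asymptotic"),
                                            reps = 10000, seed = NULL,
                                            refit = TRUE) {
  loci <- attr(space, "loci")
  if (is.null(loci)) stop("space must carry its loci attribute")
  cnt <- stats::setNames(numeric(nrow(space)), space$key)
  if (!all(names(observed) %in% space$key))
    stop("observed keys outside the state space")
  cnt[names(observed)] <- observed
  est <- lapply(loci, function(l) {
    v <- space[[l]]; ok <- !is.na(v)
    tot <- sum(cnt[ok])
    if (tot == 0) stop("no informative counts at locus ", l)
    states <- unique(v[ok])
    pr <- vapply(states, function(s) sum(cnt[ok & v == s]) / tot, numeric(1))
    stats::setNames(pr, states)
  })
  names(est) <- loci
  epi <- all(FREQ_LOCI %in% loci) && any(is.na(space$GSOH))
  expected <- expected_haplotype_frequencies(est, loci = loci,
                                             epistasis = epi)
  observed_vs_expected_test(cnt[cnt > 0], expected, mode = mode,
                            reps = reps, seed = seed, refit = refit)
}

# Run code with a local RNG seed without disturbing the caller's stream.
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}
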