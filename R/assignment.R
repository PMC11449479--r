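#' Match observed peaks to theoretical masses
#'
#' Nearest-mass assignment of deisotoped neutral-mass peaks against a
#' theoretical mass table. A peak is assigned to the closest theoretical
#' species within tolerance, left unassigned otherwise, and flagged
#' ambiguous when two or more candidate species fall within the tolerance
#' window (including exactly coincident theoretical masses, e.g. the
#' Lys-Arg fragment of the nn and on isotopologues). Exact distance ties
#' resolve deterministically to the lower theoretical mass, then to table
#' order. The result is invariant to the order of the input peaks.
#'
#' @param peaks data.frame with at least columns `mz` (neutral mass, Da) and
#'   `intensity`; extra columns (`level`, `time_min`, `replicate`,
#'   `precursor_mz`) pass through.
#' @param theoretical data.frame with columns `mass` plus identifier columns
#'   (e.g. from [theoretical_masses()]), or a matrix from
#'   [theoretical_table()].
#' @param tol_ppm Relative tolerance in ppm (default 20, the MS1 window).
#' @param tol_da Absolute tolerance in Da; when non-NULL it replaces the ppm
#'   window (0.02 Da is the MS2 default).
#' @return `peaks` with columns `fragment`, `isotopologue`, `theoretical_mass`,
#'   `error_da`, `error_ppm`, `ambiguous` appended (NA where unassigned).
#' @export
match_peaks <- function(peaks, theoretical = theoretical_masses(),
                        tol_ppm = 20, tol_da = NULL) {
  if (is.matrix(theoretical)) {
    theoretical <- data.frame(
      fragment = rep(rownames(theoretical), times = ncol(theoretical)),
      isotopologue = rep(colnames(theoretical), each = nrow(theoretical)),
      mass = as.vector(theoretical), stringsAsFactors = FALSE)
  }
  if (nrow(theoretical) == 0) stop("empty theoretical table")
  if (is.null(tol_da)) stopifnot(tol_ppm > 0) else stopifnot(tol_da > 0)
  # deterministic candidate order: by mass, then original row
  ord <- order(theoretical$mass, seq_len(nrow(theoretical)))
  theo <- theoretical[ord, , drop = FALSE]

  n <- nrow(peaks)
  idx <- rep(NA_integer_, n)
  amb <- rep(FALSE, n)
  for (i in seq_len(n)) {
    tol <- if (is.null(tol_da)) peaks$mz[i] * tol_ppm * 1e-6 else tol_da
    d <- abs(theo$mass - peaks$mz[i])
    inside <- which(d <= tol)
    if (length(inside) == 0) next
    idx[i] <- inside[which.min(d[inside])]  # ties -> lower mass (sorted)
    amb[i] <- length(inside) >= 2
  }
  out <- peaks
  out$fragment <- if ("fragment" %in% names(theo)) theo$fragment[idx] else NA
  out$isotopologue <-
    if ("isotopologue" %in% names(theo)) theo$isotopologue[idx] else NA
  out$theoretical_mass <- theo$mass[idx]
  out$error_da <- out$mz - out$theoretical_mass
  out$error_ppm <- 1e6 * out$error_da / out$theoretical_mass
  out$ambiguous <- amb
  out
}

#' Classify a parental peak into one of the four isotopologues
#'
#' Assigns an observed parental mass to the nearest member of the
#' theoretical parental quartet within tolerance. An exact midpoint between
#' two candidates resolves to the lower mass and is flagged ambiguous.
#'
#' @param mass Observed neutral parental mass (Da).
#' @param quartet Named numeric vector of the four parental masses (default:
#'   first row of [theoretical_table()]).
#' @param tol_ppm,tol_da Tolerance as in [match_peaks()].
#' @return list with `isotopologue` (one of nn, no, on, oo), `error_da`,
#'   `ambiguous`.
#' @export
classify_isotopologue <- function(mass, quartet = theoretical_table()[1, ],
                                  tol_ppm = 20, tol_da = NULL) {
  tol <- if (is.null(tol_da)) mass * tol_ppm * 1e-6 else tol_da
  ord <- order(quartet)
  q <- quartet[ord]
  d <- abs(q - mass)
  inside <- which(d <= tol)
  if (length(inside) == 0)
    stop("no isotopologue within tolerance of mass ", format(mass))
  pick <- inside[which.min(d[inside])]
  list(isotopologue = names(q)[pick], error_da = unname(mass - q[pick]),
       ambiguous = length(inside) >= 2)
}

#' Confirm a label state from diagnostic MS2 fragments
#'
#' The Lys-Arg fragment carries only the lpp moiety, so its mass (302.21
#' light vs 320.23 heavy) reads the Lpp label directly; the DAP->Lys-Arg
#' fragment adds the DAP stem residue, whose +9.02 Da increment reads the
#' stem label. Every assigned fragment that contains (or lacks) a moiety
#' votes on it; conflicting votes are reported, never silently overridden.
#'
#' @param assignments Output of [match_peaks()] for the MS2 peaks of one
#'   precursor (rows with NA species are ignored).
#' @return list with `isotopologue` (NA if conflicted), `stem`, `lpp`
#'   (labels or NA where no evidence), `conflict` (logical), and `evidence`
#'   (per-fragment labels).
#' @export
diagnostic_fragments <- function(assignments) {
  a <- assignments[!is.na(assignments$isotopologue), , drop = FALSE]
  if (nrow(a) == 0) stop("no assigned MS2 fragments")
  states <- isotopologue_states()
  frags <- fragment_series()
  votes_stem <- character(0); votes_lpp <- character(0)
  for (i in seq_len(nrow(a))) {
    st <- states[[a$isotopologue[i]]]
    fr <- frags[[a$fragment[i]]]
    if (is.null(fr)) next
    if ("stem" %in% fr$moieties) votes_stem <- c(votes_stem, st[["stem"]])
    if ("lpp" %in% fr$moieties) votes_lpp <- c(votes_lpp, st[["lpp"]])
  }
  pick <- function(v) {
    u <- unique(v)
    if (length(u) == 0) NA_character_ else if (length(u) == 1) u else "conflict"
  }
  stem <- pick(votes_stem); lpp <- pick(votes_lpp)
  conflict <- identical(stem, "conflict") || identical(lpp, "conflict")
  iso <- NA_character_
  if (!conflict && !is.na(stem) && !is.na(lpp)) {
    match_st <- vapply(states, function(s)
      s[["stem"]] == stem && s[["lpp"]] == lpp, logical(1))
    iso <- names(states)[match_st]
  }
  list(isotopologue = iso, stem = stem, lpp = lpp, conflict = conflict,
       evidence = a[, c("fragment", "isotopologue")])
}

#' Relative abundance of the four isotopologues
#'
#' The quantification statistic of the labeling experiment: each
#' isotopologue's intensity as a percentage of the summed intensities of
#' all four, in fixed order nn, oo, on, no.
#'
#' @param intensities Numeric vector of 4 non-negative intensities; if
#'   named with the isotopologue codes they are reordered, otherwise taken
#'   as already in order nn, oo, on, no.
#' @return Named numeric vector of 4 percentages summing to 100.
#' @examples
#' relative_abundance(c(nn = 2, oo = 3, on = 4, no = 1))
#' @export
relative_abundance <- function(intensities) {
  ord <- c("nn", "oo", "on", "no")
  stopifnot(length(intensities) == 4)
  if (!is.null(names(intensities))) {
    stopifnot(setequal(names(intensities), ord))
    intensities <- intensities[ord]
  } else names(intensities) <- ord
  if (any(intensities < 0)) stop("negative intensity")
  tot <- sum(intensities)
  if (tot <= 0) stop("relative abundance undefined: all intensities zero")
  100 * intensities / tot
}

#' Aggregate isotopologue abundances by moiety age
#'
#' Old-Lpp abundance adds the two isotopologues with a heavy Lpp moiety
#' (oo + no); old-stem adds the two with a heavy stem (oo + on); the new
#' aggregates are their complements, so each old/new pair sums to 100.
#'
#' @param quant Named vector of 4 percentages (nn, oo, on, no) or a
#'   data.frame with those columns.
#' @return Same shape with columns/elements old_lpp, new_lpp, old_stem,
#'   new_stem.
#' @export
aggregate_moieties <- function(quant) {
  if (is.data.frame(quant)) {
    stopifnot(all(c("nn", "oo", "on", "no") %in% names(quant)))
    out <- quant[setdiff(names(quant), c("nn", "oo", "on", "no"))]
    out$old_lpp <- quant$oo + quant$no
    out$new_lpp <- quant$nn + quant$on
    out$old_stem <- quant$oo + quant$on
    out$new_stem <- quant$nn + quant$no
    return(out)
  }
  q <- quant[c("nn", "oo", "on", "no")]
  c(old_lpp = unname(q["oo"] + q["no"]), new_lpp = unname(q["nn"] + q["on"]),
    old_stem = unname(q["oo"] + q["on"]), new_stem = unname(q["nn"] + q["no"]))
}

#' Quantify isotopologues from assigned MS1 peaks
#'
#' Sums assigned parental-ion intensities per sample and isotopologue and
#' computes relative abundances per replicate (replicates are never pooled
#' before the ratio; averaging across replicates, if wanted, happens on the
#' percentage scale afterwards).
#'
#' @param assignments Output of [match_peaks()] on MS1 peaks matched against
#'   the parental quartet; needs columns `time_min`, `replicate`,
#'   `intensity`, `isotopologue`.
#' @return data.frame with columns time_min, replicate, nn, oo, on, no.
#' @export
quantify_assignments <- function(assignments) {
  a <- assignments[!is.na(assignments$isotopologue), , drop = FALSE]
  if (nrow(a) == 0) stop("no assigned peaks to quantify")
  samples <- unique(a[, c("time_min", "replicate")])
  samples <- samples[order(samples$time_min, samples$replicate), , drop = FALSE]
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    sel <- a$time_min == samples$time_min[i] & a$replicate == samples$replicate[i]
    I <- vapply(c("nn", "oo", "on", "no"), function(k)
      sum(a$intensity[sel & a$isotopologue == k]), numeric(1))
    q <- relative_abundance(I)
    data.frame(time_min = samples$time_min[i], replicate = samples$replicate[i],
               nn = q[["nn"]], oo = q[["oo"]], on = q[["on"]], no = q[["no"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
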